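test_that("architecture specs carry the reference layout", {
  ls <- linearnet_spec()
  expect_equal(ls$channels, c(64L, 256L, 512L, 512L, 512L, 256L, 64L, 6L))
  expect_equal(ls$strides, c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(ls$kernels[1], 7L)
  expect_equal(ls$relu_layers, 1:5)
  expect_equal(ls$output_scale, 0.01)
  ns <- nonlinearnet_spec()
  expect_equal(ns$enc_channels, c(64L, 128L, 256L, 512L))
  expect_equal(ns$dec_channels, c(256L, 128L, 64L, 2L))
  expect_equal(ns$output_scale, 0.1)
})

test_that("zero-initialized LinearNet emits the exact identity transform", {
  set.seed(51)
  net <- linear_net(linearnet_spec(input_res = 64, width_mult = 0.25,
                                   final_init = "zero"))
  for (k in 1:5) {
    p <- linearnet_forward(net, matrix(runif(64 * 64), 64, 64),
                           matrix(runif(64 * 64), 64, 64))
    expect_identical(unname(unclass(p)), c(1, 0, 0, 1, 0, 0))
  }
  # kaiming final init stays near the identity through the x0.01 damping
  net2 <- linear_net(linearnet_spec(input_res = 64, width_mult = 0.25))
  p2 <- linearnet_forward(net2, matrix(runif(64 * 64), 64, 64),
                          matrix(runif(64 * 64), 64, 64))
  expect_lt(max(abs(unclass(p2) - c(1, 0, 0, 1, 0, 0))), 0.05)
})

test_that("LinearNet output is six scalars and pooling sees the expected
           footprint", {
  set.seed(52)
  net <- linear_net(linearnet_spec(input_res = 256, width_mult = 1 / 16))
  x <- array(runif(256 * 256 * 2 * 2), c(256, 256, 2, 2))
  P <- dualreg:::linear_net_fwd(net, x)
  expect_equal(dim(P), c(6L, 2L))
  # five stride-2 stages: 256 -> 8 before global average pooling
  expect_equal(net$gap_in_dim[1:2], c(8L, 8L))
  expect_error(linearnet_forward(net, matrix(0, 60, 60),
                                 matrix(0, 60, 60)), "multiple of 32")
})

test_that("NonlinearNet output is a bounded field at input resolution", {
  set.seed(53)
  net <- nonlinear_net(nonlinearnet_spec(input_res = 64,
                                         width_mult = 0.25))
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  f <- nonlinearnet_forward(net, a, b)
  expect_s3_class(f, "dense_field")
  expect_equal(dim(f)[1:2], c(64L, 64L))
  expect_lt(max(abs(f)), 0.1)
  # eval-mode forward is deterministic under fixed weights
  expect_identical(unclass(f), unclass(nonlinearnet_forward(net, a, b)))
  expect_error(nonlinearnet_forward(net, matrix(0, 40, 40),
                                    matrix(0, 40, 40)), "multiple of 16")
})

test_that("concat skip mode runs and matches channel arithmetic", {
  set.seed(54)
  net <- nonlinear_net(nonlinearnet_spec(input_res = 64, width_mult = 0.25,
                                         skip = "concat"))
  f <- nonlinearnet_forward(net, matrix(runif(4096), 64, 64),
                            matrix(runif(4096), 64, 64))
  expect_equal(dim(f)[1:2], c(64L, 64L))
  expect_lt(max(abs(f)), 0.1)
})

test_that("the dual network is far smaller than a FlowNet-class model", {
  nets <- dualnet()
  n <- n_params(nets)
  expect_gt(n, 1e6)
  expect_lt(n, 38e6) # FlowNetS carries ~38M learnable parameters
  expect_equal(n, n_params(nets$linear) + n_params(nets$nonlinear))
})

test_that("image-space loss gradients reach both networks through the
           warps (finite differences)", {
  set.seed(55)
  tex <- synth_texture(64, 64, n_cells = 12, seed = 5)
  pr <- make_pair(tex$image, NULL, deformation_spec(), seed = 11)
  cfg <- train_config(epochs = 1, linear_res = 32, nonlinear_res = 64,
                      width_mult = 0.25, linear_output_scale = 0.05)
  set.seed(42)
  nets <- dualreg:::build_nets(cfg)
  pair <- dualreg:::pair_at_res(pr, 64)
  loss_of <- function() {
    fw <- dualreg:::pipeline_fwd(nets, list(pair), cfg, training = TRUE)
    fn <- dense_field(fw$Fn[, , 1, 1], fw$Fn[, , 2, 1])
    total_loss(fw$it_l[[1]], fw$warped_lin[[1]], fw$warped_nonlin[[1]],
               fw$fl[[1]], fn, cfg$weights, cfg$ssim_cfg)$total
  }
  # accumulate analytic gradients for one step without updating
  fw <- dualreg:::pipeline_fwd(nets, list(pair), cfg, training = TRUE)
  fn_i <- dense_field(fw$Fn[, , 1, 1], fw$Fn[, , 2, 1])
  lo <- dualreg:::losses_with_grads(fw$it_l[[1]], fw$warped_lin[[1]],
                                    fw$warped_nonlin[[1]], fw$fl[[1]],
                                    fn_i, cfg$weights, cfg$ssim_cfg, TRUE)
  r1 <- dualreg:::.warp_bilinear_bwd(fw$warp_base[[1]], fw$Fn[, , 1, 1],
                                     fw$Fn[, , 2, 1], lo$g_warped_nonlin,
                                     TRUE)
  g_Fn <- array(0, dim = dim(fw$Fn))
  g_Fn[, , 1, 1] <- lo$g_fn[, , 1] + r1$gdx
  g_Fn[, , 2, 1] <- lo$g_fn[, , 2] + r1$gdy
  dualreg:::zero_grads(dualreg:::all_layers(nets))
  gx <- dualreg:::nonlinear_net_bwd(nets$nonlinear, g_Fn, TRUE)
  gwl <- lo$g_warped_lin + r1$gimg + gx[, , 1, 1]
  r2 <- dualreg:::.warp_bilinear_bwd(fw$is_l[[1]],
                                     dualreg:::field_dx(fw$fl[[1]]),
                                     dualreg:::field_dy(fw$fl[[1]]),
                                     gwl, FALSE)
  g <- norm_grid(64, 64)
  gflx <- r2$gdx + lo$g_fl[, , 1]
  gfly <- r2$gdy + lo$g_fl[, , 2]
  gP <- matrix(c(sum(gflx * g$x), sum(gflx * g$y),
                 sum(gfly * g$x), sum(gfly * g$y),
                 sum(gflx), sum(gfly)), 6, 1)
  dualreg:::linear_net_bwd(nets$linear, gP)

  check_weight <- function(layer, idx, tol_abs = 2e-6) {
    eps <- 1e-5
    v0 <- layer$w
    vp <- v0; vp[idx] <- vp[idx] + eps; layer$w <- vp; lp <- loss_of()
    vm <- v0; vm[idx] <- vm[idx] - eps; layer$w <- vm; lm <- loss_of()
    layer$w <- v0
    fd <- (lp - lm) / (2 * eps)
    expect_equal(fd, layer$gw[idx], tolerance = tol_abs / max(abs(fd), 1e-8))
    abs(fd)
  }
  set.seed(7)
  # residual branch: encoder, decoder, projection
  m1 <- check_weight(nets$nonlinear$layers$conv3,
                     sample(length(nets$nonlinear$layers$conv3$w), 1))
  m2 <- check_weight(nets$nonlinear$layers$conv8,
                     sample(length(nets$nonlinear$layers$conv8$w), 1))
  # affine branch: a weight with nonzero gradient (loss must respond)
  gw7 <- nets$linear$layers$conv7$gw
  idx7 <- which(abs(gw7) == max(abs(gw7)))[1]
  m3 <- check_weight(nets$linear$layers$conv7, idx7)
  expect_gt(m3, 0) # the affine branch genuinely receives gradient
})
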