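tiny_cfg <- function(...) {
  defaults <- list(epochs = 1, linear_res = 32, nonlinear_res = 64,
                   width_mult = 0.125, linear_output_scale = 0.05)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

layers_state_for_test <- function(m) {
  dualreg:::layers_state(dualreg:::all_layers(m$nets))
}

tiny_dataset <- function(n = 4, seed = 61) {
  make_dataset(n, resolution = 64, n_base = 1, n_cells = 8,
               spec = deformation_spec(), seed = seed)
}

test_that("train_config validates schedules and resolutions", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(linear_res = 48), "power of 2")
  expect_error(train_config(nonlinear_res = 96), "power of 2")
  expect_error(train_config(linear_res = 256, nonlinear_res = 64),
               "multiple")
  cfg <- train_config(epochs = 20)
  expect_equal(cfg$lr_halve_epochs, c(10L, 15L))
})

test_that("forward_pipeline returns all intermediates and is exact for
           identity networks on an undeformed pair", {
  set.seed(62)
  tex <- synth_texture(64, 64, n_cells = 8, seed = 2)
  pair <- image_pair(tex$image, tex$image)
  cfg <- tiny_cfg()
  nets <- dualnet(
    linearnet_spec(input_res = 32, width_mult = 0.125,
                   output_scale = 0.05, final_init = "zero"),
    nonlinearnet_spec(input_res = 64, width_mult = 0.125))
  # silence the residual stage too: zero final conv gives a zero field
  nets$nonlinear$layers$conv8$w[] <- 0
  nets$nonlinear$layers$conv8$b[] <- 0
  res <- forward_pipeline(pair, nets, cfg)
  expect_s3_class(res, "registration_result")
  expect_identical(unname(unclass(res$affine)), c(1, 0, 0, 1, 0, 0))
  expect_true(all(res$fn_field == 0))
  expect_equal(res$warped_lin, pair$source)
  expect_equal(res$warped_nonlin, pair$source) # identity warps are exact
  expect_s3_class(res$total_field, "dense_field")
})

test_that("one epoch on four tiny pairs runs end to end", {
  ds <- tiny_dataset()
  model <- train_dualnet(ds, tiny_cfg(seed = 63))
  expect_s3_class(model, "dualreg_model")
  expect_equal(nrow(model$history), 2) # 3 train pairs, batch 2
  expect_true(all(is.finite(model$history$total)))
  expect_equal(nrow(model$validation), 1)
  g <- glance(model)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$steps, 2)
  expect_identical(tidy(model), model$history)
})

test_that("training loss trends downward on fixed small data", {
  ds <- tiny_dataset(n = 6, seed = 64)
  model <- train_dualnet(ds, tiny_cfg(epochs = 10, lr = 0.003, seed = 65))
  by_epoch <- tapply(model$history$total, model$history$epoch, mean)
  expect_lt(mean(tail(by_epoch, 3)), mean(head(by_epoch, 3)))
})

test_that("checkpoints round-trip bit-identically", {
  ds <- tiny_dataset()
  model <- train_dualnet(ds, tiny_cfg(seed = 66))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(layers_state_for_test(model), layers_state_for_test(back))
  expect_identical(back$history, model$history)
  # restored model computes the identical registration
  p <- ds$pairs[[1]]
  r1 <- forward_pipeline(p, model$nets, model$cfg)
  r2 <- forward_pipeline(p, back$nets, back$cfg)
  expect_identical(unclass(r1$affine), unclass(r2$affine))
  expect_identical(unclass(r1$fn_field), unclass(r2$fn_field))
})

test_that("register_pair reports metrics and evaluate_model tabulates
           them", {
  ds <- tiny_dataset()
  model <- train_dualnet(ds, tiny_cfg(seed = 67))
  res <- register_pair(model, ds$pairs[[1]])
  expect_true(all(c("ssim_before", "ssim_after", "dice_before",
                    "dice_after") %in% names(res$metrics)))
  expect_true(is.matrix(res$warped_label))
  ev <- evaluate_model(model, ds$pairs[1:2])
  expect_equal(nrow(ev), 2)
  expect_true(all(is.finite(unlist(ev[, -1]))))
})

test_that("ablate trains one model per grid cell", {
  ds <- tiny_dataset(n = 10, seed = 68)
  tab <- ablate(ds, loss_subsets = list(LI = "intensity",
                                        all = c("intensity", "ssim",
                                                "linear", "smooth")),
                cfg = tiny_cfg(seed = 69))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("loss", "ssim", "dice") %in% names(tab)))
  tab1 <- ablate(ds, loss_subsets = list(all = c("intensity", "ssim",
                                                 "linear", "smooth")),
                 cfg = tiny_cfg(seed = 69))
  expect_equal(nrow(tab1), 1)
})

test_that("endpoint error measures distance to the inverse affine map", {
  p <- affine_params(a11 = 1.05, a12 = 0.02, a21 = -0.01, a22 = 0.98,
                     tx = 0.04, ty = -0.03)
  base <- endpoint_error(NULL, p, 32, 32)
  expect_gt(base, 0)
  # the exact inverse map as an affine field scores (numerically) zero
  A <- matrix(unclass(p)[1:4], 2, 2, byrow = TRUE)
  Ai <- solve(A)
  ti <- -Ai %*% unclass(p)[5:6]
  inv <- affine_params(Ai[1, 1], Ai[1, 2], Ai[2, 1], Ai[2, 2],
                       ti[1], ti[2])
  expect_lt(endpoint_error(affine_to_field(inv, 32, 32), p), 1e-12)
  expect_lt(endpoint_error(affine_to_field(inv, 32, 32), p), base)
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- tiny_dataset()
  cfg <- tiny_cfg(seed = 70, lr = NaN) # poisons the weights on step one
  expect_error(train_dualnet(ds, cfg), "non-finite")
})
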