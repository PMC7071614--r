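#' LinearNet specification
#'
#' Architecture of the affine-regression branch: an eight-stage
#' convolutional encoder over the concatenated low-resolution pair
#' (kernel 7 then 3s; five stride-2 stages with ReLU, three stride-1
#' stages with no activation so negative outputs are reachable), global
#' average pooling to six values, then `identity + output_scale * v` so a
#' zero final layer emits exactly the identity transform.
#'
#' @param input_res Input side length in pixels (default 256; must be a
#'   multiple of 32).
#' @param width_mult Channel width multiplier; 1 gives the reference
#'   channel progression 64, 256, 512, 512, 512, 256, 64, 6.
#' @param output_scale Scale applied to the pooled 6-vector before adding
#'   the identity (default 0.01).
#' @param final_init Initialization of the last convolution: `"kaiming"`
#'   (default) keeps the start near the identity through the
#'   `output_scale` damping while letting gradients reach every layer
#'   from the first step; `"zero"` makes the identity start exact but
#'   blocks gradient flow into the encoder until the final layer has
#'   moved off zero.
#' @return An object of class `linearnet_spec`.
#' @export
linearnet_spec <- function(input_res = 256, width_mult = 1,
                           output_scale = 0.01,
                           final_init = c("kaiming", "zero")) {
  base <- c(64, 256, 512, 512, 512, 256, 64)
  structure(list(
    input_res = as.integer(input_res),
    channels = c(pmax(1L, as.integer(round(base * width_mult))), 6L),
    kernels = c(7L, rep(3L, 7L)),
    strides = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
    relu_layers = 1:5,
    output_scale = output_scale,
    final_init = match.arg(final_init)), class = "linearnet_spec")
}

#' NonlinearNet specification
#'
#' Architecture of the residual dense-field branch: a shallow
#' encoder-decoder over the concatenated (affinely warped source,
#' reference) pair. Four stride-2 encoder stages (BN + LeakyReLU), then
#' three stride-1 decoder stages each fed by the 2x nearest-neighbour
#' upsampling of the previous stage combined with the matching encoder
#' feature, and a final tanh stage scaled by `output_scale` so every
#' displacement lies in (-0.1, 0.1).
#'
#' The upsampled and skip branches have unequal channel counts at the
#' reference widths (e.g. 512 vs 256), so element-wise addition requires a
#' 1x1 channel projection on the upsampled branch (`skip = "project_add"`,
#' the default); `skip = "concat"` concatenates the branches instead.
#'
#' @param input_res Input side length in pixels (default 512; must be a
#'   multiple of 16).
#' @param width_mult Channel width multiplier; 1 gives the reference
#'   channels 64, 128, 256, 512, 256, 128, 64, 2.
#' @param output_scale Field bound (default 0.1).
#' @param skip Skip-combination mode.
#' @param lrelu_slope Negative slope of the LeakyReLU (default 0.2).
#' @return An object of class `nonlinearnet_spec`.
#' @export
nonlinearnet_spec <- function(input_res = 512, width_mult = 1,
                              output_scale = 0.1,
                              skip = c("project_add", "concat"),
                              lrelu_slope = 0.2) {
  wmch <- function(x) pmax(1L, as.integer(round(x * width_mult)))
  structure(list(
    input_res = as.integer(input_res),
    enc_channels = wmch(c(64, 128, 256, 512)),
    dec_channels = c(wmch(c(256, 128, 64)), 2L),
    output_scale = output_scale,
    skip = match.arg(skip),
    lrelu_slope = lrelu_slope), class = "nonlinearnet_spec")
}

#' Build a LinearNet
#'
#' Weights are Kaiming-initialized; with `final_init = "zero"` the final
#' convolution starts at zero so the network emits the exact identity
#' transform for any input. Uses the current RNG state; seed beforehand
#' for reproducibility.
#'
#' @param spec A [linearnet_spec()].
#' @return An object of class `linear_net`.
#' @export
linear_net <- function(spec = linearnet_spec()) {
  ch <- c(2L, spec$channels)
  layers <- list()
  for (i in 1:8) {
    layers[[paste0("conv", i)]] <- layer_conv(
      spec$kernels[i], spec$kernels[i], ch[i], ch[i + 1],
      stride = spec$strides[i],
      init = if (i == 8 && identical(spec$final_init, "zero")) "zero" else
        "kaiming")
  }
  for (i in spec$relu_layers) {
    layers[[paste0("act", i)]] <- layer_act("relu")
  }
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$layers <- layers
  class(e) <- "linear_net"
  e
}

# x: [H, W, 2, N] concatenated (source, reference). Returns 6 x N matrix of
# affine parameters (a11, a12, a21, a22, tx, ty per column).
linear_net_fwd <- function(net, x) {
  L <- net$layers
  for (i in 1:8) {
    x <- conv_fwd(L[[paste0("conv", i)]], x)
    if (i %in% net$spec$relu_layers) x <- act_fwd(L[[paste0("act", i)]], x)
  }
  v <- gap_fwd(x)
  net$gap_in_dim <- attr(v, "in_dim")
  id6 <- c(1, 0, 0, 1, 0, 0)
  params <- id6 + net$spec$output_scale * unclass(v)
  dim(params) <- dim(v)
  params
}

linear_net_bwd <- function(net, gparams) {
  L <- net$layers
  g <- gap_bwd(gparams * net$spec$output_scale, net$gap_in_dim)
  for (i in 8:1) {
    if (i %in% net$spec$relu_layers) g <- act_bwd(L[[paste0("act", i)]], g)
    g <- conv_bwd(L[[paste0("conv", i)]], g, need_gx = i > 1)
  }
  invisible(NULL)
}

#' Run LinearNet on an image pair
#'
#' @param net A [linear_net()].
#' @param source,reference Images at the network input resolution.
#' @return An [affine_params()] estimate of the linear deformation.
#' @export
linearnet_forward <- function(net, source, reference) {
  check_same_shape(source, reference)
  if (nrow(source) %% 32 != 0) {
    stop("linearnet_forward: input size must be a multiple of 32")
  }
  p <- linear_net_fwd(net, stack_batch(as.matrix(source),
                                       as.matrix(reference)))
  as_affine_params(p[, 1])
}

#' Build a NonlinearNet
#'
#' @param spec A [nonlinearnet_spec()].
#' @return An object of class `nonlinear_net`.
#' @export
nonlinear_net <- function(spec = nonlinearnet_spec()) {
  ec <- spec$enc_channels
  dc <- spec$dec_channels
  project <- spec$skip == "project_add"
  dec_in <- if (project) c(ec[3], ec[2], ec[1]) else
    c(ec[4] + ec[3], dc[1] + ec[2], dc[2] + ec[1])
  layers <- list(
    conv1 = layer_conv(7, 7, 2, ec[1], stride = 2),
    bn1 = layer_bn(ec[1]), act1 = layer_act("lrelu", spec$lrelu_slope),
    conv2 = layer_conv(3, 3, ec[1], ec[2], stride = 2),
    bn2 = layer_bn(ec[2]), act2 = layer_act("lrelu", spec$lrelu_slope),
    conv3 = layer_conv(3, 3, ec[2], ec[3], stride = 2),
    bn3 = layer_bn(ec[3]), act3 = layer_act("lrelu", spec$lrelu_slope),
    conv4 = layer_conv(3, 3, ec[3], ec[4], stride = 2),
    bn4 = layer_bn(ec[4]), act4 = layer_act("lrelu", spec$lrelu_slope),
    conv5 = layer_conv(3, 3, dec_in[1], dc[1], stride = 1),
    bn5 = layer_bn(dc[1]), act5 = layer_act("lrelu", spec$lrelu_slope),
    conv6 = layer_conv(3, 3, dec_in[2], dc[2], stride = 1),
    bn6 = layer_bn(dc[2]), act6 = layer_act("lrelu", spec$lrelu_slope),
    conv7 = layer_conv(3, 3, dec_in[3], dc[3], stride = 1),
    bn7 = layer_bn(dc[3]), act7 = layer_act("lrelu", spec$lrelu_slope),
    conv8 = layer_conv(3, 3, dc[3], 2L, stride = 1),
    act8 = layer_act("tanh"))
  if (project) {
    layers$proj5 <- layer_conv(1, 1, ec[4], ec[3], stride = 1, pad = 0)
    layers$proj6 <- layer_conv(1, 1, dc[1], ec[2], stride = 1, pad = 0)
    layers$proj7 <- layer_conv(1, 1, dc[2], ec[1], stride = 1, pad = 0)
  }
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$layers <- layers
  class(e) <- "nonlinear_net"
  e
}

cat_c <- function(a, b) {
  # concatenate two [H, W, C, N] arrays along the channel axis
  d <- dim(a); db <- dim(b)
  out <- array(0, dim = c(d[1], d[2], d[3] + db[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(db[3]), ] <- b
  out
}

# x: [H, W, 2, N] concatenated (warped source, reference). Returns
# [H, W, 2, N] displacement field, every value in (-scale, scale).
nonlinear_net_fwd <- function(net, x, training = FALSE) {
  L <- net$layers
  project <- net$spec$skip == "project_add"
  block <- function(i, inp) {
    act_fwd(L[[paste0("act", i)]],
            bn_fwd(L[[paste0("bn", i)]],
                   conv_fwd(L[[paste0("conv", i)]], inp), training))
  }
  x1 <- block(1, x)
  x2 <- block(2, x1)
  x3 <- block(3, x2)
  x4 <- block(4, x3)
  s5 <- if (project) conv_fwd(L$proj5, up2_fwd(x4)) + x3 else
    cat_c(up2_fwd(x4), x3)
  x5 <- block(5, s5)
  s6 <- if (project) conv_fwd(L$proj6, up2_fwd(x5)) + x2 else
    cat_c(up2_fwd(x5), x2)
  x6 <- block(6, s6)
  s7 <- if (project) conv_fwd(L$proj7, up2_fwd(x6)) + x1 else
    cat_c(up2_fwd(x6), x1)
  x7 <- block(7, s7)
  z <- conv_fwd(L$conv8, up2_fwd(x7))
  net$enc_ch <- c(dim(x1)[3], dim(x2)[3], dim(x3)[3])
  act_fwd(L$act8, z) * net$spec$output_scale
}

nonlinear_net_bwd <- function(net, g, need_gx = TRUE) {
  L <- net$layers
  project <- net$spec$skip == "project_add"
  block_bwd <- function(i, gi, need = TRUE) {
    conv_bwd(L[[paste0("conv", i)]],
             bn_bwd(L[[paste0("bn", i)]],
                    act_bwd(L[[paste0("act", i)]], gi)), need_gx = need)
  }
  split_c <- function(gs, n_up) {
    # adjoint of cat_c: first n_up channels to the upsampled branch
    nc <- dim(gs)[3]
    list(up = gs[, , seq_len(n_up), , drop = FALSE],
         skip = gs[, , (n_up + 1):nc, , drop = FALSE])
  }
  gz <- act_bwd(L$act8, g * net$spec$output_scale)
  g7 <- up2_bwd(conv_bwd(L$conv8, gz))
  gs7 <- block_bwd(7, g7)
  if (project) {
    g6 <- up2_bwd(conv_bwd(L$proj7, gs7))
    gskip1 <- gs7
  } else {
    sp <- split_c(gs7, dim(gs7)[3] - net$enc_ch[1])
    g6 <- up2_bwd(sp$up)
    gskip1 <- sp$skip
  }
  gs6 <- block_bwd(6, g6)
  if (project) {
    g5 <- up2_bwd(conv_bwd(L$proj6, gs6))
    gskip2 <- gs6
  } else {
    sp <- split_c(gs6, dim(gs6)[3] - net$enc_ch[2])
    g5 <- up2_bwd(sp$up)
    gskip2 <- sp$skip
  }
  gs5 <- block_bwd(5, g5)
  if (project) {
    g4 <- up2_bwd(conv_bwd(L$proj5, gs5))
    gskip3 <- gs5
  } else {
    sp <- split_c(gs5, dim(gs5)[3] - net$enc_ch[3])
    g4 <- up2_bwd(sp$up)
    gskip3 <- sp$skip
  }
  gx3 <- block_bwd(4, g4) + gskip3
  gx2 <- block_bwd(3, gx3) + gskip2
  gx1 <- block_bwd(2, gx2) + gskip1
  block_bwd(1, gx1, need = need_gx)
}

#' Run NonlinearNet on a (warped source, reference) pair
#'
#' @param net A [nonlinear_net()].
#' @param warped_source,reference Images at the network input resolution
#'   (side length a multiple of 16).
#' @param training Use batch statistics (TRUE) or running statistics
#'   (FALSE) in the batch-norm layers.
#' @return A [dense_field()] with every displacement in
#'   (-output_scale, output_scale).
#' @export
nonlinearnet_forward <- function(net, warped_source, reference,
                                 training = FALSE) {
  check_same_shape(warped_source, reference)
  if (nrow(warped_source) %% 16 != 0) {
    stop("nonlinearnet_forward: input size must be a multiple of 16")
  }
  f <- nonlinear_net_fwd(net, stack_batch(as.matrix(warped_source),
                                          as.matrix(reference)), training)
  dense_field(f[, , 1, 1], f[, , 2, 1])
}

#' Dual network: LinearNet plus NonlinearNet
#'
#' @param linear_spec,nonlinear_spec Architecture specifications.
#' @return An object of class `dualnet` with elements `linear` and
#'   `nonlinear`.
#' @export
dualnet <- function(linear_spec = linearnet_spec(),
                    nonlinear_spec = nonlinearnet_spec()) {
  structure(list(linear = linear_net(linear_spec),
                 nonlinear = nonlinear_net(nonlinear_spec)),
            class = "dualnet")
}

all_layers <- function(nets) c(nets$linear$layers, nets$nonlinear$layers)

#' Number of learnable parameters
#'
#' @param nets A `dualnet`, `linear_net` or `nonlinear_net`.
#' @return Integer parameter count (convolution weights and biases, BN
#'   scale and shift).
#' @export
n_params <- function(nets) {
  layers <- if (inherits(nets, "dualnet")) all_layers(nets) else nets$layers
  sum(vapply(layers, layer_n_params, numeric(1)))
}

#' @export
print.dualnet <- function(x, ...) {
  cat(sprintf(
    "<dualnet> LinearNet %s params @%d^2, NonlinearNet %s params @%d^2\n",
    format(n_params(x$linear), big.mark = ","), x$linear$spec$input_res,
    format(n_params(x$nonlinear), big.mark = ","),
    x$nonlinear$spec$input_res))
  invisible(x)
}
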