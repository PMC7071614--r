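#' Loss weights for unsupervised training
#'
#' Weights of the four unsupervised loss terms: L1 intensity, structural
#' similarity, the affine near-identity constraint, and the dense-field
#' smoothness constraint. Defaults are the published operating point
#' (0.15, 0.85, 1, 0.1).
#'
#' @param intensity,ssim,linear,smooth Non-negative scalars.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(intensity = 0.15, ssim = 0.85, linear = 1,
                         smooth = 0.1) {
  w <- c(intensity = intensity, ssim = ssim, linear = linear,
         smooth = smooth)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("loss_weights: weights must be finite and non-negative")
  }
  structure(as.list(w), class = "loss_weights")
}

check_same_shape <- function(...) {
  ms <- list(...)
  d <- dim(as.matrix(ms[[1]]))
  for (m in ms[-1]) {
    if (!identical(dim(as.matrix(m)), d)) stop("shape mismatch")
  }
  invisible(d)
}

#' Intensity (L1) loss
#'
#' Sum of the mean absolute differences between the reference and each of
#' the two warped source images (after the affine stage and after the
#' residual stage). The L1 norm is normalized per pixel so the weight keeps
#' its meaning across image resolutions.
#'
#' @param it Reference image.
#' @param warped_lin Source warped by the affine stage.
#' @param warped_nonlin Source after the residual dense warp.
#' @return Non-negative scalar; 0 iff both warps equal the reference.
#' @export
intensity_loss <- function(it, warped_lin, warped_nonlin) {
  check_same_shape(it, warped_lin, warped_nonlin)
  mean(abs(it - warped_lin)) + mean(abs(it - warped_nonlin))
}

#' Structural-similarity loss
#'
#' `(1 - SSIM(it, warped_lin))/2 + (1 - SSIM(it, warped_nonlin))/2`: each
#' term maps SSIM in \[-1, 1\] linearly to \[0, 1\], so the loss lies in
#' \[0, 2\] and vanishes exactly at perfect alignment of both stages. Set
#' `halved = FALSE` to drop the /2 (the alternative reading of the
#' term).
#'
#' @inheritParams intensity_loss
#' @param cfg An [ssim_config()]; the same patch machinery as the
#'   evaluation metric.
#' @param halved Divide each `1 - SSIM` term by two (default).
#' @return Non-negative scalar.
#' @export
ssim_loss <- function(it, warped_lin, warped_nonlin, cfg = ssim_config(),
                      halved = TRUE) {
  check_same_shape(it, warped_lin, warped_nonlin)
  s <- if (halved) 2 else 1
  (1 - ssim(warped_lin, it, cfg)) / s + (1 - ssim(warped_nonlin, it, cfg)) / s
}

#' Affine near-identity constraint
#'
#' Mean absolute value of the dense expansion of the affine deformation
#' field. Penalizing the field (rather than the raw parameters) keeps the
#' early, randomly initialized affine stage from drifting into implausible
#' scalings: every displacement it induces must stay near zero.
#'
#' @param fl A `dense_field` (the affine deformation expanded on the grid).
#' @return Non-negative scalar; 0 iff the affine is the identity.
#' @export
linear_constraint <- function(fl) {
  fl <- as_dense_field(fl)
  mean(abs(fl))
}

# forward first differences along rows and columns, valid region only
diff_rows <- function(m) m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
diff_cols <- function(m) m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]

#' Smoothness constraint on the residual dense field
#'
#' Mean L1 norm of first-order plus second-order forward finite
#' differences of the field, over both spatial axes and both displacement
#' channels (valid region only, no padding). Zero for any constant field;
#' for a linear ramp only the first-order term contributes.
#'
#' @param fn A `dense_field`.
#' @return Non-negative scalar.
#' @export
smoothness_constraint <- function(fn) {
  fn <- as_dense_field(fn)
  d1 <- c(); d2 <- c()
  for (ch in 1:2) {
    m <- fn[, , ch]
    dr <- diff_rows(m); dc <- diff_cols(m)
    d1 <- c(d1, dr, dc)
    d2 <- c(d2, diff_rows(dr), diff_cols(dc))
  }
  mean(abs(d1)) + mean(abs(d2))
}

#' Total training loss
#'
#' Weighted combination of the four unsupervised terms,
#' `total = w_I * L_I + w_SSIM * L_SSIM + w_lc * L_lc + w_nc * L_nc`,
#' returned with each term individually for logging and loss-ablation
#' studies. Zero weights drop a term from both the total and (in training)
#' its gradient.
#'
#' @inheritParams ssim_loss
#' @param fl Dense expansion of the estimated affine deformation.
#' @param fn Estimated residual dense field.
#' @param w A [loss_weights()].
#' @return An object of class `loss_report` with elements `intensity`,
#'   `ssim`, `linear`, `smooth`, `total`, `weights`.
#' @export
total_loss <- function(it, warped_lin, warped_nonlin, fl, fn,
                       w = loss_weights(), cfg = ssim_config(),
                       halved = TRUE) {
  if (!inherits(w, "loss_weights")) w <- do.call(loss_weights, as.list(w))
  li <- intensity_loss(it, warped_lin, warped_nonlin)
  ls <- ssim_loss(it, warped_lin, warped_nonlin, cfg, halved)
  lc <- linear_constraint(fl)
  nc <- smoothness_constraint(fn)
  structure(list(intensity = li, ssim = ls, linear = lc, smooth = nc,
                 total = w$intensity * li + w$ssim * ls +
                   w$linear * lc + w$smooth * nc,
                 weights = w),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "<loss_report> total %.5f (LI %.5f, LSSIM %.5f, Llc %.5f, Lnc %.5f)\n",
    x$total, x$intensity, x$ssim, x$linear, x$smooth))
  invisible(x)
}

#' Tidy a loss report into a one-row tibble
#' @param x A `loss_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.loss_report <- function(x, ...) {
  tibble::tibble(intensity = x$intensity, ssim = x$ssim, linear = x$linear,
                 smooth = x$smooth, total = x$total)
}

# ---- gradient machinery (training-internal) --------------------------------

# d mean|x - ref| / dx
l1_grad <- function(x, ref) sign(x - ref) / length(x)

# gradient of smoothness_constraint w.r.t. the field array
smoothness_grad <- function(fn) {
  h <- dim(fn)[1]; w <- dim(fn)[2]
  n1 <- 2 * ((h - 1) * w + h * (w - 1))
  n2 <- 2 * (max(h - 2, 0) * w + h * max(w - 2, 0))
  g <- array(0, dim = dim(fn))
  add_adj_rows <- function(gm, s) { # adjoint of diff_rows with upstream s
    gm[-1, ] <- gm[-1, ] + s
    gm[-nrow(gm), ] <- gm[-nrow(gm), ] - s
    gm
  }
  add_adj_cols <- function(gm, s) {
    gm[, -1] <- gm[, -1] + s
    gm[, -ncol(gm)] <- gm[, -ncol(gm)] - s
    gm
  }
  for (ch in 1:2) {
    m <- fn[, , ch]
    dr <- diff_rows(m); dc <- diff_cols(m)
    gm <- matrix(0, h, w)
    gm <- add_adj_rows(gm, sign(dr) / n1)
    gm <- add_adj_cols(gm, sign(dc) / n1)
    if (n2 > 0) {
      if (h > 2) {
        gdr <- add_adj_rows(matrix(0, h - 1, w), sign(diff_rows(dr)) / n2)
        gm <- add_adj_rows(gm, gdr)
      }
      if (w > 2) {
        gdc <- add_adj_cols(matrix(0, h, w - 1), sign(diff_cols(dc)) / n2)
        gm <- add_adj_cols(gm, gdc)
      }
    }
    g[, , ch] <- gm
  }
  g
}

# All four losses with gradients w.r.t. the two warped images and the two
# fields. Zero-weight terms contribute nothing (and skip their gradient).
losses_with_grads <- function(it, warped_lin, warped_nonlin, fl, fn,
                              w = loss_weights(), cfg = ssim_config(),
                              halved = TRUE) {
  s <- if (halved) 2 else 1
  g_lin <- matrix(0, nrow(it), ncol(it))
  g_nonlin <- matrix(0, nrow(it), ncol(it))

  li <- mean(abs(it - warped_lin)) + mean(abs(it - warped_nonlin))
  if (w$intensity > 0) {
    g_lin <- g_lin + w$intensity * l1_grad(warped_lin, it)
    g_nonlin <- g_nonlin + w$intensity * l1_grad(warped_nonlin, it)
  }

  if (w$ssim > 0) {
    sg1 <- ssim_with_grad(warped_lin, it, cfg)
    sg2 <- ssim_with_grad(warped_nonlin, it, cfg)
    ls <- (1 - sg1$value) / s + (1 - sg2$value) / s
    g_lin <- g_lin - w$ssim * sg1$grad / s
    g_nonlin <- g_nonlin - w$ssim * sg2$grad / s
  } else {
    ls <- ssim_loss(it, warped_lin, warped_nonlin, cfg, halved)
  }

  lc <- mean(abs(fl))
  g_fl <- if (w$linear > 0) {
    w$linear * array(sign(as.vector(fl)) / length(fl), dim = dim(fl))
  } else {
    array(0, dim = dim(fl))
  }

  nc <- smoothness_constraint(fn)
  g_fn <- if (w$smooth > 0) {
    w$smooth * smoothness_grad(fn)
  } else {
    array(0, dim = dim(fn))
  }

  list(report = structure(list(
         intensity = li, ssim = ls, linear = lc, smooth = nc,
         total = w$intensity * li + w$ssim * ls + w$linear * lc +
           w$smooth * nc,
         weights = w), class = "loss_report"),
       g_warped_lin = g_lin, g_warped_nonlin = g_nonlin,
       g_fl = g_fl, g_fn = g_fn)
}
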