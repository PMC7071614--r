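# Quick-look displays built on base graphics (images are matrices; a
# raster display is all that is needed).

img_raster <- function(m, main = "") {
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(m) / ncol(m), main = main,
                  useRaster = TRUE)
}

#' @export
plot.image_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  img_raster(x$source, "source")
  img_raster(x$reference, "reference")
  invisible(x)
}

#' @param every Subsampling stride of the displacement arrows.
#' @export
#' @rdname dense_field
plot.dense_field <- function(x, every = max(1, nrow(x) %/% 16), ...) {
  h <- nrow(x); w <- ncol(x)
  ii <- seq(1, h, by = every); jj <- seq(1, w, by = every)
  g <- norm_grid(h, w)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(1, -1), asp = 1,
                 xlab = "x", ylab = "y", main = "displacement field")
  graphics::arrows(g$x[ii, jj], g$y[ii, jj],
                   g$x[ii, jj] + x[ii, jj, 1], g$y[ii, jj] + x[ii, jj, 2],
                   length = 0.03, col = "steelblue")
  invisible(x)
}

#' @export
plot.registration_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  img_raster(x$pair$source, "source")
  img_raster(x$pair$reference, "reference")
  img_raster(x$warped_lin, "after affine")
  img_raster(x$warped_nonlin, "registered")
  invisible(x)
}

#' @export
plot.dualreg_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$total, type = "l", xlab = "step",
                 ylab = "loss", main = "training loss")
  invisible(x)
}
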