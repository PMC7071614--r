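#' Affine transformation parameters
#'
#' Six scalars parameterizing a 2-D affine map `x -> A x + t` on the
#' normalized image grid, where `A = [[a11, a12], [a21, a22]]` and
#' `t = (tx, ty)`. The normalized grid spans \[-1, 1\] in each axis with
#' pixel centers at the endpoints (align-corners convention), so the same
#' parameters describe the same geometric transform at any resolution.
#'
#' @param a11,a12,a21,a22 Dimensionless linear-part coefficients.
#' @param tx,ty Translations in normalized coordinates.
#' @return An object of class `affine_params` (named numeric of length 6).
#' @seealso [identity_affine()], [affine_to_field()], [apply_affine()]
#' @export
affine_params <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1,
                          tx = 0, ty = 0) {
  p <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22, tx = tx, ty = ty)
  if (length(p) != 6L || !is.numeric(p)) {
    stop("affine_params: six numeric scalars required")
  }
  if (!all(is.finite(p))) stop("affine_params: non-finite parameter")
  structure(as.double(p), names = names(p), class = "affine_params")
}

#' @rdname affine_params
#' @export
identity_affine <- function() affine_params()

#' @param x Numeric vector of length 6 (order a11, a12, a21, a22, tx, ty)
#'   or an `affine_params` object.
#' @rdname affine_params
#' @export
as_affine_params <- function(x) {
  if (inherits(x, "affine_params")) return(x)
  x <- as.double(x)
  if (length(x) != 6L) stop("as_affine_params: expected 6 values")
  affine_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params> A = [", format(x[1:2], digits = 4), ";",
      format(x[3:4], digits = 4), "], t = (",
      format(x[5], digits = 4), ",", format(x[6], digits = 4), ")\n")
  invisible(x)
}

#' Determinant of the linear part of an affine transform
#'
#' Invertibility is checked on request, not at construction.
#' @param p An `affine_params` object.
#' @return The determinant `a11*a22 - a12*a21`.
#' @export
affine_det <- function(p) {
  p <- as_affine_params(p)
  unname(p["a11"] * p["a22"] - p["a12"] * p["a21"])
}

#' Dense displacement field
#'
#' A per-pixel 2-vector displacement map in normalized coordinates: channel
#' `dx` displaces along image columns (x, horizontal), channel `dy` along
#' rows (y, vertical). Warping is backward: the output pixel at grid
#' position `x` samples the source image at `x + d(x)`.
#'
#' @param dx,dy Numeric H x W matrices of displacements.
#' @return An H x W x 2 array of class `dense_field` with the third
#'   dimension named `c("dx", "dy")`.
#' @export
dense_field <- function(dx, dy) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy))) stop("dense_field: dx/dy shape mismatch")
  if (!all(is.finite(dx)) || !all(is.finite(dy))) {
    stop("dense_field: non-finite displacement")
  }
  f <- array(c(dx, dy), dim = c(nrow(dx), ncol(dx), 2L),
             dimnames = list(NULL, NULL, c("dx", "dy")))
  class(f) <- c("dense_field", "array")
  f
}

#' @param h,w Field height and width in pixels.
#' @rdname dense_field
#' @export
zero_field <- function(h, w) {
  z <- matrix(0, h, w)
  dense_field(z, z)
}

#' @export
print.dense_field <- function(x, ...) {
  cat(sprintf("<dense_field> %d x %d, |d| in [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(abs(x)), max(abs(x))))
  invisible(x)
}

field_dx <- function(f) f[, , 1L]
field_dy <- function(f) f[, , 2L]

as_dense_field <- function(f) {
  if (inherits(f, "dense_field")) return(f)
  if (is.array(f) && length(dim(f)) == 3L && dim(f)[3] == 2L) {
    return(dense_field(f[, , 1L], f[, , 2L]))
  }
  stop("expected a dense_field or an H x W x 2 array")
}

#' Normalized coordinate grid
#'
#' Pixel-center coordinates of an `h` x `w` grid in the align-corners
#' normalized convention: column j maps to x = -1 + 2 (j-1)/(w-1), row i to
#' y = -1 + 2 (i-1)/(h-1).
#'
#' @param h,w Grid size in pixels (both >= 2).
#' @return List with H x W matrices `x` and `y`.
#' @export
norm_grid <- function(h, w) {
  if (h < 2 || w < 2) stop("norm_grid: grid must be at least 2 x 2")
  gx <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  gy <- matrix(seq(-1, 1, length.out = h), h, w)
  list(x = gx, y = gy)
}

#' Expand affine parameters to a dense displacement field
#'
#' Evaluates `d(x) = A x + t - x` on the normalized grid, so that warping
#' with the resulting field applies the affine transform through the same
#' sampler as any dense field. The expansion is resolution-free: the same
#' parameters yield the same geometric transform at any grid size.
#'
#' @param p An `affine_params` object (or length-6 numeric).
#' @param h,w Output grid size in pixels (both >= 2).
#' @return A `dense_field` of size h x w.
#' @export
affine_to_field <- function(p, h, w) {
  p <- as_affine_params(p)
  g <- norm_grid(h, w)
  dx <- (p[["a11"]] - 1) * g$x + p[["a12"]] * g$y + p[["tx"]]
  dy <- p[["a21"]] * g$x + (p[["a22"]] - 1) * g$y + p[["ty"]]
  dense_field(dx, dy)
}

#' Warp an image with a dense displacement field
#'
#' Backward warping through a spatial-transformer-style sampler:
#' `out(x) = image(x + d(x))`, with bilinear interpolation for intensity
#' images (differentiable with respect to the field) or nearest-neighbour
#' for integer label images. Samples falling outside the image replicate
#' the border value.
#'
#' @param image Numeric H x W matrix.
#' @param field A `dense_field` with the same H x W shape.
#' @param mode `"bilinear"` for intensities, `"nearest"` for labels.
#' @return Warped H x W matrix (integer-valued when the input is and mode
#'   is nearest).
#' @export
warp_image <- function(image, field, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  image <- as.matrix(image)
  field <- as_dense_field(field)
  if (!identical(dim(image), dim(field)[1:2])) {
    stop("warp_image: image and field shapes differ")
  }
  if (mode == "bilinear") {
    .warp_bilinear(image, field_dx(field), field_dy(field))
  } else {
    .warp_nearest(image, field_dx(field), field_dy(field))
  }
}

#' Compose two displacement fields
#'
#' Returns the field `c` of the composite warp, such that
#' `warp_image(I, c)` approximates `warp_image(warp_image(I, inner), outer)`
#' up to interpolation error:
#' `c(x) = d_outer(x) + d_inner(x + d_outer(x))`, with the inner field
#' sampled bilinearly (border replicated).
#'
#' @param outer,inner `dense_field`s of identical shape. `outer` is the
#'   field of the warp applied last.
#' @return A `dense_field`.
#' @export
compose_fields <- function(outer, inner) {
  outer <- as_dense_field(outer); inner <- as_dense_field(inner)
  if (!identical(dim(outer), dim(inner))) {
    stop("compose_fields: shape mismatch")
  }
  odx <- field_dx(outer); ody <- field_dy(outer)
  dense_field(odx + .warp_bilinear(field_dx(inner), odx, ody),
              ody + .warp_bilinear(field_dy(inner), odx, ody))
}

#' Apply an affine transform to an image
#'
#' Equivalent to `warp_image(image, affine_to_field(p, out_h, out_w))`.
#' Because parameters live in normalized coordinates, a transform estimated
#' at one resolution can be applied at another (e.g. estimated on a 256^2
#' downsample, applied at 512^2).
#'
#' @param image Numeric matrix.
#' @param p An `affine_params` object.
#' @param out_h,out_w Output size; defaults to the input size.
#' @param mode Interpolation mode, as in [warp_image()].
#' @return Warped matrix of size `out_h` x `out_w`.
#' @export
apply_affine <- function(image, p, out_h = nrow(image), out_w = ncol(image),
                         mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  image <- as.matrix(image)
  f <- affine_to_field(p, out_h, out_w)
  if (mode == "bilinear") {
    .warp_bilinear(image, field_dx(f), field_dy(f))
  } else {
    .warp_nearest(image, field_dx(f), field_dy(f))
  }
}

#' Image pair container
#'
#' A source/reference image pair (intensities in \[0, 1\]) with optional
#' co-registered integer label images for overlap evaluation.
#'
#' @param source,reference Numeric H x W matrices in \[0, 1\].
#' @param source_label,reference_label Optional non-negative integer H x W
#'   matrices.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(source, reference,
                       source_label = NULL, reference_label = NULL) {
  source <- as.matrix(source); reference <- as.matrix(reference)
  if (!identical(dim(source), dim(reference))) {
    stop("image_pair: source and reference shapes differ")
  }
  for (lab in list(source_label, reference_label)) {
    if (!is.null(lab)) {
      if (!identical(dim(as.matrix(lab)), dim(source))) {
        stop("image_pair: label shape differs from images")
      }
      if (any(lab < 0) || any(lab != round(lab))) {
        stop("image_pair: labels must be non-negative integers")
      }
    }
  }
  structure(list(source = source, reference = reference,
                 source_label = source_label,
                 reference_label = reference_label,
                 resolution = dim(source)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d%s\n", nrow(x$source), ncol(x$source),
              if (!is.null(x$source_label)) ", with labels" else ""))
  invisible(x)
}

#' Block-average downsampling
#'
#' Area-averaging downsample by an integer factor, used to build the
#' low-resolution inputs of the affine-regression network.
#'
#' @param image Numeric H x W matrix; H and W must be multiples of
#'   `factor`.
#' @param factor Integer downsampling factor (>= 1).
#' @return Matrix of size (H/factor) x (W/factor).
#' @export
downsample_image <- function(image, factor) {
  image <- as.matrix(image)
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- nrow(image); w <- ncol(image)
  if (h %% factor != 0 || w %% factor != 0) {
    stop("downsample_image: size not divisible by factor")
  }
  a <- array(image, dim = c(factor, h %/% factor, factor, w %/% factor))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}
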