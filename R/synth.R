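#' Random deformation specification
#'
#' Parameters of the synthetic deformation protocol: a random affine
#' perturbation of the identity combined with a thin-plate-spline (TPS)
#' field whose control-point displacement vectors are drawn from a
#' zero-mean normal distribution at positions uniformly distributed over
#' the image grid.
#'
#' Default magnitudes (affine_sigma 0.05, 10 control points, tps_sigma
#' 0.03, all in normalized units) are chosen so the deformations are
#' visibly nontrivial yet leave a residual representable within the
#' (-0.1, 0.1) output range of the residual network once the affine part
#' has been removed.
#'
#' @param affine_sigma Std-dev of zero-mean normal perturbations applied to
#'   all six identity-affine entries (dimensionless / normalized units).
#' @param n_control_points Number of TPS control points (>= 3 whenever
#'   `tps_sigma > 0`).
#' @param tps_sigma Std-dev of control-point displacement vectors in
#'   normalized units.
#' @param tps_reg TPS regularization added to the kernel diagonal; 0 gives
#'   exact interpolation.
#' @param seed Optional RNG seed used by generator calls that draw from
#'   this spec.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(affine_sigma = 0.05, n_control_points = 10,
                             tps_sigma = 0.03, tps_reg = 0, seed = NULL) {
  if (affine_sigma < 0 || tps_sigma < 0 || tps_reg < 0) {
    stop("deformation_spec: sigmas must be >= 0")
  }
  if (tps_sigma > 0 && n_control_points < 3) {
    stop("deformation_spec: need >= 3 control points when tps_sigma > 0")
  }
  structure(list(affine_sigma = affine_sigma,
                 n_control_points = as.integer(n_control_points),
                 tps_sigma = tps_sigma, tps_reg = tps_reg, seed = seed),
            class = "deformation_spec")
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Draw a random affine transform
#'
#' Identity parameters plus independent zero-mean normal perturbations of
#' std-dev `affine_sigma` on all six entries.
#'
#' @param spec A [deformation_spec()].
#' @param seed Optional seed (defaults to `spec$seed`); `NULL` continues
#'   the current RNG stream.
#' @return An [affine_params()].
#' @export
random_affine <- function(spec = deformation_spec(), seed = spec$seed) {
  maybe_seed(seed)
  as_affine_params(c(1, 0, 0, 1, 0, 0) +
                     stats::rnorm(6, 0, spec$affine_sigma))
}

# thin-plate radial basis U(r) = r^2 log(r^2), with U(0) = 0
tps_u <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

# Solve the TPS system for one displacement component: weights w and
# affine part a such that f(x) = a0 + a1 x + a2 y + sum_i w_i U(|x - p_i|)
# interpolates v at the control points p.
tps_solve <- function(pts, v, reg = 0) {
  n <- nrow(pts)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  K <- tps_u(d2) + diag(reg, n)
  P <- cbind(1, pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, 0, 0, 0))
  list(w = sol[1:n], a = sol[n + 1:3])
}

tps_eval <- function(fit, pts, gx, gy) {
  d2 <- outer(as.vector(gx), pts[, 1], "-")^2 +
    outer(as.vector(gy), pts[, 2], "-")^2
  v <- fit$a[1] + fit$a[2] * as.vector(gx) + fit$a[3] * as.vector(gy) +
    as.vector(tps_u(d2) %*% fit$w)
  matrix(v, nrow = nrow(gx))
}

#' Draw a random thin-plate-spline displacement field
#'
#' Control points are uniform over the normalized grid; their displacement
#' vectors are N(0, tps_sigma^2) per component. The dense field is the TPS
#' interpolant (radial basis `U(r) = r^2 log r^2` plus affine term) of
#' those displacements, solved per component; it passes exactly through
#' every control-point displacement when `tps_reg = 0`.
#'
#' @inheritParams random_affine
#' @param h,w Field size in pixels.
#' @param on_singular What to do if the control points make the TPS system
#'   numerically singular: redraw them (`"resample"`, default) or raise.
#' @return A [dense_field()] carrying the drawn control points and
#'   displacements as attributes `control_points` and `displacements`.
#' @export
random_tps_field <- function(spec = deformation_spec(), h, w,
                             seed = spec$seed,
                             on_singular = c("resample", "error")) {
  on_singular <- match.arg(on_singular)
  maybe_seed(seed)
  if (spec$tps_sigma == 0) return(zero_field(h, w))
  n <- spec$n_control_points
  g <- norm_grid(h, w)
  for (attempt in 1:20) {
    pts <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1))
    disp <- cbind(stats::rnorm(n, 0, spec$tps_sigma),
                  stats::rnorm(n, 0, spec$tps_sigma))
    fit <- tryCatch(list(x = tps_solve(pts, disp[, 1], spec$tps_reg),
                         y = tps_solve(pts, disp[, 2], spec$tps_reg)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      f <- dense_field(tps_eval(fit$x, pts, g$x, g$y),
                       tps_eval(fit$y, pts, g$x, g$y))
      attr(f, "control_points") <- pts
      attr(f, "displacements") <- disp
      return(f)
    }
    if (on_singular == "error") {
      stop("random_tps_field: singular TPS system")
    }
  }
  stop("random_tps_field: singular TPS system after 20 redraws")
}

#' Generate a deformed synthetic pair
#'
#' Applies a random affine plus TPS deformation to a base image (treated as
#' the reference): the total field is the composition of the TPS field with
#' the dense affine field, the source is the reference warped by that total
#' field (bilinear for intensity, nearest for the label). The drawn ground
#' truth is stored so recovery can be measured.
#'
#' @param base_image Reference intensity image in \[0, 1\].
#' @param base_label Optional integer label image of the same shape.
#' @param spec A [deformation_spec()].
#' @param seed Optional seed (defaults to `spec$seed`).
#' @return An object of class `synthetic_pair`: an [image_pair()] plus
#'   `gt_affine`, `gt_tps_field` and `gt_field` (the total applied
#'   deformation).
#' @export
make_pair <- function(base_image, base_label = NULL,
                      spec = deformation_spec(), seed = spec$seed) {
  base_image <- as.matrix(base_image)
  if (!is.null(base_label)) check_same_shape(base_image, base_label)
  maybe_seed(seed)
  h <- nrow(base_image); w <- ncol(base_image)
  p <- random_affine(spec, seed = NULL)
  tps <- random_tps_field(spec, h, w, seed = NULL)
  total <- compose_fields(tps, affine_to_field(p, h, w))
  src <- warp_image(base_image, total, mode = "bilinear")
  src_lab <- if (!is.null(base_label)) {
    warp_image(base_label, total, mode = "nearest")
  }
  pair <- image_pair(src, base_image, source_label = src_lab,
                     reference_label = base_label)
  structure(c(pair, list(gt_affine = p, gt_tps_field = tps,
                         gt_field = total)),
            class = c("synthetic_pair", "image_pair"))
}

#' Synthesize a neuron-like base texture
#'
#' A Voronoi tessellation of the image into `n_cells` cell bodies (the
#' label image, values exactly 1..n_cells, background-free), rendered as an
#' intensity image with dark membranes along cell boundaries, per-cell gray
#' levels, a little smooth intra-cell shading and Gaussian noise, clipped
#' to \[0, 1\]. A stand-in for serial-section EM texture; deterministic
#' under a fixed seed.
#'
#' @param h,w Image size in pixels.
#' @param n_cells Number of cells (>= 1).
#' @param seed Optional RNG seed.
#' @param noise_sd Gaussian pixel noise std-dev.
#' @return List with `image` (numeric in \[0,1\]) and `label` (integer).
#' @export
synth_texture <- function(h, w, n_cells = 30, seed = NULL,
                          noise_sd = 0.02) {
  if (n_cells < 1) stop("synth_texture: n_cells must be >= 1")
  maybe_seed(seed)
  g <- norm_grid(h, w)
  cx <- stats::runif(n_cells, -1, 1)
  cy <- stats::runif(n_cells, -1, 1)
  d2 <- outer(as.vector(g$x), cx, "-")^2 + outer(as.vector(g$y), cy, "-")^2
  label <- matrix(max.col(-d2, ties.method = "first"), nrow = h)

  gray <- stats::runif(n_cells, 0.45, 0.75)
  img <- matrix(gray[label], nrow = h)
  # multi-octave smoothed noise: EM-like intracellular texture, so image
  # gradients are informative everywhere, not only at membranes
  zf <- zero_field(h, w)
  for (oct in c(6L, 12L, 24L, 48L)) {
    if (oct >= min(h, w)) next
    coarse <- matrix(stats::rnorm(oct * oct), oct, oct)
    img <- img + 0.06 * .warp_bilinear(coarse, field_dx(zf), field_dy(zf))
  }
  # membranes: pixels whose 4-neighbourhood crosses a cell boundary
  memb <- matrix(FALSE, h, w)
  memb[-h, ] <- memb[-h, ] | label[-h, ] != label[-1, ]
  memb[-1, ] <- memb[-1, ] | label[-1, ] != label[-h, ]
  memb[, -w] <- memb[, -w] | label[, -w] != label[, -1]
  memb[, -1] <- memb[, -1] | label[, -1] != label[, -w]
  img[memb] <- stats::runif(sum(memb), 0.03, 0.12)
  img <- img + stats::rnorm(h * w, 0, noise_sd)
  list(image = pmin(pmax(img, 0), 1), label = label)
}

#' Generate a synthetic dataset by repeated deformation
#'
#' Expands a handful of base textures into `n_pairs` deformed pairs (each
#' base is re-deformed with fresh random draws) and assigns
#' train/validation/test tags by pair index under a fixed split seed.
#'
#' @param n_pairs Number of pairs to generate.
#' @param resolution Image side length in pixels.
#' @param n_base Number of distinct base textures to deform (default 1:
#'   serial sections all image the same volume).
#' @param n_cells Cells per base texture.
#' @param spec A [deformation_spec()].
#' @param seed Master RNG seed for the whole dataset.
#' @param split Train/validation/test proportions (sum to 1).
#' @param split_seed Seed for the split assignment.
#' @return An object of class `synthetic_dataset`: list with `pairs` (list
#'   of `synthetic_pair`) and `split` (factor with levels train/val/test).
#' @export
make_dataset <- function(n_pairs, resolution = 128, n_base = 1,
                         n_cells = 30, spec = deformation_spec(),
                         seed = 1, split = c(0.8, 0.1, 0.1),
                         split_seed = 99) {
  stopifnot(abs(sum(split) - 1) < 1e-8)
  set.seed(seed)
  bases <- lapply(seq_len(n_base), function(i) {
    synth_texture(resolution, resolution, n_cells = n_cells, seed = NULL)
  })
  pairs <- lapply(seq_len(n_pairs), function(i) {
    b <- bases[[(i - 1) %% n_base + 1]]
    make_pair(b$image, b$label, spec, seed = NULL)
  })
  set.seed(split_seed)
  tags <- sample(rep(c("train", "val", "test"),
                     times = round_split(n_pairs, split)))
  structure(list(pairs = pairs,
                 split = factor(tags, levels = c("train", "val", "test"))),
            class = "synthetic_dataset")
}

round_split <- function(n, split) {
  counts <- floor(n * split)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  counts
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d pairs (%s)\n", length(x$pairs),
              paste(names(table(x$split)), table(x$split), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
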