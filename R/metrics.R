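#' SSIM configuration
#'
#' Patchwise structural similarity settings. The three stabilizing
#' constants follow the conventional choice `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, `C3 = C2 / 2` for images with dynamic range `L = 1`.
#'
#' @param patch_size Odd window side length in pixels (>= 3). Serial-section
#'   EM evaluation favours the small 3 x 3 window so fine neurite structure
#'   dominates the score.
#' @param C1,C2,C3 Positive stabilizers.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(patch_size = 3, C1 = 0.01^2, C2 = 0.03^2,
                        C3 = C2 / 2) {
  if (patch_size < 3 || patch_size %% 2 == 0) {
    stop("ssim_config: patch_size must be odd and >= 3")
  }
  if (any(c(C1, C2, C3) <= 0)) stop("ssim_config: constants must be > 0")
  structure(list(patch_size = as.integer(patch_size),
                 C1 = C1, C2 = C2, C3 = C3),
            class = "ssim_config")
}

# Window moments over all fully interior patch_size x patch_size windows.
# Unbiased (n-1) variance and covariance, as in the three-factor SSIM with
# mean/std/correlation components.
ssim_moments <- function(i1, i2, k) {
  n <- k * k
  s1 <- .box_sum_valid(i1, k); s2 <- .box_sum_valid(i2, k)
  s11 <- .box_sum_valid(i1 * i1, k)
  s22 <- .box_sum_valid(i2 * i2, k)
  s12 <- .box_sum_valid(i1 * i2, k)
  u1 <- s1 / n; u2 <- s2 / n
  v1 <- pmax((s11 - s1 * u1) / (n - 1), 0)
  v2 <- pmax((s22 - s2 * u2) / (n - 1), 0)
  c12 <- (s12 - s1 * u2) / (n - 1)
  list(u1 = u1, u2 = u2, v1 = v1, v2 = v2, c12 = c12, n = n)
}

ssim_map <- function(m, cfg) {
  sd1 <- sqrt(m$v1); sd2 <- sqrt(m$v2)
  l <- (2 * m$u1 * m$u2 + cfg$C1) / (m$u1^2 + m$u2^2 + cfg$C1)
  co <- (2 * sd1 * sd2 + cfg$C2) / (m$v1 + m$v2 + cfg$C2)
  st <- (m$c12 + cfg$C3) / (sd1 * sd2 + cfg$C3)
  list(map = l * co * st, l = l, co = co, st = st, sd1 = sd1, sd2 = sd2)
}

#' Structural similarity index between two images
#'
#' Mean patchwise SSIM over dense (stride-1) sliding windows. Each window
#' contributes the product of a luminance factor
#' `(2 u1 u2 + C1) / (u1^2 + u2^2 + C1)`, a contrast factor
#' `(2 s1 s2 + C2) / (s1^2 + s2^2 + C2)` and a structure factor
#' `(s12 + C3) / (s1 s2 + C3)`, with window means `u`, unbiased standard
#' deviations `s` and covariance `s12`. Bounded in \[-1, 1\]; equals 1 for
#' identical images.
#'
#' @param i1,i2 Numeric matrices of identical shape with values in \[0, 1\].
#' @param cfg An [ssim_config()].
#' @return Scalar mean SSIM.
#' @export
ssim <- function(i1, i2, cfg = ssim_config()) {
  i1 <- as.matrix(i1); i2 <- as.matrix(i2)
  if (!identical(dim(i1), dim(i2))) stop("ssim: shape mismatch")
  k <- cfg$patch_size
  if (nrow(i1) < k || ncol(i1) < k) stop("ssim: image smaller than patch")
  m <- ssim_moments(i1, i2, k)
  mean(ssim_map(m, cfg)$map)
}

# Mean SSIM and its gradient with respect to the first image; the second
# image is treated as the fixed reference. Used by the SSIM training loss.
ssim_with_grad <- function(i1, i2, cfg = ssim_config()) {
  k <- cfg$patch_size
  m <- ssim_moments(i1, i2, k)
  sm <- ssim_map(m, cfg)
  M <- length(sm$map)
  value <- sum(sm$map) / M

  eps <- 1e-12
  den_l <- m$u1^2 + m$u2^2 + cfg$C1
  dl_du1 <- (2 * m$u2 * den_l - (2 * m$u1 * m$u2 + cfg$C1) * 2 * m$u1) / den_l^2
  den_c <- m$v1 + m$v2 + cfg$C2
  dco_dv1 <- ((sm$sd2 / pmax(sm$sd1, eps)) * den_c -
              (2 * sm$sd1 * sm$sd2 + cfg$C2)) / den_c^2
  den_s <- sm$sd1 * sm$sd2 + cfg$C3
  dst_dv1 <- -(m$c12 + cfg$C3) * sm$sd2 / (2 * pmax(sm$sd1, eps)) / den_s^2
  dst_dc12 <- 1 / den_s

  g <- 1 / M # upstream gradient of the mean, per window
  g_u1 <- g * dl_du1 * sm$co * sm$st
  g_v1 <- g * sm$l * (dco_dv1 * sm$st + sm$co * dst_dv1)
  g_c12 <- g * sm$l * sm$co * dst_dc12

  n <- m$n
  g_s1 <- g_u1 / n - g_v1 * 2 * m$u1 / (n - 1) - g_c12 * m$u2 / (n - 1)
  g_s11 <- g_v1 / (n - 1)
  g_s12 <- g_c12 / (n - 1)
  h <- nrow(i1); w <- ncol(i1)
  grad <- .box_sum_scatter(g_s1, k, h, w) +
    2 * i1 * .box_sum_scatter(g_s11, k, h, w) +
    i2 * .box_sum_scatter(g_s12, k, h, w)
  list(value = value, grad = grad)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary masks. Both masks empty
#' is scored as perfect agreement (1).
#'
#' @param a,b Logical (or 0/1) matrices of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: shape mismatch")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Dice evaluation configuration
#'
#' @param n_regions Number of largest reference regions to average over
#'   (by pixel count in the reference label image).
#' @param match How warped regions are matched to reference regions:
#'   `"id"` matches by identical integer label (the natural choice for
#'   co-registered label volumes), `"overlap"` matches each reference
#'   region to the warped label with maximal overlap.
#' @return An object of class `dice_config`.
#' @export
dice_config <- function(n_regions = 50, match = c("id", "overlap")) {
  if (n_regions < 1) stop("dice_config: n_regions must be >= 1")
  structure(list(n_regions = as.integer(n_regions),
                 match = match.arg(match)),
            class = "dice_config")
}

#' Mean Dice over the largest labelled regions
#'
#' Selects the `n_regions` largest nonzero regions of the reference label
#' image (ties broken by label id), computes the Dice overlap of each
#' against the warped label image, and returns their mean. Regions absent
#' from the warped labels score 0. Fewer regions than requested are
#' averaged as-is.
#'
#' @param warped_label,gt_label Non-negative integer matrices of identical
#'   shape; `gt_label` is the reference.
#' @param cfg A [dice_config()].
#' @return List with `mean_dice`, and `per_region` (named numeric, one
#'   entry per selected reference label).
#' @export
mean_dice_over_largest <- function(warped_label, gt_label,
                                   cfg = dice_config()) {
  warped_label <- as.matrix(warped_label); gt_label <- as.matrix(gt_label)
  if (!identical(dim(warped_label), dim(gt_label))) {
    stop("mean_dice_over_largest: shape mismatch")
  }
  counts <- table(gt_label[gt_label > 0])
  if (length(counts) == 0) {
    stop("mean_dice_over_largest: reference has no nonzero labels")
  }
  ids <- as.integer(names(counts))
  ord <- order(-as.integer(counts), ids)
  sel <- ids[ord][seq_len(min(cfg$n_regions, length(ids)))]
  per <- vapply(sel, function(id) {
    ref_mask <- gt_label == id
    if (cfg$match == "id") {
      dice(warped_label == id, ref_mask)
    } else {
      inside <- warped_label[ref_mask]
      inside <- inside[inside > 0]
      if (length(inside) == 0) return(0)
      best <- as.integer(names(which.max(table(inside))))
      dice(warped_label == best, ref_mask)
    }
  }, numeric(1))
  names(per) <- sel
  list(mean_dice = mean(per), per_region = per)
}
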