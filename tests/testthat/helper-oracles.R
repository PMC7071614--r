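# Independent brute-force oracles used to validate the fast implementations.

# per-pixel bilinear gather with border replication, straight from the
# sampling definition
oracle_bilinear_warp <- function(img, field) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      px <- (j - 1) + field[i, j, 1] * (W - 1) / 2
      py <- (i - 1) + field[i, j, 2] * (H - 1) / 2
      px <- min(max(px, 0), W - 1)
      py <- min(max(py, 0), H - 1)
      x0 <- min(floor(px), W - 2); y0 <- min(floor(py), H - 2)
      fx <- px - x0; fy <- py - y0
      out[i, j] <- img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
        img[y0 + 1, x0 + 2] * fx * (1 - fy) +
        img[y0 + 2, x0 + 1] * (1 - fx) * fy +
        img[y0 + 2, x0 + 2] * fx * fy
    }
  }
  out
}

# windowed SSIM directly from per-window means, unbiased sds and covariance
oracle_ssim <- function(i1, i2, k = 3, C1 = 1e-4, C2 = 9e-4, C3 = C2 / 2) {
  H <- nrow(i1); W <- ncol(i1)
  vals <- c()
  for (i in 1:(H - k + 1)) {
    for (j in 1:(W - k + 1)) {
      p1 <- as.vector(i1[i:(i + k - 1), j:(j + k - 1)])
      p2 <- as.vector(i2[i:(i + k - 1), j:(j + k - 1)])
      u1 <- mean(p1); u2 <- mean(p2)
      s1 <- stats::sd(p1); s2 <- stats::sd(p2)
      c12 <- stats::cov(p1, p2)
      vals <- c(vals,
                ((2 * u1 * u2 + C1) / (u1^2 + u2^2 + C1)) *
                  ((2 * s1 * s2 + C2) / (s1^2 + s2^2 + C2)) *
                  ((c12 + C3) / (s1 * s2 + C3)))
    }
  }
  mean(vals)
}

# smoothness penalty from first principles
oracle_smoothness <- function(f) {
  d1 <- c(); d2 <- c()
  for (ch in 1:2) {
    m <- f[, , ch]
    dr <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    dc <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    d1 <- c(d1, dr, dc)
    d2 <- c(d2, dr[-1, , drop = FALSE] - dr[-nrow(dr), , drop = FALSE],
            dc[, -1, drop = FALSE] - dc[, -ncol(dc), drop = FALSE])
  }
  mean(abs(d1)) + mean(abs(d2))
}

random_field <- function(h, w, sd = 0.05) {
  dense_field(matrix(stats::rnorm(h * w, 0, sd), h, w),
              matrix(stats::rnorm(h * w, 0, sd), h, w))
}

# a small smooth field (low-frequency) for composition tests
smooth_field <- function(h, w, amp = 0.05) {
  g <- norm_grid(h, w)
  dense_field(amp * sin(pi * g$x) * cos(pi * g$y),
              amp * cos(pi * g$x) * sin(pi * g$y))
}
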