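test_that("affine parameter construction and validation", {
  p <- identity_affine()
  expect_s3_class(p, "affine_params")
  expect_equal(unname(unclass(p)), c(1, 0, 0, 1, 0, 0))
  expect_equal(affine_det(p), 1)
  expect_error(affine_params(a11 = NaN), "non-finite")
  expect_error(as_affine_params(1:5), "6 values")
  expect_equal(affine_det(affine_params(a11 = 2, a22 = 3)), 6)
})

test_that("affine_to_field matches the pointwise definition", {
  # identity expands to the zero field
  expect_true(all(affine_to_field(identity_affine(), 8, 8) == 0))
  # pure translation is a constant field
  f <- affine_to_field(affine_params(tx = 0.5), 6, 9)
  expect_equal(max(abs(f[, , 1] - 0.5)), 0)
  expect_equal(max(abs(f[, , 2])), 0)
  # scale-by-2 on a 3x3 grid: d(x) = A x + t - x = x
  f2 <- affine_to_field(affine_params(a11 = 2, a22 = 2), 3, 3)
  g <- norm_grid(3, 3)
  expect_equal(f2[, , 1], g$x)
  expect_equal(f2[, , 2], g$y)
  # general parameters against a per-pixel oracle
  set.seed(11)
  p <- as_affine_params(c(1, 0, 0, 1, 0, 0) + rnorm(6, 0, 0.1))
  f3 <- affine_to_field(p, 5, 7)
  for (i in 1:5) {
    for (j in 1:7) {
      x <- -1 + 2 * (j - 1) / 6; y <- -1 + 2 * (i - 1) / 4
      expect_equal(unname(f3[i, j, 1]), p[["a11"]] * x + p[["a12"]] * y +
                     p[["tx"]] - x, tolerance = 1e-12)
      expect_equal(unname(f3[i, j, 2]), p[["a21"]] * x + p[["a22"]] * y +
                     p[["ty"]] - y, tolerance = 1e-12)
    }
  }
  expect_error(affine_to_field(p, 1, 8), "2 x 2")
})

test_that("warping with the zero field is the identity", {
  set.seed(1)
  img <- matrix(runif(15 * 11), 15, 11)
  expect_identical(warp_image(img, zero_field(15, 11)), img)
  expect_identical(warp_image(img, zero_field(15, 11), mode = "nearest"),
                   img)
})

test_that("bilinear warp agrees with the brute-force oracle", {
  set.seed(2)
  worst <- 0
  for (k in 1:25) {
    img <- matrix(runif(16 * 16), 16, 16)
    f <- random_field(16, 16, sd = 0.1)
    worst <- max(worst, max(abs(warp_image(img, f) -
                                  oracle_bilinear_warp(img, unclass(f)))))
  }
  expect_lt(worst, 1e-6)
})

test_that("constant one-pixel shift moves columns, replicating the border", {
  ramp <- matrix(rep(1:4, each = 4) / 4, 4, 4)
  one_px <- 2 / (4 - 1) # one pixel in normalized units
  shifted <- warp_image(ramp, dense_field(matrix(one_px, 4, 4),
                                          matrix(0, 4, 4)))
  expect_equal(shifted[, 1:3], ramp[, 2:4])
  expect_equal(shifted[, 4], ramp[, 4]) # border replication
})

test_that("nearest warp of a label image never invents labels", {
  set.seed(3)
  lab <- matrix(sample(c(1L, 5L, 9L), 64, replace = TRUE), 8, 8)
  for (k in 1:10) {
    f <- random_field(8, 8, sd = 0.2)
    out <- warp_image(lab, f, mode = "nearest")
    expect_true(all(out %in% unique(as.vector(lab))))
  }
})

test_that("warp rejects shape mismatches", {
  expect_error(warp_image(matrix(0, 4, 4), zero_field(5, 5)), "shape")
})

test_that("compose_fields has the identity element and adds translations", {
  set.seed(4)
  f <- random_field(12, 12, 0.05)
  z <- zero_field(12, 12)
  expect_equal(compose_fields(z, f), f, tolerance = 1e-12)
  expect_equal(compose_fields(f, z), f, tolerance = 1e-12)
  a <- dense_field(matrix(0.1, 16, 16), matrix(0, 16, 16))
  b <- dense_field(matrix(0, 16, 16), matrix(0.2, 16, 16))
  comp <- compose_fields(a, b)
  expect_equal(max(abs(comp[, , 1] - 0.1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(comp[, , 2] - 0.2)), 0, tolerance = 1e-9)
  expect_error(compose_fields(zero_field(4, 4), zero_field(5, 5)), "shape")
})

test_that("composed field reproduces sequential warps on smooth fields", {
  g16 <- norm_grid(16, 16)
  # band-limited image so interpolation error reflects the fields, not
  # pixel-scale image roughness
  img <- 0.5 + 0.25 * sin(2 * pi * g16$x) + 0.2 * cos(2 * pi * g16$y)
  outer <- smooth_field(16, 16, 0.04)
  inner <- smooth_field(16, 16, 0.03)
  sequential <- warp_image(warp_image(img, inner), outer)
  oneshot <- warp_image(img, compose_fields(outer, inner))
  # interpolation error only; fields are smooth so the gap is small
  expect_lt(max(abs(sequential - oneshot)), 0.02)
})

test_that("compose_fields is associative up to interpolation tolerance", {
  a <- smooth_field(24, 24, 0.03)
  b <- smooth_field(24, 24, 0.02)
  g <- norm_grid(24, 24)
  c_ <- dense_field(0.02 * cos(pi * g$y), 0.02 * sin(pi * g$x))
  left <- compose_fields(compose_fields(a, b), c_)
  right <- compose_fields(a, compose_fields(b, c_))
  expect_lt(max(abs(left - right)), 5e-3)
})

test_that("apply_affine warps like the dense-field route and is
           resolution-free", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(apply_affine(img, identity_affine()), img)
  p <- affine_params(a11 = 1.04, a12 = 0.02, a21 = -0.03, a22 = 0.97,
                     tx = 0.05, ty = -0.02)
  expect_equal(apply_affine(img, p),
               warp_image(img, affine_to_field(p, 32, 32)))
  # one-pixel translation moves a delta image's spike by one pixel
  delta <- matrix(0, 9, 9); delta[5, 4] <- 1
  moved <- apply_affine(delta, affine_params(tx = 2 / 8))
  expect_equal(moved[5, 3], 1)
  expect_equal(sum(moved), 1)
  # normalized coordinates: warping a coordinate ramp gives the same
  # geometric transform at any resolution (interior pixels, exact since
  # the ramp is bilinear)
  for (res in c(16L, 48L)) {
    g <- norm_grid(res, res)
    out <- apply_affine(g$x, affine_params(tx = 0.25))
    interior <- g$x + 0.25 <= 1
    expect_equal(out[interior], (g$x + 0.25)[interior], tolerance = 1e-12)
  }
})

test_that("image_pair validates shapes and labels", {
  a <- matrix(0.5, 8, 8)
  expect_s3_class(image_pair(a, a), "image_pair")
  expect_error(image_pair(a, matrix(0, 4, 4)), "shape")
  expect_error(image_pair(a, a, source_label = matrix(-1L, 8, 8)),
               "non-negative")
  expect_error(image_pair(a, a, source_label = matrix(0.5, 8, 8)),
               "integer")
})

test_that("downsample_image is a block mean", {
  m <- matrix(1:16, 4, 4)
  d <- downsample_image(m, 2)
  expect_equal(d, matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                           mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2, 2))
  expect_error(downsample_image(matrix(0, 5, 5), 2), "divisible")
})
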