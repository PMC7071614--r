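test_that("deformation_spec validates its inputs", {
  expect_s3_class(deformation_spec(), "deformation_spec")
  expect_error(deformation_spec(affine_sigma = -1), ">= 0")
  expect_error(deformation_spec(tps_sigma = 0.1, n_control_points = 2),
               "control points")
  # 2 control points are fine when the TPS part is disabled
  expect_silent(deformation_spec(tps_sigma = 0, n_control_points = 2))
})

test_that("random_affine is an identity-centered normal perturbation", {
  expect_equal(unclass(random_affine(deformation_spec(affine_sigma = 0),
                                     seed = 1)),
               unclass(identity_affine()))
  a <- random_affine(deformation_spec(), seed = 7)
  b <- random_affine(deformation_spec(), seed = 7)
  expect_identical(unclass(a), unclass(b))
  # sampling statistics: each parameter's sample mean within 3 sd / sqrt(n)
  # of its identity value
  sigma <- 0.05; n <- 10000
  set.seed(42)
  draws <- replicate(n, unclass(random_affine(
    deformation_spec(affine_sigma = sigma), seed = NULL)))
  id6 <- c(1, 0, 0, 1, 0, 0)
  for (k in 1:6) {
    expect_lt(abs(mean(draws[k, ]) - id6[k]), 3 * sigma / sqrt(n))
  }
})

test_that("thin-plate-spline fields interpolate their control points", {
  expect_true(all(random_tps_field(deformation_spec(tps_sigma = 0), 16, 16,
                                   seed = 1) == 0))
  f <- random_tps_field(deformation_spec(tps_sigma = 0.05), 129, 129,
                        seed = 3)
  pts <- attr(f, "control_points")
  disp <- attr(f, "displacements")
  # the exact interpolation property, checked through the internal solver
  fit <- dualreg:::tps_solve(pts, disp[, 1])
  at_knots <- dualreg:::tps_eval(fit, pts, matrix(pts[, 1], 1),
                                 matrix(pts[, 2], 1))
  expect_equal(as.vector(at_knots), disp[, 1], tolerance = 1e-8)
  # and through the rendered grid: sample the dense field at each control
  # point (dense grid, so nearest pixel is within interpolation tolerance)
  for (k in seq_len(nrow(pts))) {
    i <- round((pts[k, 2] + 1) / 2 * 128) + 1
    j <- round((pts[k, 1] + 1) / 2 * 128) + 1
    expect_lt(abs(f[i, j, 1] - disp[k, 1]), 5e-3)
    expect_lt(abs(f[i, j, 2] - disp[k, 2]), 5e-3)
  }
})

test_that("TPS fields are smooth and finite across seeded draws", {
  spec <- deformation_spec()
  for (s in 1:20) {
    f <- random_tps_field(spec, 32, 32, seed = s)
    expect_true(all(is.finite(f)))
    # discrete gradient magnitude bounded: displacements vary gently
    # relative to the +-1 grid extent
    expect_lt(max(abs(diff(f[, , 1]))), 0.2)
    expect_lt(max(abs(diff(f[, , 2]))), 0.2)
  }
})

test_that("make_pair stores a ground truth that reproduces the source", {
  tex <- synth_texture(48, 48, n_cells = 8, seed = 9)
  # all-zero deformation: source equals reference exactly
  p0 <- make_pair(tex$image, tex$label,
                  deformation_spec(affine_sigma = 0, tps_sigma = 0),
                  seed = 1)
  expect_equal(p0$source, p0$reference)
  expect_equal(p0$source_label, p0$reference_label)
  # generic deformation: warping the reference by the stored total field
  # reproduces the source (by construction, asserted)
  p <- make_pair(tex$image, tex$label, deformation_spec(), seed = 2)
  expect_lt(max(abs(warp_image(p$reference, p$gt_field) - p$source)), 1e-12)
  expect_identical(warp_image(p$reference_label, p$gt_field,
                              mode = "nearest"), p$source_label)
  # nontrivial nonlinear deformation misaligns the labels
  d <- mean_dice_over_largest(p$source_label, p$reference_label)$mean_dice
  expect_lt(d, 1)
})

test_that("synthetic textures are deterministic label tessellations", {
  one <- synth_texture(24, 24, n_cells = 1, seed = 5)
  expect_true(all(one$label == 1L))
  tex <- synth_texture(32, 32, n_cells = 7, seed = 5)
  expect_setequal(unique(as.vector(tex$label)), 1:7)
  expect_true(all(tex$image >= 0 & tex$image <= 1))
  tex2 <- synth_texture(32, 32, n_cells = 7, seed = 5)
  expect_identical(tex, tex2)
  expect_error(synth_texture(16, 16, n_cells = 0), "n_cells")
})

test_that("make_dataset expands bases with a reproducible split", {
  ds <- make_dataset(10, resolution = 32, n_base = 2, n_cells = 6,
                     spec = deformation_spec(), seed = 4)
  expect_length(ds$pairs, 10)
  expect_equal(as.vector(table(ds$split)), c(8, 1, 1))
  ds2 <- make_dataset(10, resolution = 32, n_base = 2, n_cells = 6,
                      spec = deformation_spec(), seed = 4)
  expect_identical(ds$pairs[[3]]$source, ds2$pairs[[3]]$source)
  expect_identical(ds$split, ds2$split)
  # every pair round-trips through its stored ground truth
  for (p in ds$pairs[1:3]) {
    expect_lt(max(abs(warp_image(p$reference, p$gt_field) - p$source)),
              1e-12)
  }
})
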