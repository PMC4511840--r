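test_that("voxelize tiles a section with partial-edge flags", {
  t1 <- voxelize(256, 256, 1, 64)
  expect_equal(nrow(t1), 16)
  expect_false(any(t1$partial))

  t2 <- voxelize(250, 250, 1, 64)
  expect_equal(nrow(t2), 16)
  expect_true(all(t2$partial[t2$i == 3 | t2$j == 3]))
  expect_false(any(t2$partial[t2$i < 3 & t2$j < 3]))

  # 340 um voxels on 1.3 um pixels: 262 px tiles
  t3 <- voxelize(524, 524, 1.3, 340)
  expect_equal(t3$row1[1] - t3$row0[1] + 1, 262)
})

test_that("staining intensity is one minus the mean gray level", {
  expect_equal(staining_intensity(matrix(1, 4, 4)), 0)
  expect_equal(staining_intensity(matrix(0, 4, 4)), 1)
  expect_equal(staining_intensity(c(rep(0, 8), rep(1, 8))), 0.5)
  # valid mask restricts the mean
  expect_equal(staining_intensity(c(0, 1, 1, 1), c(TRUE, FALSE, FALSE, FALSE)),
               1)
  expect_true(is.na(staining_intensity(c(0.5), valid = FALSE)))
})

test_that("orientation histograms bin, normalize and wrap correctly", {
  h <- orientation_histogram(rep(45.2, 10))
  expect_equal(h[46], 1)
  expect_equal(sum(h), 1)

  h <- orientation_histogram(c(10.5, 170.5))
  expect_equal(h[11], 0.5)
  expect_equal(h[171], 0.5)

  # uniform orientations approach the flat histogram
  set.seed(3)
  h <- orientation_histogram(runif(2e5, 0, 180))
  expect_lt(max(abs(h - 1 / 180)), 1 / 180)

  # undefined orientations only -> NULL (voxel discarded)
  expect_null(orientation_histogram(c(NA_real_, NA_real_)))

  # literal divisor option: total tile pixels
  h <- orientation_histogram(c(30.1, NA), divisor = "tile")
  expect_equal(sum(h), 0.5)
})

test_that("histogram smoothing conserves mass, wraps, and has the right FWHM", {
  u <- rep(1 / 180, 180)
  expect_lt(max(abs(smooth_histogram(u) - u)), 1e-12)

  delta <- rep(0, 180)
  delta[46] <- 1  # bin 45
  s <- smooth_histogram(delta, fwhm_deg = 23)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(which.max(s), 46)
  # half-max crossings at 45 +/- 11.5 bins
  half <- max(s) / 2
  above <- which(s >= half)
  expect_equal(length(above), 24, tolerance = 1)

  # wrap: delta at bin 0 leaks symmetrically into bins 1 and 179
  d0 <- rep(0, 180)
  d0[1] <- 1
  s0 <- smooth_histogram(d0)
  expect_equal(s0[2], s0[180], tolerance = 1e-12)

  # direct circular convolution oracle
  set.seed(8)
  h <- runif(180)
  sig <- 23 / (2 * sqrt(2 * log(2)))
  w <- exp(-pmin(0:179, 180 - 0:179)^2 / (2 * sig^2))
  w <- w / sum(w)
  oracle <- vapply(seq_len(180), function(i) {
    sum(h * w[((i - seq_len(180)) %% 180) + 1])
  }, numeric(1))
  expect_lt(max(abs(smooth_histogram(h) - oracle)), 1e-12)
})

test_that("axial von Mises density peaks at theta, wraps, and has uniform limit", {
  f <- axial_von_mises_pdf(0:179, 60, 10)
  expect_equal(which.max(f), 61)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # axial symmetry about theta = 0: f(1) = f(179)
  f0 <- axial_von_mises_pdf(c(1, 179), 0, 5)
  expect_equal(f0[1], f0[2], tolerance = 1e-12)
  # kappa = 0: uniform
  expect_lt(max(abs(axial_von_mises_pdf(0:179, 33, 0) - 1 / 180)), 1e-15)
  expect_error(axial_von_mises_pdf(0, 0, -1), "kappa")
})

test_that("greedy mixture fitting recovers one and two components", {
  h1 <- axial_von_mises_pdf(0:179, 60, 10)
  fit <- fit_von_mises_mixture(h1)
  expect_lte(axis_angle_diff(fit$theta[1], 60), 1)
  expect_lt(abs(fit$kappa[1] - 10) / 10, 0.15)
  expect_true(all(diff(fit$amplitude) <= 1e-12))

  h2 <- 0.5 * axial_von_mises_pdf(0:179, 30, 15) +
    0.5 * axial_von_mises_pdf(0:179, 120, 15)
  fit2 <- fit_von_mises_mixture(h2)
  got <- sort(fit2$theta[1:2])
  expect_lte(axis_angle_diff(got[1], 30), 2)
  expect_lte(axis_angle_diff(got[2], 120), 2)
  expect_lt(abs(fit2$kappa[1] - 15) / 15, 0.15)
  expect_lt(abs(fit2$kappa[2] - 15) / 15, 0.15)

  # reconstruction explains >= 95% of squared mass
  recon <- Reduce(`+`, lapply(seq_len(nrow(fit2)), function(k) {
    f <- axial_von_mises_pdf(0:179, fit2$theta[k], fit2$kappa[k])
    fit2$amplitude[k] * f / axial_von_mises_pdf(fit2$theta[k], fit2$theta[k],
                                                fit2$kappa[k])
  }))
  expect_gt(1 - sum((h2 - recon)^2) / sum(h2^2), 0.95)
})

test_that("flat and empty histograms hit the degenerate contracts", {
  fit <- fit_von_mises_mixture(rep(1 / 180, 180))
  expect_equal(fit$kappa[1], 0.01, tolerance = 1e-3)
  # fitted flat component stays near the uniform level in its window
  expect_equal(fit$amplitude[1], 1 / 180, tolerance = 1e-6)

  empty <- fit_von_mises_mixture(rep(0, 180))
  expect_equal(nrow(empty), 0)
})

test_that("fitted centers shift with a global orientation shift", {
  base <- 0.6 * axial_von_mises_pdf(0:179, 40, 12) +
    0.4 * axial_von_mises_pdf(0:179, 100, 8)
  f0 <- fit_von_mises_mixture(base)
  for (delta in c(17, 90)) {
    shifted <- 0.6 * axial_von_mises_pdf(0:179, (40 + delta) %% 180, 12) +
      0.4 * axial_von_mises_pdf(0:179, (100 + delta) %% 180, 8)
    fs <- fit_von_mises_mixture(shifted)
    expect_lte(max(axis_angle_diff(fs$theta[1:2],
                                   (f0$theta[1:2] + delta) %% 180)), 1)
  }
})

test_that("component width interpolates between 0 and 1", {
  expect_equal(component_width(5, 5), 0)
  expect_equal(component_width(0, 5), 1)
  expect_equal(component_width(2.5, 5), 0.5)
  expect_error(component_width(6, 5), "exceeds")
})

test_that("section_fods discards damaged and unstained voxels with a tally", {
  set.seed(21)
  img <- matrix(runif(128 * 128, 0, 0.6), 128, 128)
  mask <- matrix(TRUE, 128, 128)
  mask[1:32, 1:32] <- FALSE       # one fully damaged tile
  img[1:32, 33:64] <- 1           # one unstained tile
  fods <- section_fods(img, mask, pixel_size_um = 2, voxel_size_um = 64)
  excl <- attr(fods, "exclusions")
  expect_equal(excl$n_removed[excl$stage == "damage"], 1)
  expect_equal(excl$n_removed[excl$stage == "unstained"], 1)
  expect_equal(nrow(fods), 14)
  expect_true(all(fods$stain > 0.02))
})

test_that("widths use the analysis-set kappa maximum", {
  fods <- tibble::tibble(kappa1 = c(2, 4), kappa2 = c(1, NA),
                         kappa3 = c(NA_real_, NA_real_))
  out <- add_component_widths(fods)
  expect_equal(attr(out, "kappa_max"), 4)
  expect_equal(out$width1, c(0.5, 0))
  expect_equal(out$width2, c(0.75, NA))
})
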