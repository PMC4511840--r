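test_that("axis-angle difference matches its formula and is a metric", {
  expect_equal(axis_angle_diff(10, 170), 20)
  expect_equal(axis_angle_diff(0, 90), 90)
  xs <- seq(0, 179.5, by = 0.5)
  expect_true(all(axis_angle_diff(xs, xs) == 0))
  expect_warning(axis_angle_diff(185, 5), "wrapped")
  expect_equal(suppressWarnings(axis_angle_diff(185, 5)), 0)

  # metric axioms on the exhaustive 1-degree grid
  grid <- 0:179
  D <- outer(grid, grid, axis_angle_diff)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[upper.tri(D)] > 0))
  for (b in seq_along(grid)) {
    # d(a, c) <= d(a, b) + d(b, c) for all a, c at this b
    expect_true(all(D <= outer(D[, b], D[b, ], `+`) + 1e-12))
  }
})

test_that("the axial mean behaves symmetrically and flags orthogonal ties", {
  expect_equal(mean_axis(10, 30), 20)
  expect_equal(mean_axis(170, 10), 0)
  expect_true(is.na(mean_axis(0, 90)))
  expect_true(is.na(mean_axis(45, 135)))
  # weights pull the mean toward the heavier axis
  expect_lt(axis_angle_diff(mean_axis(0, 60, 3, 1), 0),
            axis_angle_diff(mean_axis(0, 60, 1, 1), 0))
  expect_error(mean_axis(10, 20, 0, 0), "zero")
})

test_that("crossing-fiber averaging is bounded by 45 degrees on the grid", {
  dmax <- 0
  for (a in 0:179) {
    b <- (a + 1:89) %% 180  # separations 1..89; 90 is the undefined tie
    m <- mean_axis(rep(a, 89), b)
    dmax <- max(dmax, axis_angle_diff(m, rep(a, 89)))
  }
  expect_lte(dmax, 45)
  expect_equal(dmax, 44.5)  # attained at the 89-degree separation
  # approaching the orthogonal tie at half-degree resolution tends to 45
  expect_equal(axis_angle_diff(mean_axis(0, 89.5), 0), 44.75)
})

test_that("difference summaries match a brute-force groupby oracle", {
  tbl <- random_voxel_table()

  # truncated mean drops, then averages
  expect_equal(summarize_differences(
    data.frame(diff = c(10, 60), tissue = "WM"), by = "tissue",
    truncation_deg = 50)$mean, 10)

  # constant group: SE 0, mean = median
  const <- data.frame(diff = rep(12, 5), tissue = "WM")
  s <- summarize_differences(const, by = "tissue")
  expect_equal(s$se, 0)
  expect_equal(s$mean, s$median)

  # random table vs naive split-loop oracle, tissue x FA bins
  got <- summarize_differences(tbl, by = c("tissue", "fa_bin"),
                               fa_bin_width = 0.2, min_bin_n = 10)
  key <- paste(tbl$tissue, floor(tbl$fa / 0.2) * 0.2)
  for (r in seq_len(nrow(got))) {
    g <- tbl$diff[key == paste(got$tissue[r], got$fa_bin[r])]
    expect_equal(got$n[r], length(g))
    expect_equal(got$mean[r], mean(g), tolerance = 1e-12)
    expect_equal(got$median[r], median(g), tolerance = 1e-12)
    expect_equal(got$ci95[r], 1.96 * sd(g) / sqrt(length(g)),
                 tolerance = 1e-12)
    expect_equal(got$suppressed[r], length(g) < 10)
  }
})

test_that("GPD fitting recovers parameters and rates its own fit highly", {
  set.seed(42)
  x <- rgpd(50000, shape = 0.3, scale = 8)
  x <- x[x <= 90]
  f <- fit_gpd(x, upper = 90)
  expect_lt(abs(f$shape - 0.3), 0.05)
  expect_lt(abs(f$scale - 8), 0.5)
  expect_gt(f$r_squared, 0.99)

  # self-fit: R^2 against its own binned density
  set.seed(43)
  y <- rgpd(200000, 0.2, 10)
  expect_gt(fit_gpd(y)$r_squared, 0.999)

  # uniform samples are a visibly worse fit than the Pareto-like case
  set.seed(44)
  u <- runif(20000, 0, 90)
  expect_lt(fit_gpd(u, upper = 90)$r_squared, fit_gpd(y)$r_squared)

  expect_error(fit_gpd(rep(5, 200)), "degenerate")
  expect_error(fit_gpd(runif(50)), "100")

  td <- tidy(f)
  expect_equal(td$estimate[td$term == "shape"], f$shape)
  gl <- glance(f)
  expect_equal(gl$nobs, f$n)
})

test_that("sectionwise correlations equal the weighted brute-force oracle", {
  vars <- c("diff", "fa", "md", "stain", "ampl1")
  tbl <- random_voxel_table(n_sections = 5, n_per = 40)

  got <- sectionwise_correlations(tbl, vars)$correlation
  # naive loop oracle
  num <- den <- matrix(0, length(vars), length(vars))
  for (sid in unique(tbl$section_id)) {
    sec <- tbl[tbl$section_id == sid, vars]
    num <- num + nrow(sec) * cor(sec)
    den <- den + nrow(sec)
  }
  oracle <- num / den
  expect_lt(max(abs(got - oracle)), 1e-12)
  expect_true(isSymmetric(unname(got)))
  expect_true(all(diag(got) == 1))

  # single section: plain Pearson matrix
  one <- tbl[tbl$section_id == 0, ]
  expect_lt(max(abs(sectionwise_correlations(one, vars)$correlation -
                      cor(one[, vars]))), 1e-12)

  # two equal-sized sections: arithmetic mean of the two matrices
  two <- tbl[tbl$section_id %in% c(0, 1), ]
  m0 <- cor(tbl[tbl$section_id == 0, vars])
  m1 <- cor(tbl[tbl$section_id == 1, vars])
  expect_lt(max(abs(sectionwise_correlations(two, vars)$correlation -
                      (m0 + m1) / 2)), 1e-12)

  # constant variable in one section: that section skipped for its pairs
  tbl2 <- tbl
  tbl2$stain[tbl2$section_id == 2] <- 0.5
  got2 <- sectionwise_correlations(tbl2, vars)
  expect_equal(got2$n_sections_used["stain", "fa"], 4L)
  expect_equal(got2$n_sections_used["diff", "fa"], 5L)
})

test_that("regression R2 is exact, null-calibrated, and oracle-identical", {
  tbl <- random_voxel_table(n_sections = 5, n_per = 60)
  preds <- c("stain", "ampl1", "ampl2", "ampl3", "width1", "width2", "width3")

  # exact linear combination: R^2 = 1
  tbl$fa <- 0.2 + 0.5 * tbl$stain - 0.3 * tbl$ampl1 + 0.1 * tbl$width2
  expect_equal(regression_r2(tbl, "fa", preds)$r_squared, 1,
               tolerance = 1e-10)

  # independent noise target: R^2 near zero at large n
  set.seed(31)
  big <- random_voxel_table(n_sections = 1, n_per = 10000, seed = 32)
  big$fa <- rnorm(10000)
  expect_lt(regression_r2(big, "fa", preds)$r_squared, 0.05)

  # weighted combination matches the brute-force oracle
  tbl <- random_voxel_table(n_sections = 5, n_per = 60, seed = 55)
  got <- regression_r2(tbl, "md", preds)
  num <- den <- 0
  for (sid in unique(tbl$section_id)) {
    sec <- tbl[tbl$section_id == sid, ]
    fit <- lm(reformulate(preds, "md"), data = sec)
    r2 <- summary(fit)$r.squared
    num <- num + nrow(sec) * r2
    den <- den + nrow(sec)
  }
  expect_equal(got$r_squared, num / den, tolerance = 1e-12)

  # rank-deficient section is skipped and tallied
  tbl3 <- tbl
  tbl3$ampl2[tbl3$section_id == 1] <- tbl3$ampl1[tbl3$section_id == 1]
  got3 <- regression_r2(tbl3, "md", c("ampl1", "ampl2"))
  expect_equal(got3$n_skipped, 1L)
})

test_that("voxel-table assembly applies the filters in order with a ledger", {
  fods <- tibble::tibble(
    section_id = 0L, i = 0:7, j = 0L,
    stain = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    valid_frac = c(1, 1, 0.01, 1, 1, 1, 1, 1),
    phi_st = c(10, 20, 30, 40, 50, 60, 70, 80)
  )
  tensors <- tibble::tibble(
    slice = 0L, i = 0:7, j = 0L, tissue = "WM",
    fa = 0.5, md = 7e-4, rd = 3e-4,
    phi_dt = c(10, 25, 30, 40, 50, 60, 70, 80),
    oop_deg = c(0, 10, 20, 30, 40, 45, 50, 60),
    proj_len = 1
  )
  rec <- build_voxel_table(fods, tensors)
  excl <- attr(rec, "exclusions")
  expect_equal(excl$stage, c("damage", "unstained", "out_of_plane"))
  expect_equal(excl$n_removed, c(1L, 0L, 2L))
  # voxel i=2 lost to damage; 50 and 60 degree out-of-plane rows dropped;
  # the 45-degree row retained (inclusive threshold)
  expect_equal(nrow(rec), 5)
  expect_true(45 %in% rec$oop_deg)
  expect_equal(rec$diff[rec$i == 1], 5)

  # phantom-style no-exclusion case: all ledger fractions zero
  clean_f <- dplyr::mutate(fods[1:4, ], valid_frac = 1)
  clean_t <- dplyr::mutate(tensors[1:4, ], oop_deg = 0)
  excl0 <- attr(build_voxel_table(clean_f, clean_t), "exclusions")
  expect_equal(excl0$fraction, c(0, 0, 0))

  # known 25% damaged-voxel fraction shows up in the damage stage
  dmg <- dplyr::mutate(fods, valid_frac = c(0.01, 0.01, 1, 1, 1, 1, 1, 1))
  excl1 <- attr(build_voxel_table(dmg, tensors), "exclusions")
  expect_equal(excl1$fraction[1], 0.25)

  expect_error(build_voxel_table(fods[0, ], tensors), "empty")
})

test_that("report pipeline summarizes a synthetic table end to end", {
  tbl <- random_voxel_table(n_sections = 4, n_per = 200, seed = 77)
  tbl$diff <- rgpd(800, 0.2, 9)
  tbl$diff <- pmin(tbl$diff, 90)
  rep <- validation_report(tbl, min_bin_n = 20)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$overall$n, 800)
  expect_true(all(c("WM", "GM") %in% rep$by_tissue$tissue))
  expect_true(all(rep$truncated$mean <= 50))
  expect_output(print(rep), "validation report")
})
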