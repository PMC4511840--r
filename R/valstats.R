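#' Join histology and DTI voxel tables into the analysis sample
#'
#' Inner-joins the per-voxel FOD table (histology) and the tensor table
#' (DTI) on voxel index, then applies the inclusion filters in the fixed
#' order: damage (valid-pixel fraction), stained material (staining
#' intensity floor), and out-of-plane angle.  The first two filters are
#' already applied inside [section_fods()]; their tallies are carried
#' through when available.  The exclusion ledger (attribute
#' `"exclusions"`) reports counts and fractions removed at each stage, in
#' order.
#'
#' @param fods Histology voxel table (rows = voxels with fitted FODs),
#'   with columns `section_id`, `i`, `j`, `stain`, `valid_frac`, `phi_st`,
#'   amplitude/width columns.
#' @param tensors DTI voxel table from [fit_dti_volume()].
#' @param assignment Tibble pairing `section` with `slice` (from
#'   [assign_sections()]); default: identity on `section_id`.
#' @param max_oop_deg Out-of-plane threshold, degrees (default 45).
#' @return Tibble of joined `VoxelRecord` rows with `diff =
#'   axis_angle_diff(phi_dt, phi_st)`, plus the exclusion ledger attribute.
#' @export
build_voxel_table <- function(fods, tensors, assignment = NULL,
                              max_oop_deg = 45) {
  if (nrow(fods) == 0 || nrow(tensors) == 0) {
    stop("build_voxel_table(): empty input table")
  }
  if (is.null(assignment)) {
    assignment <- tibble::tibble(section = unique(fods$section_id),
                                 slice = unique(fods$section_id))
  }
  fods <- dplyr::inner_join(fods, assignment,
                            by = c(section_id = "section"))
  joined <- dplyr::inner_join(
    fods, tensors,
    by = c("slice", "i", "j"),
    suffix = c("_hist", "_dti")
  )
  if (nrow(joined) == 0) {
    stop("build_voxel_table(): join produced no rows; ",
         "check voxel grids and section-slice assignment")
  }
  n0 <- nrow(joined)
  # stages, in order (damage and stain may already be pre-filtered)
  ok_damage <- joined$valid_frac >= 0.05
  joined <- joined[ok_damage, ]
  n1 <- nrow(joined)
  ok_stain <- !is.na(joined$stain) & joined$stain > 0
  joined <- joined[ok_stain, ]
  n2 <- nrow(joined)
  joined <- dplyr::filter(joined,
                          !is.na(.data$oop_deg),
                          .data$oop_deg <= max_oop_deg,
                          !is.na(.data$phi_dt), !is.na(.data$phi_st))
  n3 <- nrow(joined)
  out <- dplyr::mutate(joined,
                       diff = axis_angle_diff(.data$phi_dt, .data$phi_st))
  attr(out, "exclusions") <- tibble::tibble(
    stage = c("damage", "unstained", "out_of_plane"),
    n_removed = c(n0 - n1, n1 - n2, n2 - n3),
    n_total = c(n0, n1, n2),
    fraction = c(n0 - n1, n1 - n2, n2 - n3) / c(n0, n1, n2)
  )
  out
}

#' Summarize angular differences by tissue and/or FA bin
#'
#' Per group: voxel count, arithmetic mean, median, standard error and the
#' 1.96 * SE half-width of the confidence interval.  Optional truncation
#' first drops records with `diff` above the threshold (the paper-style
#' truncated mean); optional FA binning groups by intervals of width
#' `fa_bin_width`, and bins with fewer than `min_bin_n` voxels are flagged
#' `suppressed`.
#'
#' @param records Voxel table with `diff`, `tissue`, `fa` columns.
#' @param by Character vector of grouping variables: any of `"tissue"`,
#'   `"fa_bin"`; empty for an overall summary.
#' @param fa_bin_width FA bin width (default 0.05).
#' @param min_bin_n Minimum voxels per displayed bin (default 100).
#' @param truncation_deg Drop records with `diff` above this before
#'   summarizing; `NULL` for none.
#' @return Tibble with one row per group: grouping columns, `n`, `mean`,
#'   `median`, `se`, `ci95`, `suppressed`.
#' @export
summarize_differences <- function(records, by = "tissue",
                                  fa_bin_width = 0.05, min_bin_n = 100,
                                  truncation_deg = NULL) {
  stopifnot(nrow(records) > 0)
  if (!is.null(truncation_deg)) {
    records <- dplyr::filter(records, .data$diff <= truncation_deg)
  }
  if ("fa_bin" %in% by) {
    records <- dplyr::mutate(
      records,
      fa_bin = floor(.data$fa / fa_bin_width) * fa_bin_width
    )
  }
  grouped <- dplyr::group_by(records,
                             dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean = mean(.data$diff),
    median = stats::median(.data$diff),
    se = stats::sd(.data$diff) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  dplyr::mutate(out,
                se = ifelse(.data$n == 1, 0, .data$se),
                ci95 = 1.96 * .data$se,
                suppressed = .data$n < min_bin_n)
}

#' Fit a generalized Pareto distribution to angular differences
#'
#' Maximum-likelihood fit of the GPD with location pinned to 0 (density
#' `(1/scale) * (1 + shape * x / scale)^(-1/shape - 1)`, exponential in the
#' `shape -> 0` limit).  The quality of fit is summarized as `R^2 = 1 -
#' SSres/SStot` between the fitted per-bin probability mass (CDF
#' differences over 1-degree bins) and the empirical normalized histogram.
#'
#' @param diffs Numeric vector of angular differences in `[0, 90]`,
#'   `n >= 100`.
#' @param bin_width Histogram bin width in degrees for the R^2 (default 1).
#' @param upper Known upper support bound of the data.  The default `Inf`
#'   is the plain GPD likelihood; `upper = 90` conditions the likelihood on
#'   the sample lying in `[0, 90]` (axis-angle differences cannot exceed
#'   90), which removes the shape bias a hard truncation otherwise
#'   induces.
#' @return Object of class `gpd_fit`: list with `shape`, `scale`,
#'   `r_squared`, `n`, `loglik`, and the binned observed/fitted masses.
#' @export
fit_gpd <- function(diffs, bin_width = 1, upper = Inf) {
  diffs <- diffs[!is.na(diffs)]
  stopifnot(all(diffs >= 0), all(diffs <= upper))
  if (length(diffs) < 100) stop("fit_gpd(): need at least 100 observations")
  if (stats::sd(diffs) == 0) stop("fit_gpd(): degenerate (constant) sample")
  x <- diffs
  cdf <- function(q, xi, sigma) {
    if (abs(xi) < 1e-9) return(1 - exp(-q / sigma))
    1 - pmax(1 + xi * q / sigma, 0)^(-1 / xi)
  }
  nll <- function(par) {
    xi <- par[1]
    sigma <- exp(par[2])
    base <- if (abs(xi) < 1e-9) {
      length(x) * log(sigma) + sum(x) / sigma
    } else {
      z <- 1 + xi * x / sigma
      if (any(z <= 0)) return(1e10)
      length(x) * log(sigma) + (1 / xi + 1) * sum(log(z))
    }
    if (is.finite(upper)) {
      p_up <- cdf(upper, xi, sigma)
      if (p_up <= 0) return(1e10)
      base <- base + length(x) * log(p_up)
    }
    base
  }
  # moment-based start
  m <- mean(x); v <- stats::var(x)
  xi0 <- 0.5 * (1 - m^2 / v)
  s0 <- 0.5 * m * (m^2 / v + 1)
  opt <- stats::optim(c(xi0, log(max(s0, 1e-6))), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  shape <- opt$par[1]
  scale <- exp(opt$par[2])
  pgpd <- function(q) {
    if (abs(shape) < 1e-9) 1 - exp(-q / scale) else
      1 - pmax(1 + shape * q / scale, 0)^(-1 / shape)
  }
  edges <- seq(0, ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  obs <- graphics::hist(x, breaks = edges, plot = FALSE)$counts / length(x)
  fitted_mass <- diff(pgpd(edges))
  if (is.finite(upper)) fitted_mass <- fitted_mass / pgpd(upper)
  ss_res <- sum((obs - fitted_mass)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  structure(list(shape = shape, scale = scale,
                 r_squared = 1 - ss_res / ss_tot,
                 n = length(x), loglik = -opt$value,
                 bin_edges = edges, observed = obs, fitted = fitted_mass),
            class = "gpd_fit")
}

#' Draw samples from a generalized Pareto distribution (location 0)
#'
#' Inverse-CDF sampling, independent of the likelihood machinery in
#' [fit_gpd()] so the two can cross-check each other.
#'
#' @param n Sample size.
#' @param shape,scale GPD parameters (scale > 0).
#' @return Numeric vector of length `n`.
#' @export
rgpd <- function(n, shape, scale) {
  stopifnot(scale > 0)
  u <- stats::runif(n)
  if (abs(shape) < 1e-12) -scale * log(1 - u) else
    scale / shape * ((1 - u)^(-shape) - 1)
}

#' @export
print.gpd_fit <- function(x, ...) {
  cat("Generalized Pareto fit (location 0)\n")
  cat(sprintf("  shape = %.4f, scale = %.4f\n", x$shape, x$scale))
  cat(sprintf("  R^2 vs %d-bin histogram = %.4f (n = %d)\n",
              length(x$observed), x$r_squared, x$n))
  invisible(x)
}

#' Tidy a GPD fit
#' @param x A `gpd_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @exportS3Method generics::tidy
tidy.gpd_fit <- function(x, ...) {
  tibble::tibble(term = c("shape", "scale"),
                 estimate = c(x$shape, x$scale))
}

#' One-row summary of a GPD fit
#' @inheritParams tidy.gpd_fit
#' @return One-row tibble with `r.squared`, `logLik`, `nobs`.
#' @exportS3Method generics::glance
glance.gpd_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, logLik = x$loglik, nobs = x$n)
}

#' Section-wise voxel-count-weighted Pearson correlation matrix
#'
#' Stain intensity varies between sections for technical reasons, so
#' pooled correlations are unreliable; instead the Pearson correlation
#' matrix is computed per section and combined as the voxel-count-weighted
#' mean `sum_s n_s r_s / sum_s n_s`.  Sections where a variable is constant
#' are skipped for the pairs involving it (per-pair weights).
#'
#' @param records Voxel table with a `section_id` column.
#' @param variables Character vector of numeric column names.
#' @return List with `correlation` (symmetric matrix, unit diagonal),
#'   `n_sections_used` (per-pair matrix), and `n_total`.
#' @export
sectionwise_correlations <- function(records,
                                     variables = c("diff", "fa", "md", "rd",
                                                   "stain", "ampl1", "width1",
                                                   "ampl2")) {
  p <- length(variables)
  num <- matrix(0, p, p, dimnames = list(variables, variables))
  den <- matrix(0, p, p, dimnames = list(variables, variables))
  used <- matrix(0L, p, p, dimnames = list(variables, variables))
  for (sec in split(records, records$section_id)) {
    n_s <- nrow(sec)
    if (n_s < 2) next
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        xa <- sec[[variables[a]]]
        xb <- sec[[variables[b]]]
        cc <- sec[!is.na(xa) & !is.na(xb), ]
        xa <- cc[[variables[a]]]
        xb <- cc[[variables[b]]]
        if (length(xa) < 2 || stats::sd(xa) == 0 || stats::sd(xb) == 0) next
        r <- if (a == b) 1 else stats::cor(xa, xb)
        num[a, b] <- num[a, b] + length(xa) * r
        den[a, b] <- den[a, b] + length(xa)
        used[a, b] <- used[a, b] + 1L
      }
    }
  }
  corr <- num / den
  corr[den == 0] <- NA_real_
  diag(corr) <- ifelse(is.na(diag(corr)), NA_real_, 1)
  list(correlation = corr, n_sections_used = used,
       n_total = nrow(records))
}

#' Section-wise weighted multiple-regression R-squared
#'
#' Per section, ordinary least squares predicting `target` from the
#' histology-based predictors; the per-section R-squared values are
#' combined as the voxel-count-weighted mean.  Sections with too few voxels
#' or a rank-deficient predictor matrix are skipped and tallied.
#'
#' @param records Voxel table with a `section_id` column.
#' @param target Response column name (`"fa"`, `"md"` or `"rd"`).
#' @param predictors Character vector of predictor column names.
#' @return List with `r_squared` (weighted mean), `per_section` tibble, and
#'   `n_skipped`.
#' @export
regression_r2 <- function(records, target = "fa",
                          predictors = c("stain", "ampl1", "ampl2", "ampl3",
                                         "width1", "width2", "width3")) {
  res <- list()
  skipped <- 0L
  for (sec in split(records, records$section_id)) {
    cc <- sec[stats::complete.cases(sec[, c(target, predictors)]), ]
    n_s <- nrow(cc)
    if (n_s <= length(predictors) + 1) {
      skipped <- skipped + 1L
      next
    }
    X <- as.matrix(cc[, predictors])
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      skipped <- skipped + 1L
      next
    }
    fit <- stats::lm.fit(cbind(1, X), cc[[target]])
    y <- cc[[target]]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    res[[length(res) + 1]] <- tibble::tibble(
      section_id = sec$section_id[1], n = n_s, r_squared = r2
    )
  }
  per_section <- dplyr::bind_rows(res)
  if (nrow(per_section) == 0) {
    stop("regression_r2(): no usable section")
  }
  list(
    r_squared = sum(per_section$n * per_section$r_squared) /
      sum(per_section$n),
    per_section = per_section,
    n_skipped = skipped
  )
}

#' Full statistical report for a joined voxel table
#'
#' Runs the complete evaluation battery: per-tissue and overall
#' mean/median angular differences, truncated means, FA-binned difference
#' curves with 1.96 SE confidence half-widths, generalized Pareto fits per
#' tissue, the section-wise weighted correlation matrix, and section-wise
#' weighted regression R-squared for FA, MD and RD.
#'
#' @param records Voxel table from [build_voxel_table()] (with width
#'   columns attached).
#' @param fa_bin_width,min_bin_n,truncation_deg Tuning parameters (defaults
#'   0.05, 100, 50).
#' @param gpd_min_n Minimum per-tissue sample for the Pareto fit.
#' @return List of class `validation_report`.
#' @export
validation_report <- function(records, fa_bin_width = 0.05, min_bin_n = 100,
                              truncation_deg = 50, gpd_min_n = 100) {
  overall <- summarize_differences(records, by = character())
  by_tissue <- summarize_differences(records, by = "tissue")
  truncated <- summarize_differences(records, by = "tissue",
                                     truncation_deg = truncation_deg)
  fa_curves <- summarize_differences(records, by = c("tissue", "fa_bin"),
                                     fa_bin_width = fa_bin_width,
                                     min_bin_n = min_bin_n)
  gpd <- lapply(split(records$diff, records$tissue), function(d) {
    if (length(d) >= gpd_min_n && stats::sd(d) > 0) fit_gpd(d) else NULL
  })
  corr <- sectionwise_correlations(records)
  reg <- lapply(c(fa = "fa", md = "md", rd = "rd"), function(tg) {
    tryCatch(regression_r2(records, target = tg), error = function(e) NULL)
  })
  structure(list(
    overall = overall, by_tissue = by_tissue, truncated = truncated,
    fa_curves = fa_curves, gpd = gpd, correlations = corr,
    regression = reg, n = nrow(records),
    exclusions = attr(records, "exclusions")
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Histology-DTI validation report (N = %d voxels)\n", x$n))
  cat(sprintf("  overall angular difference: mean %.2f deg, median %.2f deg\n",
              x$overall$mean, x$overall$median))
  for (r in seq_len(nrow(x$by_tissue))) {
    cat(sprintf("  %s: mean %.2f, median %.2f (n = %d)\n",
                x$by_tissue$tissue[r], x$by_tissue$mean[r],
                x$by_tissue$median[r], x$by_tissue$n[r]))
  }
  for (tn in names(x$gpd)) {
    if (!is.null(x$gpd[[tn]])) {
      cat(sprintf("  GPD %s: shape %.3f scale %.3f R^2 %.3f\n", tn,
                  x$gpd[[tn]]$shape, x$gpd[[tn]]$scale,
                  x$gpd[[tn]]$r_squared))
    }
  }
  for (tg in names(x$regression)) {
    if (!is.null(x$regression[[tg]])) {
      cat(sprintf("  regression R^2 (%s) = %.3f\n", toupper(tg),
                  x$regression[[tg]]$r_squared))
    }
  }
  invisible(x)
}
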