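#' Build a diffusion gradient scheme object
#'
#' @param bvals Numeric vector of b-values, s/mm^2, one per volume.
#' @param bvecs Numeric matrix `n x 3` of unit gradient directions (rows for
#'   b = 0 volumes are zero).
#' @return A `gradient_scheme` list with `bvals` and `bvecs`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[nz] - 1) > 1e-6)) {
    warning("non-unit gradient directions renormalized")
    bvecs[nz, ] <- bvecs[nz, ] / nrm[nz]
  }
  bvecs[!nz, ] <- 0
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

# design matrix of the log-linear tensor model:
# ln S = ln S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                   + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
tensor_design <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3],
    1
  )
}

#' Fit a diffusion tensor to one voxel's signals by log-linear least squares
#'
#' Ordinary least squares of `ln S` on the six tensor terms plus an
#' intercept (`ln S0`).  Non-positive signals are clamped to the smallest
#' positive observed signal and the voxel flagged.
#'
#' @param signals Numeric vector of measured signals, one per volume.
#' @param scheme A [gradient_scheme()] with at least 7 measurements,
#'   at least one b = 0 and at least 6 distinct directions.
#' @param method `"ols"` (default) or `"wls"`: weighted least squares with
#'   squared fitted signals as weights (one reweighting pass from the OLS
#'   solution), which counteracts the log-transform's noise distortion at
#'   low signal.
#' @return List with `D` (symmetric 3x3, mm^2/s), `S0`, and `clamped`.
#' @export
fit_tensor <- function(signals, scheme, method = c("ols", "wls")) {
  method <- match.arg(method)
  stopifnot(length(signals) == length(scheme$bvals))
  if (length(signals) < 7 || !any(scheme$bvals == 0)) {
    stop("fit_tensor(): need >= 7 measurements including >= 1 b = 0")
  }
  X <- tensor_design(scheme)
  if (qr(X)$rank < 7) {
    stop("fit_tensor(): unsolvable design (fewer than 6 distinct directions)")
  }
  clamped <- FALSE
  if (any(signals <= 0)) {
    pos <- signals[signals > 0]
    if (length(pos) == 0) stop("fit_tensor(): all signals non-positive")
    signals[signals <= 0] <- min(pos)
    clamped <- TRUE
  }
  y <- log(signals)
  beta <- qr.solve(X, y)
  if (method == "wls") {
    w <- exp(X %*% beta)^2  # fitted-signal-squared weights
    beta <- qr.solve(sqrt(as.vector(w)) * X, sqrt(as.vector(w)) * y)
  }
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  list(D = D, S0 = exp(beta[7]), clamped = clamped)
}

#' Scalar maps and eigensystem of a diffusion tensor
#'
#' Standard rotation-invariant measures: mean diffusivity
#' `MD = (l1 + l2 + l3)/3`, radial diffusivity `RD = (l2 + l3)/2`, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))`.
#'
#' @param D Symmetric 3x3 tensor, mm^2/s.
#' @return List with `evals` (decreasing), `evecs` (columns, matching
#'   order), `fa`, `md`, `rd`, and flags `negative_evals` and `degenerate`
#'   (`l1` within 1e-12 of `l2`: principal eigenvector unstable).
#' @export
scalar_maps <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == 3))
  if (max(abs(D - t(D))) > 1e-10) stop("scalar_maps(): D must be symmetric")
  es <- eigen((D + t(D)) / 2, symmetric = TRUE)
  l <- es$values  # decreasing
  md <- mean(l)
  rd <- (l[2] + l[3]) / 2
  ss <- sum(l^2)
  fa <- if (ss == 0) 0 else sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(ss)
  list(evals = l, evecs = es$vectors, fa = fa, md = md, rd = rd,
       negative_evals = any(l < 0),
       degenerate = (l[1] - l[2]) <= 1e-12 * max(abs(l[1]), 1))
}

#' Project a principal eigenvector into the sectioning plane
#'
#' The sectioning plane is the volume's xy-plane, so the projection discards
#' the z-coordinate.  Returns the in-plane axis angle, the out-of-plane
#' angle `asin(|wz|)`, and the projection length `sqrt(wx^2 + wy^2)`.  The
#' eigenvector sign is irrelevant (axial data).  A purely through-plane
#' vector has no defined in-plane axis (`phi_dt = NA`).
#'
#' @param w Unit 3-vector.
#' @return List with `phi_dt` (degrees `[0, 180)` or `NA`), `oop_deg`
#'   (`[0, 90]`), `proj_len` (`[0, 1]`).
#' @export
project_principal <- function(w) {
  stopifnot(length(w) == 3)
  if (abs(sqrt(sum(w^2)) - 1) > 1e-6) {
    stop("project_principal(): w must be a unit vector")
  }
  proj <- sqrt(w[1]^2 + w[2]^2)
  oop <- rad2deg(asin(min(abs(w[3]), 1)))
  phi <- if (proj < 1e-12) NA_real_ else rad2deg(atan2(w[2], w[1])) %% 180
  list(phi_dt = phi, oop_deg = oop, proj_len = proj)
}

#' Filter voxels by out-of-plane angle
#'
#' Retains rows whose principal eigenvector is at most `max_angle` degrees
#' out of the sectioning plane (inclusive, "maximally 45 degrees").  The
#' retained fraction is recorded in the `"exclusions"` attribute.
#'
#' @param voxels Data frame with a numeric `oop_deg` column.
#' @param max_angle Threshold in degrees, default 45.
#' @return Filtered tibble, with exclusion tally attribute.
#' @export
out_of_plane_filter <- function(voxels, max_angle = 45) {
  keep <- !is.na(voxels$oop_deg) & voxels$oop_deg <= max_angle
  out <- voxels[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    stage = "out_of_plane",
    n_removed = sum(!keep), n_total = length(keep),
    fraction = sum(!keep) / length(keep)
  )
  out
}

#' Estimate SNR from b = 0 volumes
#'
#' The ratio of the mean signal within the tissue mask (over all b = 0
#' volumes) to the standard deviation of the signal in a signal-free noise
#' box.  On magnitude MR data the background is Rayleigh-distributed, so
#' the raw ratio overestimates the Gaussian-noise SNR by a factor
#' `1/sqrt(2 - pi/2) ~ 1.53`; `correction = "rayleigh"` divides the box
#' standard deviation by `sqrt(2 - pi/2)` to undo this.  The default is no
#' correction (the conventional corner-ratio estimate).
#'
#' @param b0 Numeric array (3D, or 4D stack of b = 0 volumes).
#' @param tissue_mask Logical/0-1 array matching the volume grid.
#' @param noise_mask Logical/0-1 array marking the signal-free box; must be
#'   disjoint from the tissue.
#' @param correction `"none"` (default) or `"rayleigh"`.
#' @return Scalar SNR estimate (`Inf` for a noiseless volume).
#' @export
estimate_snr <- function(b0, tissue_mask, noise_mask,
                         correction = c("none", "rayleigh")) {
  correction <- match.arg(correction)
  tissue_mask <- as.logical(tissue_mask)
  noise_mask <- as.logical(noise_mask)
  if (!any(tissue_mask) || !any(noise_mask)) {
    stop("estimate_snr(): empty tissue mask or noise box")
  }
  if (any(tissue_mask & noise_mask)) {
    stop("estimate_snr(): noise box overlaps the tissue mask")
  }
  # replicate masks across trailing volume dimension if b0 is a stack
  rep_mask <- function(m) {
    if (length(b0) == length(m)) m else rep(m, length(b0) / length(m))
  }
  sig <- mean(b0[rep_mask(tissue_mask)])
  sd_n <- stats::sd(b0[rep_mask(noise_mask)])
  if (correction == "rayleigh") sd_n <- sd_n / sqrt(2 - pi / 2)
  if (sd_n == 0) return(Inf)
  sig / sd_n
}

#' Fit diffusion tensors to a 4D volume and tabulate voxel results
#'
#' Applies [fit_tensor()], [scalar_maps()] and [project_principal()] to every
#' voxel inside the tissue mask and returns one row per voxel.
#'
#' @param dwi 4D numeric array `x, y, z, volume`.
#' @param scheme A [gradient_scheme()].
#' @param tissue Integer array `x, y, z`: 0 background, 1 GM, 2 WM.
#' @return Tibble with `i`, `j` (0-based in-plane voxel indices: `i` = x,
#'   `j` = y), `slice` (0-based z), `tissue` (`"GM"`/`"WM"`), tensor entries,
#'   `fa`, `md`, `rd`, `phi_dt`, `oop_deg`, `proj_len`, `s0`, `degenerate`.
#' @export
fit_dti_volume <- function(dwi, scheme, tissue) {
  stopifnot(length(dim(dwi)) == 4, identical(dim(dwi)[1:3], dim(tissue)))
  X <- tensor_design(scheme)
  if (qr(X)$rank < 7) stop("fit_dti_volume(): unsolvable design")
  idx <- which(tissue > 0, arr.ind = TRUE)
  # vectorized OLS: solve for all voxels at once
  d4 <- dim(dwi)[4]
  sig <- matrix(0, nrow(idx), d4)
  for (v in seq_len(d4)) {
    sig[, v] <- dwi[cbind(idx, v)]
  }
  smallest_pos <- suppressWarnings(min(sig[sig > 0]))
  sig[sig <= 0] <- smallest_pos
  beta <- t(qr.solve(X, t(log(sig))))  # n_vox x 7
  rows <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    b <- beta[r, ]
    D <- matrix(c(b[1], b[4], b[5], b[4], b[2], b[6], b[5], b[6], b[3]), 3, 3)
    sm <- scalar_maps(D)
    pr <- project_principal(sm$evecs[, 1])
    rows[[r]] <- tibble::tibble(
      i = idx[r, 1] - 1L, j = idx[r, 2] - 1L, slice = idx[r, 3] - 1L,
      tissue = c("GM", "WM")[tissue[idx[r, 1], idx[r, 2], idx[r, 3]]],
      dxx = D[1, 1], dyy = D[2, 2], dzz = D[3, 3],
      dxy = D[1, 2], dxz = D[1, 3], dyz = D[2, 3],
      fa = sm$fa, md = sm$md, rd = sm$rd,
      phi_dt = pr$phi_dt, oop_deg = pr$oop_deg, proj_len = pr$proj_len,
      s0 = exp(b[7]), degenerate = sm$degenerate
    )
  }
  dplyr::bind_rows(rows)
}
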