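#' Partition a section into voxel-sized tiles
#'
#' Splits a pixel grid into non-overlapping square tiles whose side is
#' `round(voxel_size_um / pixel_size_um)` pixels, anchored at the image
#' origin.  Tiles that extend past the image edge are flagged partial.
#'
#' @param n_rows,n_cols Image size in pixels.
#' @param pixel_size_um Pixel edge length, micrometers.
#' @param voxel_size_um Target voxel edge length, micrometers (>= pixel
#'   size).
#' @return Tibble with one row per tile: `i`, `j` (0-based tile indices,
#'   `i` = column/x, `j` = row/y), pixel ranges `row0`, `row1`, `col0`,
#'   `col1` (1-based, inclusive) and `partial`.
#' @export
voxelize <- function(n_rows, n_cols, pixel_size_um, voxel_size_um) {
  stopifnot(voxel_size_um >= pixel_size_um, pixel_size_um > 0)
  side <- round(voxel_size_um / pixel_size_um)
  nj <- ceiling(n_rows / side)
  ni <- ceiling(n_cols / side)
  grid <- tidyr::expand_grid(j = seq_len(nj) - 1L, i = seq_len(ni) - 1L)
  dplyr::mutate(
    grid,
    row0 = .data$j * side + 1L,
    row1 = pmin((.data$j + 1L) * side, n_rows),
    col0 = .data$i * side + 1L,
    col1 = pmin((.data$i + 1L) * side, n_cols),
    partial = (.data$row1 - .data$row0 + 1L < side) |
      (.data$col1 - .data$col0 + 1L < side)
  )[, c("i", "j", "row0", "row1", "col0", "col1", "partial")]
}

#' Staining intensity of a tile
#'
#' Defined as `1 - mean gray level` over valid pixels, so 0 is unstained
#' (white) and 1 fully stained (black).
#'
#' @param pixels Numeric vector or matrix of gray levels in `[0, 1]`.
#' @param valid Logical mask of the same length; default all valid.
#' @return Scalar intensity, or `NA` when no pixel is valid (the voxel is
#'   then discarded upstream as containing no stained material).
#' @export
staining_intensity <- function(pixels, valid = NULL) {
  v <- as.vector(pixels)
  if (!is.null(valid)) v <- v[as.vector(valid)]
  if (length(v) == 0) return(NA_real_)
  1 - mean(v)
}

#' 180-bin orientation histogram of a tile
#'
#' Bin `b` (0..179) counts orientations in `[b, b + 1)` degrees.  The
#' histogram is normalized by a pixel count so that amplitudes are
#' comparable across voxels: by default the count of valid pixels with a
#' defined orientation (`divisor = "defined"`), so that masked-out holes do
#' not deflate amplitudes; `divisor = "tile"` divides by the total tile
#' pixel count instead.
#'
#' @param phi Numeric vector/matrix of axis angles in degrees, `NA` where
#'   undefined.
#' @param valid Optional logical mask.
#' @param divisor `"defined"` (default) or `"tile"`.
#' @param weights Optional non-negative per-pixel weights (e.g. structure
#'   tensor coherence); default unweighted.
#' @return Numeric vector of 180 bin masses (sums to 1 for the default
#'   divisor), or `NULL` when no orientation is defined.
#' @export
orientation_histogram <- function(phi, valid = NULL,
                                  divisor = c("defined", "tile"),
                                  weights = NULL) {
  divisor <- match.arg(divisor)
  phi <- as.vector(phi)
  n_tile <- length(phi)
  keep <- !is.na(phi)
  if (!is.null(valid)) keep <- keep & as.vector(valid)
  w <- if (is.null(weights)) rep(1, n_tile) else as.vector(weights)
  stopifnot(length(w) == n_tile, all(w >= 0, na.rm = TRUE))
  phi <- phi[keep]
  w <- w[keep]
  if (length(phi) == 0 || sum(w) == 0) return(NULL)
  b <- floor(norm_axis_deg(phi)) %% 180
  h <- vapply(0:179, function(k) sum(w[b == k]), numeric(1))
  den <- if (divisor == "defined") sum(w) else n_tile
  h / den
}

#' Circularly smooth an orientation histogram
#'
#' Convolution with a unit-sum Gaussian window specified by its full width at
#' half maximum (default 23 degrees), wrapping at 180 degrees.  Total
#' histogram mass is conserved.
#'
#' @param h Numeric vector of 180 bin masses.
#' @param fwhm_deg Full width at half maximum of the window, degrees (> 0).
#' @return Smoothed histogram, same length and total mass.
#' @export
smooth_histogram <- function(h, fwhm_deg = 23) {
  stopifnot(fwhm_deg > 0)
  n <- length(h)
  sigma <- fwhm_deg / (2 * sqrt(2 * log(2)))
  # circular distance between bins, in degrees
  d <- pmin(0:(n - 1), n - 0:(n - 1))
  w <- exp(-d^2 / (2 * sigma^2))
  w <- w / sum(w)
  # circular convolution by FFT
  Re(stats::fft(stats::fft(h) * stats::fft(w), inverse = TRUE)) / n
}

#' Axial von Mises density on the half circle
#'
#' Density of an axial (180-degree periodic) von Mises distribution with
#' center `theta` and concentration `kappa`, discretized so that the mass
#' summed over the 180 one-degree bins equals 1:
#' `f(x) = exp(kappa * cos(2 * (x - theta) * pi/180)) / Z`.
#' The doubling of the angle makes `f(0) = f(180)`, the axial continuity
#' condition; `kappa = 0` gives the uniform density `1/180`.
#'
#' @param x Angles in degrees at which to evaluate.
#' @param theta Center in degrees `[0, 180)`.
#' @param kappa Concentration, >= 0.
#' @return Density per one-degree bin at `x`.
#' @export
axial_von_mises_pdf <- function(x, theta, kappa) {
  if (kappa < 0) stop("axial_von_mises_pdf(): kappa must be >= 0")
  grid <- 0:179
  un <- function(a) exp(kappa * (cos(2 * deg2rad(a - theta)) - 1))
  z <- sum(un(grid))
  un(x) / z
}

#' Greedy axial von Mises mixture fit of a smoothed orientation histogram
#'
#' Repeats up to `n_components` times: (1) take the histogram argmax as
#' component center `theta` (ties break to the lowest bin index) and its
#' height as amplitude `d`; (2) find the concentration `kappa` minimizing the
#' squared error between the histogram and the peak-normalized component
#' `c(x) = d * f(x; theta, kappa) / f(theta; theta, kappa)` over a circular
#' window `theta +/- window_deg`; (3) subtract `c` from the histogram
#' (residuals are not clipped) and repeat.  Greediness guarantees amplitudes
#' in non-increasing fit order; the first center is the voxel's primary
#' orientation.
#'
#' @param h Numeric vector of 180 smoothed bin masses.
#' @param n_components Maximum number of components (default 3).
#' @param window_deg Half-width of the kappa-fit window in degrees
#'   (default 42).
#' @param kappa_bounds Search interval for kappa (default `c(0.01, 100)`).
#' @return Tibble with one row per component in fit order: `component`,
#'   `theta`, `kappa`, `amplitude`.  Zero rows for an all-zero histogram.
#' @export
fit_von_mises_mixture <- function(h, n_components = 3, window_deg = 42,
                                  kappa_bounds = c(0.01, 100)) {
  stopifnot(length(h) == 180, n_components >= 1, window_deg > 0)
  if (all(h == 0)) {
    return(tibble::tibble(component = integer(), theta = numeric(),
                          kappa = numeric(), amplitude = numeric()))
  }
  bins <- 0:179
  res <- h
  out <- vector("list", n_components)
  for (k in seq_len(n_components)) {
    imax <- which.max(res)  # ties -> lowest index
    theta <- bins[imax]
    d <- res[imax]
    idx <- ((theta - window_deg):(theta + window_deg)) %% 180 + 1
    target <- res[idx]
    x <- (theta - window_deg):(theta + window_deg)
    sse <- function(kappa) {
      f <- axial_von_mises_pdf(x, theta, kappa)
      fmax <- axial_von_mises_pdf(theta, theta, kappa)
      sum((target - d * f / fmax)^2)
    }
    opt <- stats::optimize(sse, interval = kappa_bounds, tol = 1e-6)
    kappa <- opt$minimum
    comp_full <- {
      f <- axial_von_mises_pdf(bins, theta, kappa)
      d * f / axial_von_mises_pdf(theta, theta, kappa)
    }
    res <- res - comp_full
    out[[k]] <- tibble::tibble(component = k, theta = theta,
                               kappa = kappa, amplitude = d)
  }
  dplyr::bind_rows(out)
}

#' Width of a fitted von Mises component
#'
#' `width = 1 - kappa / kappa_max`, where `kappa_max` is the maximum
#' concentration over all fitted components of the analysis run (or a fixed
#' reference for cross-run comparability).  0 is the sharpest component in
#' the set, 1 a flat one.
#'
#' @param kappa Concentration(s), `0 <= kappa <= kappa_max`.
#' @param kappa_max Positive reference maximum.
#' @return Width(s) in `[0, 1]`.
#' @export
component_width <- function(kappa, kappa_max) {
  stopifnot(kappa_max > 0)
  if (any(kappa > kappa_max + 1e-12, na.rm = TRUE)) {
    stop("component_width(): kappa exceeds kappa_max")
  }
  1 - kappa / kappa_max
}

#' Voxel-level fiber orientation distributions for one section
#'
#' Tiles a section into voxel-sized subimages, computes per-voxel staining
#' intensity, valid fraction, the smoothed 180-bin orientation histogram and
#' the greedy von Mises mixture, and returns one row per retained voxel.
#' Voxels are discarded when their valid-pixel fraction falls below
#' `min_valid_frac` (tissue damage) or their staining intensity below
#' `min_stain` (no stained material); discards are tallied in the
#' `"exclusions"` attribute.
#'
#' @param image Numeric gray-level matrix in `[0, 1]`.
#' @param mask Logical validity matrix (default all valid).
#' @param pixel_size_um,voxel_size_um Pixel and voxel sizes in micrometers.
#' @param section_id Integer identifier stored in the output.
#' @param fwhm_deg Histogram smoothing FWHM, degrees.
#' @param n_components,window_deg,kappa_bounds Passed to
#'   [fit_von_mises_mixture()].
#' @param min_valid_frac,min_stain Inclusion floors (defaults 0.05, 0.02).
#' @param sigma,kernel_size Structure-tensor kernel parameters.
#' @return Tibble with columns `section_id`, `i`, `j`, `stain`,
#'   `valid_frac`, `phi_st`, `theta1..3`, `kappa1..3`, `ampl1..3`, and a
#'   list-column `histogram` holding each voxel's smoothed histogram.
#' @export
section_fods <- function(image, mask = NULL, pixel_size_um, voxel_size_um,
                         section_id = 0L, fwhm_deg = 23, n_components = 3,
                         window_deg = 42, kappa_bounds = c(0.01, 100),
                         min_valid_frac = 0.05, min_stain = 0.02,
                         sigma = 2, kernel_size = 9) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  orient <- section_orientation(image, mask, sigma, kernel_size)
  tiles <- voxelize(nrow(image), ncol(image), pixel_size_um, voxel_size_um)
  n_total <- nrow(tiles)
  n_damage <- 0L
  n_unstained <- 0L
  rows <- vector("list", n_total)
  for (t in seq_len(n_total)) {
    tl <- tiles[t, ]
    rr <- tl$row0:tl$row1
    cc <- tl$col0:tl$col1
    px <- image[rr, cc]
    mk <- mask[rr, cc]
    vfrac <- mean(mk)
    if (vfrac < min_valid_frac) {
      n_damage <- n_damage + 1L
      next
    }
    stain <- staining_intensity(px, mk)
    if (is.na(stain) || stain < min_stain) {
      n_unstained <- n_unstained + 1L
      next
    }
    h <- orientation_histogram(orient$phi[rr, cc], mk)
    if (is.null(h)) {
      n_unstained <- n_unstained + 1L
      next
    }
    hs <- smooth_histogram(h, fwhm_deg)
    fit <- fit_von_mises_mixture(hs, n_components, window_deg, kappa_bounds)
    get <- function(col, k) {
      if (nrow(fit) >= k) fit[[col]][k] else NA_real_
    }
    rows[[t]] <- tibble::tibble(
      section_id = section_id, i = tl$i, j = tl$j,
      stain = stain, valid_frac = vfrac,
      phi_st = get("theta", 1),
      theta1 = get("theta", 1), kappa1 = get("kappa", 1),
      ampl1 = get("amplitude", 1),
      theta2 = get("theta", 2), kappa2 = get("kappa", 2),
      ampl2 = get("amplitude", 2),
      theta3 = get("theta", 3), kappa3 = get("kappa", 3),
      ampl3 = get("amplitude", 3),
      histogram = list(hs)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- tibble::tibble(
    stage = c("damage", "unstained"),
    n_removed = c(n_damage, n_unstained),
    n_total = n_total,
    fraction = c(n_damage, n_unstained) / n_total
  )
  out
}

#' Attach width columns to a voxel FOD table
#'
#' Computes `kappa_max` as the maximum over all fitted components of the
#' supplied table (the analysis set) unless a fixed value is given, then
#' adds `width1..width3 = 1 - kappa/kappa_max`.
#'
#' @param fods Tibble from [section_fods()] (possibly several sections
#'   row-bound).
#' @param kappa_max Optional fixed reference; default: maximum over the set.
#' @return The table with `width1`, `width2`, `width3` columns added and the
#'   `kappa_max` used stored as an attribute.
#' @export
add_component_widths <- function(fods, kappa_max = NULL) {
  if (is.null(kappa_max)) {
    kappa_max <- max(c(fods$kappa1, fods$kappa2, fods$kappa3), na.rm = TRUE)
  }
  out <- dplyr::mutate(
    fods,
    width1 = component_width(.data$kappa1, kappa_max),
    width2 = component_width(.data$kappa2, kappa_max),
    width3 = component_width(.data$kappa3, kappa_max)
  )
  attr(out, "kappa_max") <- kappa_max
  out
}
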