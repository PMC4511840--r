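#' Define one region of a phantom geometry
#'
#' A phantom geometry is a list of polygonal regions tiling the field of
#' view.  Each region carries a tissue class, one or two ground-truth fiber
#' axes with texture weights, a fiber density driving staining darkness, the
#' diffusion-tensor eigenvalues, and the rule for the tensor's principal
#' axis: `"texture_axis_1"` (tensor follows the stained texture) or
#' `"radial_override"` (tensor takes `radial_axis_deg` instead — the
#' cortical situation where tangential myelinated bands coexist with radial
#' diffusion).
#'
#' @param polygon Numeric `n x 2` matrix of `(x, y)` vertices in mm.
#' @param tissue `"WM"`, `"GM"` or `"background"`.
#' @param axes_deg Fiber axes in degrees `[0, 180)` (length 1 or 2).
#' @param weights Per-axis texture weights in `[0, 1]`, summing to <= 1.
#' @param density Fiber density in `[0, 1]`.
#' @param evals Tensor eigenvalues `(l1 >= l2 >= l3 > 0)`, mm^2/s.
#' @param principal `"texture_axis_1"` or `"radial_override"`.
#' @param radial_axis_deg Axis used when `principal = "radial_override"`.
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(polygon, tissue, axes_deg = numeric(),
                           weights = rep(1 / max(length(axes_deg), 1),
                                         length(axes_deg)),
                           density = 0,
                           evals = c(1e-3, 1e-3, 1e-3),
                           principal = c("texture_axis_1", "radial_override"),
                           radial_axis_deg = NA_real_) {
  principal <- match.arg(principal)
  tissue <- match.arg(tissue, c("WM", "GM", "background"))
  stopifnot(all(axes_deg >= 0 & axes_deg < 180),
            length(weights) == length(axes_deg),
            sum(weights) <= 1 + 1e-12,
            density >= 0, density <= 1,
            length(evals) == 3, all(diff(evals) <= 0), all(evals > 0))
  structure(list(polygon = as.matrix(polygon), tissue = tissue,
                 axes_deg = axes_deg, weights = weights, density = density,
                 evals = evals, principal = principal,
                 radial_axis_deg = radial_axis_deg),
            class = "phantom_region")
}

# even-odd ray casting; points on edges resolve by a tiny inward nudge at
# the caller (voxel/pixel centers never lie on region borders in the
# default geometry)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# region index (first match) for each point; 0 when uncovered
region_lookup <- function(geometry, px, py) {
  out <- integer(length(px))
  for (k in seq_along(geometry)) {
    hit <- out == 0L & point_in_polygon(px, py, geometry[[k]]$polygon)
    out[hit] <- k
  }
  out
}

#' Diffusion gradient directions by electrostatic repulsion
#'
#' Places `n` point charges on the whole sphere and minimizes the Coulomb
#' energy (summed inverse pairwise chord distances) by quasi-Newton descent
#' from several seeded random starts, keeping the best.  Deterministic given
#' the seed.  Directions are returned unit-norm in lexicographic order.
#'
#' @param n Number of directions (>= 2).
#' @param iterations Optimizer iteration budget per restart.
#' @param seed Integer seed for the random starts.
#' @param restarts Number of random restarts.
#' @return `n x 3` matrix of unit vectors.
#' @export
electrostatic_directions <- function(n, iterations = 500, seed = 1,
                                     restarts = 4) {
  if (n < 2) stop("electrostatic_directions(): n must be >= 2")
  energy <- function(par) {
    p <- matrix(par, n, 3)
    u <- p / sqrt(rowSums(p^2))
    dmat <- as.matrix(stats::dist(u))
    sum(1 / dmat[upper.tri(dmat)])
  }
  best <- NULL
  best_e <- Inf
  set.seed(seed)
  for (r in seq_len(restarts)) {
    start <- matrix(stats::rnorm(n * 3), n, 3)
    start <- start / sqrt(rowSums(start^2))
    opt <- stats::optim(as.vector(start), energy, method = "BFGS",
                        control = list(maxit = iterations, reltol = 1e-12))
    if (opt$value < best_e) {
      best_e <- opt$value
      best <- opt$par
    }
  }
  u <- matrix(best, n, 3)
  u <- u / sqrt(rowSums(u^2))
  u[order(u[, 1], u[, 2], u[, 3]), , drop = FALSE]
}

#' Build a full acquisition scheme (b = 0 volumes first)
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param n_b0 Number of b = 0 volumes.
#' @param bval Diffusion weighting, s/mm^2.
#' @param seed Seed for [electrostatic_directions()].
#' @return A [gradient_scheme()].
#' @export
make_scheme <- function(n_dirs = 60, n_b0 = 6, bval = 3000, seed = 1) {
  dirs <- electrostatic_directions(n_dirs, seed = seed)
  gradient_scheme(
    bvals = c(rep(0, n_b0), rep(bval, n_dirs)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
}

# oriented stripe texture: white noise filtered with an elongated Gaussian
# kernel whose long axis lies along the fiber axis (aspect ratio >= 8),
# then standardized.  Circular FFT filtering; periodic seams are invisible
# at the used kernel sizes.
stripe_texture <- function(n_rows, n_cols, axis_deg, sigma_long = 12,
                           sigma_short = 1.5) {
  th <- deg2rad(axis_deg)
  half <- ceiling(3 * sigma_long)
  off <- seq(-half, half)
  dx <- matrix(off, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  dy <- matrix(off, 2 * half + 1, 2 * half + 1)
  u <- dx * cos(th) + dy * sin(th)     # along-fiber coordinate
  v <- -dx * sin(th) + dy * cos(th)    # across-fiber coordinate
  k <- exp(-u^2 / (2 * sigma_long^2) - v^2 / (2 * sigma_short^2))
  k <- k / sum(k)
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  t <- fft_filter_circular(noise, k)
  (t - mean(t)) / stats::sd(t)
}

#' Render a synthetic myelin-stained section
#'
#' Within each region the stain pattern is a superposition of oriented
#' stripe textures at the region's ground-truth axes (anisotropically
#' filtered white noise), with darkness increasing with fiber density;
#' background regions are blank white.  Gaussian pixel noise of standard
#' deviation `noise_sd` is added and the image clipped to `[0, 1]`.
#'
#' @param geometry List of [phantom_region()]s tiling the field of view.
#' @param n_rows,n_cols Image size in pixels.
#' @param pixel_size_um Pixel edge length, micrometers.
#' @param noise_sd Gray-level noise standard deviation.
#' @param seed Integer seed (same seed, same geometry: bit-identical image).
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_section <- function(geometry, n_rows = 256, n_cols = 256,
                           pixel_size_um = 2, noise_sd = 0.02, seed = 1) {
  stopifnot(pixel_size_um > 0)
  set.seed(seed)
  mm_per_px <- pixel_size_um / 1000
  # pixel centers in mm: x = column, y = row
  cx <- (matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE) - 0.5) *
    mm_per_px
  cy <- (matrix(seq_len(n_rows), n_rows, n_cols) - 0.5) * mm_per_px
  reg <- region_lookup(geometry, as.vector(cx), as.vector(cy))
  reg <- matrix(reg, n_rows, n_cols)
  img <- matrix(1, n_rows, n_cols)
  for (k in seq_along(geometry)) {
    g <- geometry[[k]]
    inreg <- reg == k
    if (!any(inreg) || g$tissue == "background" || g$density == 0 ||
        length(g$axes_deg) == 0) next
    stain <- matrix(0, n_rows, n_cols)
    for (a in seq_along(g$axes_deg)) {
      tex <- stripe_texture(n_rows, n_cols, g$axes_deg[a])
      # squash to [0, 1]; gain sharpens stripes without hard edges
      stain <- stain + g$weights[a] * stats::pnorm(2 * tex)
    }
    img[inreg] <- 1 - g$density * stain[inreg]
  }
  img <- img + stats::rnorm(n_rows * n_cols, sd = noise_sd)
  pmin(pmax(img, 0), 1)
}

# ground-truth tensor of a region: eigenvalues along (principal axis,
# in-plane orthogonal, through-plane z)
region_tensor <- function(g) {
  ax <- if (g$principal == "radial_override") g$radial_axis_deg else
    g$axes_deg[1]
  th <- deg2rad(ax)
  e1 <- c(cos(th), sin(th), 0)
  e2 <- c(-sin(th), cos(th), 0)
  e3 <- c(0, 0, 1)
  g$evals[1] * tcrossprod(e1) + g$evals[2] * tcrossprod(e2) +
    g$evals[3] * tcrossprod(e3)
}

#' Simulate a diffusion-weighted volume from a phantom geometry
#'
#' Per voxel the ground-truth tensor is built from the region's eigenvalues
#' with its principal axis along the region's first texture axis (or the
#' radial override), and the signal follows the mono-exponential tensor
#' model `S = S0 exp(-b g' D g)`.  Rician noise is applied per measurement:
#' the magnitude of `(S + N(0, sigma), N(0, sigma))` with
#' `sigma = S0 / snr`; `snr = Inf` returns the exact model signal.
#'
#' @param geometry List of [phantom_region()]s; every voxel center must be
#'   covered.
#' @param scheme A [gradient_scheme()].
#' @param n_x,n_y,n_z Voxel grid size.
#' @param voxel_size_um Voxel edge length, micrometers.
#' @param S0 Non-diffusion-weighted signal level.
#' @param snr Signal-to-noise ratio (> 0, or `Inf` for noiseless).
#' @param seed Integer seed.
#' @return List with `dwi` (4D array `x, y, z, volume`), `tissue` (integer
#'   array: 0 background, 1 GM, 2 WM), and `truth` — a tibble per voxel with
#'   ground-truth axes, density and eigenvalues.
#' @export
simulate_dwi <- function(geometry, scheme, n_x = 8, n_y = 8, n_z = 8,
                         voxel_size_um = 64, S0 = 1000, snr = 50, seed = 1) {
  stopifnot(snr > 0)
  set.seed(seed)
  mm <- voxel_size_um / 1000
  centers <- tidyr::expand_grid(k = seq_len(n_z) - 1L,
                                j = seq_len(n_y) - 1L,
                                i = seq_len(n_x) - 1L)
  px <- (centers$i + 0.5) * mm
  py <- (centers$j + 0.5) * mm
  reg <- region_lookup(geometry, px, py)
  if (any(reg == 0L)) stop("simulate_dwi(): voxel grid not covered by geometry")
  nvol <- length(scheme$bvals)
  dwi <- array(0, c(n_x, n_y, n_z, nvol))
  tissue <- array(0L, c(n_x, n_y, n_z))
  b <- scheme$bvals
  g <- scheme$bvecs
  # per-region model signal over the scheme (tensor constant within region)
  sig_by_region <- lapply(geometry, function(gg) {
    D <- region_tensor(gg)
    S0 * exp(-b * rowSums((g %*% D) * g))
  })
  truth <- vector("list", nrow(centers))
  for (r in seq_len(nrow(centers))) {
    gg <- geometry[[reg[r]]]
    ii <- centers$i[r] + 1L
    jj <- centers$j[r] + 1L
    kk <- centers$k[r] + 1L
    tissue[ii, jj, kk] <- switch(gg$tissue, background = 0L, GM = 1L, WM = 2L)
    s <- if (gg$tissue == "background") rep(0, nvol) else
      sig_by_region[[reg[r]]]
    if (is.finite(snr)) {
      sigma <- S0 / snr
      s <- sqrt((s + stats::rnorm(nvol, sd = sigma))^2 +
                  stats::rnorm(nvol, sd = sigma)^2)
    }
    dwi[ii, jj, kk, ] <- s
    ax1 <- if (length(gg$axes_deg)) gg$axes_deg[1] else NA_real_
    truth[[r]] <- tibble::tibble(
      i = centers$i[r], j = centers$j[r], slice = centers$k[r],
      tissue = gg$tissue,
      axis1 = ax1,
      axis2 = if (length(gg$axes_deg) > 1) gg$axes_deg[2] else NA_real_,
      tensor_axis = if (gg$tissue == "background") NA_real_ else
        if (gg$principal == "radial_override") gg$radial_axis_deg else ax1,
      density = gg$density,
      l1 = gg$evals[1], l2 = gg$evals[2], l3 = gg$evals[3]
    )
  }
  list(dwi = dwi, tissue = tissue, truth = dplyr::bind_rows(truth))
}

#' The default three-regime phantom geometry
#'
#' A square field of view split into four horizontal bands: background, a
#' unidirectional white-matter pathway, a white-matter 60-degree fiber
#' crossing, and a gray-matter ribbon whose stained texture is tangential
#' (horizontal) while the diffusion tensor is overridden to the radial
#' (vertical) axis — the cortical bands-of-Baillarger situation that
#' produces near-90-degree histology-DTI mismatches.  Densities and tensor
#' eigenvalues are chosen so that staining intensity rises with FA and
#' falls with MD across regions, the sign structure expected when myelin
#' density drives both stain darkness and diffusion anisotropy.
#'
#' @param fov_mm Field-of-view edge length in mm.
#' @return List of [phantom_region()]s.
#' @export
default_phantom_geometry <- function(fov_mm = 0.512) {
  band <- function(y0, y1) {
    rbind(c(0, y0), c(fov_mm, y0), c(fov_mm, y1), c(0, y1))
  }
  q <- fov_mm / 4
  list(
    phantom_region(band(0, q), "background"),
    phantom_region(band(q, 2 * q), "WM", axes_deg = 30, weights = 1,
                   density = 0.9, evals = c(1.7e-3, 0.3e-3, 0.3e-3)),
    phantom_region(band(2 * q, 3 * q), "WM", axes_deg = c(0, 60),
                   weights = c(0.5, 0.5), density = 0.6,
                   evals = c(1.4e-3, 0.8e-3, 0.45e-3)),
    phantom_region(band(3 * q, 4 * q), "GM", axes_deg = 0, weights = 1,
                   density = 0.3, evals = c(1.1e-3, 0.9e-3, 0.85e-3),
                   principal = "radial_override", radial_axis_deg = 90)
  )
}
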