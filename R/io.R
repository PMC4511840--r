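#' Read an FSL-style gradient table
#'
#' The bval file holds one whitespace-separated row of b-values; the bvec
#' file three rows (x, y, z components).  Vectors whose norm deviates from
#' 1 by more than 1e-6 are renormalized with a warning; rows with b = 0 get
#' zero vectors (with a warning if the file said otherwise).
#'
#' @param bval_path,bvec_path File paths.
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3) {
    stop("read_gradient_table(): bvec file must have exactly 3 rows")
  }
  rows <- lapply(bvec_lines, function(l) scan(text = l, quiet = TRUE))
  if (length(unique(lengths(rows))) != 1 ||
      length(rows[[1]]) != length(bvals)) {
    stop("read_gradient_table(): bval/bvec length mismatch")
  }
  bvecs <- t(do.call(rbind, rows))
  zero_b <- bvals == 0
  if (any(zero_b & sqrt(rowSums(bvecs^2)) > 1e-12)) {
    warning("nonzero direction on a b = 0 volume zeroed")
    bvecs[zero_b, ] <- 0
  }
  gradient_scheme(bvals, bvecs)
}

#' @rdname read_gradient_table
#' @param scheme A [gradient_scheme()] to write.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  }), bvec_path)
  invisible(bval_path)
}

#' Read / write per-voxel tables as CSV
#'
#' Plain CSV with a header row; angles in degrees, diffusivities in
#' mm^2/s.  Roundtrips are lossless at full double precision.  On read,
#' axis-angle columns (`phi_st`, `phi_dt`, `theta1..3`) outside `[0, 180)`
#' are wrapped with a warning; unknown extra columns are preserved.
#'
#' @param tbl Data frame to write (list columns are dropped with a
#'   message).
#' @param path File path.
#' @param required Character vector of columns that must be present on
#'   read.
#' @return `read_voxel_table()` returns a tibble.
#' @export
write_voxel_table <- function(tbl, path) {
  is_list <- vapply(tbl, is.list, logical(1))
  if (any(is_list)) {
    message("dropping list column(s): ",
            paste(names(tbl)[is_list], collapse = ", "))
    tbl <- tbl[, !is_list, drop = FALSE]
  }
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path, required = character()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("read_voxel_table(): missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  angle_cols <- intersect(c("phi_st", "phi_dt", "theta1", "theta2", "theta3"),
                          names(tbl))
  for (cl in angle_cols) {
    v <- tbl[[cl]]
    bad <- !is.na(v) & (v < 0 | v >= 180)
    if (any(bad)) {
      warning("axis angles in column '", cl, "' wrapped into [0, 180)")
      tbl[[cl]] <- norm_axis_deg(v)
    }
  }
  tbl
}

#' Write phantom outputs to disk
#'
#' Writes the diffusion-weighted volume as 4D float32 NIfTI, the tissue
#' mask as uint8 NIfTI (0 background, 1 GM, 2 WM), section images as 8-bit
#' grayscale TIFF, the gradient table as FSL bval/bvec text, and the
#' ground-truth voxel table as CSV.
#'
#' @param sim Output of [simulate_dwi()].
#' @param sections List of section image matrices (from
#'   [render_section()]).
#' @param scheme The [gradient_scheme()] used.
#' @param dir Output directory (created if needed).
#' @param voxel_size_um Voxel edge length recorded in the NIfTI header.
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(sim, sections, scheme, dir, voxel_size_um = 64) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- voxel_size_um / 1000
  dwi <- sim$dwi
  attr(dwi, "pixdim") <- c(mm, mm, mm, 1)
  RNifti::writeNifti(RNifti::asNifti(dwi, internal = FALSE),
                     file.path(dir, "dwi.nii.gz"), datatype = "float")
  tis <- sim$tissue
  attr(tis, "pixdim") <- c(mm, mm, mm)
  RNifti::writeNifti(RNifti::asNifti(tis, internal = FALSE),
                     file.path(dir, "tissue.nii.gz"), datatype = "uint8")
  write_gradient_table(scheme, file.path(dir, "dwi.bval"),
                       file.path(dir, "dwi.bvec"))
  for (s in seq_along(sections)) {
    tiff::writeTIFF(sections[[s]],
                    file.path(dir, sprintf("section_%03d.tif", s - 1)),
                    bits.per.sample = 8)
  }
  write_voxel_table(sim$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Default pipeline configuration
#'
#' All tunables with their defaults: structure-tensor kernel (sigma 2 px,
#' size 9 px), voxel size (340 um for real acquisitions), histogram
#' smoothing FWHM (23 degrees), number of von Mises components (3) and
#' kappa window (+/- 42 degrees), out-of-plane threshold (45 degrees), FA
#' bin width (0.05), minimum displayed bin size (100 voxels), truncation
#' threshold (50 degrees).  Unknown keys in an override list are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of validated configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    st_sigma = 2, st_kernel = 9,
    fod_voxel_um = 340, fod_bins = 180, fod_fwhm_deg = 23,
    fod_components = 3, fod_window_deg = 42,
    fod_min_valid_frac = 0.05, fod_min_stain = 0.02,
    dti_max_oop_deg = 45,
    stats_fa_bin = 0.05, stats_min_bin_n = 100, stats_trunc_deg = 50,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("pipeline_config(): unknown option(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$st_sigma > 0, cfg$st_kernel %% 2 == 1,
            cfg$fod_voxel_um > 0, cfg$fod_fwhm_deg > 0,
            cfg$fod_components >= 1, cfg$dti_max_oop_deg >= 0,
            cfg$stats_fa_bin > 0, cfg$stats_min_bin_n >= 1)
  cfg
}
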