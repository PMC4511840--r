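#' Build a planar similarity transform in homogeneous coordinates
#'
#' The section-to-slice alignment is one in-plane rotation, two
#' translations and one isotropic scale, composed as translate . rotate .
#' scale about the origin and stored as a 3x3 homogeneous matrix.  Identity
#' parameters give the identity matrix.
#'
#' @param rotation_deg Rotation angle, degrees, counter-clockwise from +x
#'   toward +y.
#' @param tx,ty Translations (mm).
#' @param scale Isotropic scale factor (> 0).
#' @return 3x3 numeric matrix.
#' @export
make_affine <- function(rotation_deg = 0, tx = 0, ty = 0, scale = 1) {
  if (scale <= 0) stop("make_affine(): scale must be > 0")
  th <- deg2rad(rotation_deg)
  R <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  S <- diag(c(scale, scale, 1))
  Tm <- diag(3)
  Tm[1:2, 3] <- c(tx, ty)
  Tm %*% R %*% S
}

#' Apply a homogeneous 3x3 transform to 2D points
#'
#' @param m 3x3 transform matrix.
#' @param pts Numeric `n x 2` matrix (or length-2 vector) of `(x, y)`
#'   points.
#' @return Transformed points, same shape.
#' @export
apply_affine <- function(m, pts) {
  one <- FALSE
  if (is.null(dim(pts))) {
    pts <- matrix(pts, 1)
    one <- TRUE
  }
  hp <- cbind(pts, 1) %*% t(m)
  out <- hp[, 1:2, drop = FALSE] / hp[, 3]
  if (one) out[1, ] else out
}

#' Least-squares similarity transform from landmark pairs
#'
#' Estimates the rotation, isotropic scale and translation minimizing the
#' summed squared residuals between transformed source landmarks and their
#' targets.  With points as complex numbers the model `w = c z + t` is
#' linear in `(c, t)`, so the fit is an exact linear least squares; two
#' distinct pairs determine the 4 degrees of freedom exactly.
#'
#' @param src,dst Numeric `n x 2` matrices of corresponding `(x, y)`
#'   landmarks (`n >= 2`, source points not all coincident).
#' @return List with the 3x3 `matrix`, decomposed `rotation_deg`, `scale`,
#'   `tx`, `ty`, and `rms_residual`.
#' @export
fit_alignment <- function(src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 2) stop("fit_alignment(): need at least 2 landmark pairs")
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  if (max(Mod(z - mean(z))) < 1e-12) {
    stop("fit_alignment(): source landmarks are coincident (underdetermined)")
  }
  X <- cbind(z, rep(1 + 0i, length(z)))
  beta <- qr.solve(X, w)
  cc <- beta[1]
  tt <- beta[2]
  fitted <- cc * z + tt
  rms <- sqrt(mean(Mod(w - fitted)^2))
  list(
    matrix = make_affine(rad2deg(Arg(cc)), Re(tt), Im(tt), Mod(cc)),
    rotation_deg = rad2deg(Arg(cc)), scale = Mod(cc),
    tx = Re(tt), ty = Im(tt), rms_residual = rms
  )
}

#' Assign histological sections to volume z-slices
#'
#' Section `m` (0-based), centered at `m * section_spacing_um`, is paired
#' with slice `round(m * section_spacing_um / slice_thickness_um)`, clipped
#' to the available slice range.  With 300 um section spacing and 340 um
#' slices this reproduces the approximately 1:1 assignment in which about
#' every 8th-9th slice receives two consecutive sections.
#'
#' @param section_spacing_um Distance between consecutive analyzed
#'   sections, micrometers.
#' @param slice_thickness_um Volume slice thickness, micrometers.
#' @param n_sections,n_slices Counts.
#' @return Tibble with `section` and `slice` (both 0-based).
#' @export
assign_sections <- function(section_spacing_um, slice_thickness_um,
                            n_sections, n_slices) {
  stopifnot(section_spacing_um > 0, slice_thickness_um > 0)
  m <- seq_len(n_sections) - 1L
  s <- round(m * section_spacing_um / slice_thickness_um)
  s <- pmin(pmax(s, 0L), n_slices - 1L)
  tibble::tibble(section = m, slice = as.integer(s))
}

#' Read / write section alignment transforms as JSON
#'
#' Each transform is stored as `{section_id, z_slice, matrix}` with the
#' matrix as 9 numbers in row-major order, units mm.
#'
#' @param alignments List of lists with fields `section_id`, `z_slice`,
#'   `matrix` (3x3).
#' @param path File path.
#' @return `read_alignments()` returns the list form with 3x3 matrices.
#' @export
write_alignments <- function(alignments, path) {
  payload <- lapply(alignments, function(a) {
    list(section_id = a$section_id, z_slice = a$z_slice,
         matrix = as.vector(t(a$matrix)), units = "mm")
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(k) {
    list(section_id = payload$section_id[k],
         z_slice = payload$z_slice[k],
         matrix = matrix(unlist(payload$matrix[k]), 3, 3, byrow = TRUE))
  })
}
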