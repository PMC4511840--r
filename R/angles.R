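#' Normalize angles to the axial range [0, 180)
#'
#' Orientations of undirected structures (fiber axes, stripe textures,
#' eigenvector axes) are axial: an angle and its opposite describe the same
#' axis.  All axis angles in this package live in degrees in `[0, 180)`,
#' measured from the +x (column) axis toward the +y (row) axis.
#'
#' @param theta Numeric vector of angles in degrees.
#' @param warn Warn when values fall outside `[0, 180)` and get wrapped.
#' @return Numeric vector of angles in `[0, 180)`.
#' @export
#' @examples
#' norm_axis_deg(c(185, -10, 90))
norm_axis_deg <- function(theta, warn = FALSE) {
  out <- theta %% 180
  # x %% 180 can return exactly 180 for tiny negative x; fold to 0
  out[!is.na(out) & out >= 180] <- 0
  if (warn && any(abs(out - theta) > 1e-9, na.rm = TRUE)) {
    warning("axis angles outside [0, 180) were wrapped modulo 180")
  }
  out
}

#' Axis-angle difference between two planar orientations
#'
#' The distance between two axes `a` and `b` (degrees, axial) is
#' `min(|a - b|, 180 - |a - b|)`, which lies in `[0, 90]` and is a metric on
#' the half-circle of axes.
#'
#' @param a,b Numeric vectors of axis angles in degrees, `[0, 180)`.
#'   Out-of-range values are wrapped with a warning.
#' @return Numeric vector of differences in degrees, in `[0, 90]`.
#' @export
#' @examples
#' axis_angle_diff(10, 170)  # 20, wraps around 180
#' axis_angle_diff(0, 90)    # 90, the maximum
axis_angle_diff <- function(a, b) {
  a <- norm_axis_deg(a, warn = TRUE)
  b <- norm_axis_deg(b, warn = TRUE)
  d <- abs(a - b)
  pmin(d, 180 - d)
}

#' Weighted mean of two fiber axes (doubled-angle axial mean)
#'
#' Axial data cannot be averaged arithmetically (10 and 170 average to 90,
#' not 0).  The standard construction doubles the angles so axes become
#' directions on the full circle, takes the weighted vector mean, and halves
#' the resulting angle.  When the doubled vectors cancel exactly — the two
#' axes orthogonal with equal weights — the mean is undefined and `NA` is
#' returned.
#'
#' @param a,b Axis angles in degrees, `[0, 180)`.
#' @param w_a,w_b Non-negative weights; must not both be zero.
#' @return Mean axis in degrees `[0, 180)`, or `NA` for the orthogonal
#'   equal-weight tie.
#' @export
#' @examples
#' mean_axis(10, 30)          # 20
#' mean_axis(0, 90)           # NA: doubled vectors are antipodal
#' mean_axis(170, 10)         # 0, wraps correctly
mean_axis <- function(a, b, w_a = 1, w_b = 1) {
  stopifnot(all(w_a >= 0), all(w_b >= 0))
  if (any(w_a + w_b == 0)) {
    stop("mean_axis(): weights must not both be zero")
  }
  a2 <- 2 * norm_axis_deg(a) * pi / 180
  b2 <- 2 * norm_axis_deg(b) * pi / 180
  x <- w_a * cos(a2) + w_b * cos(b2)
  y <- w_a * sin(a2) + w_b * sin(b2)
  r <- sqrt(x^2 + y^2)
  out <- norm_axis_deg(atan2(y, x) * 180 / pi / 2)
  out[r < 1e-12] <- NA_real_
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
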