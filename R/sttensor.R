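#' Smoothed image gradient of a section image
#'
#' Convolves the image with the partial derivatives of a rotationally
#' symmetric Gaussian kernel (default size 9 px, sigma 2 px), giving the
#' regularized gradient fields used to build structure tensors.  Boundaries
#' are handled by reflection.
#'
#' @param image Numeric matrix, gray levels in `[0, 1]` (0 = darkest stain).
#'   Rows index y, columns index x.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param kernel_size Odd kernel side length in pixels.
#' @return List with matrices `fx` and `fy` of the same shape as `image`.
#' @export
image_gradient <- function(image, sigma = 2, kernel_size = 9) {
  stopifnot(is.matrix(image), sigma > 0)
  if (kernel_size %% 2 != 1) {
    stop("image_gradient(): kernel_size must be odd")
  }
  g <- gaussian_taps(sigma, kernel_size)
  d <- gaussian_deriv_taps(sigma, kernel_size)
  # x = columns: derivative taps run along columns; smoothing along rows.
  kx <- outer(g, d)
  ky <- outer(d, g)
  list(
    fx = filter2_reflect(image, kx),
    fy = filter2_reflect(image, ky)
  )
}

#' Structure tensor field from gradient images
#'
#' The structure tensor at a pixel is the Gaussian-smoothed outer product of
#' the gradient: entries `fxx`, `fxy`, `fyy` are the pointwise products
#' `fx*fx`, `fx*fy`, `fy*fy` convolved with the same unit-sum Gaussian kernel
#' used for differentiation.  Each 2x2 tensor is symmetric positive
#' semi-definite up to rounding.
#'
#' @param fx,fy Gradient matrices of identical shape (from
#'   [image_gradient()]).
#' @inheritParams image_gradient
#' @return List of matrices `fxx`, `fxy`, `fyy`, plus eigenvalue fields
#'   `lambda1 >= lambda2` and `coherence = (l1 - l2)/(l1 + l2)` (0 where both
#'   eigenvalues vanish).
#' @export
structure_tensor_field <- function(fx, fy, sigma = 2, kernel_size = 9) {
  if (!identical(dim(fx), dim(fy))) {
    stop("structure_tensor_field(): fx and fy must have the same shape")
  }
  g <- gaussian_taps(sigma, kernel_size)
  G <- outer(g, g)
  fxx <- filter2_reflect(fx * fx, G)
  fxy <- filter2_reflect(fx * fy, G)
  fyy <- filter2_reflect(fy * fy, G)
  # closed-form eigenvalues of [[fxx, fxy], [fxy, fyy]]
  tr <- fxx + fyy
  disc <- sqrt(pmax((fxx - fyy)^2 + 4 * fxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  coh <- ifelse(tr > 0, (l1 - l2) / tr, 0)
  list(fxx = fxx, fxy = fxy, fyy = fyy,
       lambda1 = l1, lambda2 = l2, coherence = coh)
}

#' Per-pixel orientation axis from a structure tensor field
#'
#' The eigenvector of the larger structure-tensor eigenvalue points along the
#' dominant gray-level gradient, i.e. *across* the stained stripes.  The
#' default `convention = "fiber"` therefore reports that axis rotated by 90
#' degrees — the stripe/fiber direction, which is what downstream comparisons
#' against diffusion-tensor orientations use.  `convention = "gradient"`
#' returns the literal dominant-gradient axis.
#'
#' Pixels whose tensor is isotropic (eigenvalue gap or gradient energy below
#' `tol`) have no defined orientation and are returned as `NA`.
#'
#' @param field List from [structure_tensor_field()].
#' @param convention `"fiber"` (default) or `"gradient"`.
#' @param tol Isotropy tolerance on the eigenvalue gap and trace.
#' @return Matrix of axis angles in degrees `[0, 180)`, `NA` where undefined.
#' @export
st_orientation <- function(field, convention = c("fiber", "gradient"),
                           tol = 1e-12) {
  convention <- match.arg(convention)
  # major-eigenvector axis of [[fxx, fxy], [fxy, fyy]]:
  # 2*phi = atan2(2 fxy, fxx - fyy)
  phi_grad <- rad2deg(0.5 * atan2(2 * field$fxy, field$fxx - field$fyy)) %% 180
  undefined <- (field$lambda1 - field$lambda2) <= tol |
    (field$lambda1 + field$lambda2) <= tol
  phi <- if (convention == "fiber") (phi_grad + 90) %% 180 else phi_grad
  phi[undefined] <- NA_real_
  phi
}

#' Full structure-tensor orientation analysis of one section
#'
#' Convenience wrapper chaining [image_gradient()], [structure_tensor_field()]
#' and [st_orientation()], restricted to a validity mask.
#'
#' @inheritParams image_gradient
#' @param mask Logical matrix, `TRUE` for valid pixels; orientation is `NA`
#'   outside the mask.  Default: all valid.
#' @inheritParams st_orientation
#' @return List with `phi` (degrees, `NA` where undefined/masked),
#'   `coherence`, and the tensor field.
#' @export
section_orientation <- function(image, mask = NULL, sigma = 2,
                                kernel_size = 9,
                                convention = c("fiber", "gradient")) {
  convention <- match.arg(convention)
  gr <- image_gradient(image, sigma, kernel_size)
  fld <- structure_tensor_field(gr$fx, gr$fy, sigma, kernel_size)
  phi <- st_orientation(fld, convention)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(image)))
    phi[!mask] <- NA_real_
  }
  list(phi = phi, coherence = fld$coherence, field = fld)
}
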