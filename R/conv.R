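# Small-kernel 2D filtering with reflective boundaries.
#
# Image matrices are indexed [row, col]; x is the column coordinate and y the
# row coordinate throughout the package.

pad_reflect <- function(img, py, px) {
  nr <- nrow(img)
  nc <- ncol(img)
  stopifnot(py < nr, px < nc)
  ridx <- c(rev(seq_len(py)), seq_len(nr), nr - seq_len(py) + 1)
  cidx <- c(rev(seq_len(px)), seq_len(nc), nc - seq_len(px) + 1)
  img[ridx, cidx, drop = FALSE]
}

# Cross-correlation of `img` with kernel `k` (odd dimensions), reflective
# padding.  For the symmetric Gaussian this equals convolution; for the
# derivative taps the sign convention is chosen so that a ramp I(x, y) = x
# yields a positive x-response.
filter2_reflect <- function(img, k) {
  kr <- nrow(k)
  kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  py <- (kr - 1) / 2
  px <- (kc - 1) / 2
  padded <- pad_reflect(img, py, px)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * padded[i:(i + nr - 1), j:(j + nc - 1)]
    }
  }
  out
}

# 1-D Gaussian taps on offsets -h..h, and the matching derivative taps.
gaussian_taps <- function(sigma, size) {
  stopifnot(size %% 2 == 1, sigma > 0)
  u <- seq(-(size - 1) / 2, (size - 1) / 2)
  g <- exp(-u^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_deriv_taps <- function(sigma, size) {
  u <- seq(-(size - 1) / 2, (size - 1) / 2)
  (u / sigma^2) * gaussian_taps(sigma, size)
}

# Circular (wrap-around) convolution via FFT, used for texture synthesis
# where periodic boundaries are harmless.  Kernel is centered.
fft_filter_circular <- function(img, k) {
  nr <- nrow(img)
  nc <- ncol(img)
  kb <- matrix(0, nr, nc)
  kr <- nrow(k)
  kc <- ncol(k)
  ri <- ((seq_len(kr) - 1 - (kr - 1) / 2) %% nr) + 1
  ci <- ((seq_len(kc) - 1 - (kc - 1) / 2) %% nc) + 1
  kb[ri, ci] <- k
  Re(stats::fft(stats::fft(img) * stats::fft(kb), inverse = TRUE)) / (nr * nc)
}
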