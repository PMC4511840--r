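# Shared fixtures, built in code at test time.

# sinusoidal grating with stripes along `alpha_deg` (intensity constant along
# the axis, varying across it); wavelength in px chosen inside the
# structure-tensor kernel's valid scale regime
make_grating <- function(alpha_deg, n = 64, wavelength = 16) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  th <- alpha_deg * pi / 180
  0.5 + 0.4 * cos(2 * pi / wavelength * (-sin(th) * x + cos(th) * y))
}

# ground-truth tensor with principal axis `axis_deg` in-plane
make_inplane_tensor <- function(axis_deg, evals) {
  th <- axis_deg * pi / 180
  e1 <- c(cos(th), sin(th), 0)
  e2 <- c(-sin(th), cos(th), 0)
  e3 <- c(0, 0, 1)
  evals[1] * tcrossprod(e1) + evals[2] * tcrossprod(e2) +
    evals[3] * tcrossprod(e3)
}

# exact mono-exponential signals for a scheme (independent of simulate_dwi)
model_signals <- function(D, scheme, S0 = 1000) {
  S0 * exp(-scheme$bvals * rowSums((scheme$bvecs %*% D) * scheme$bvecs))
}

# naive O(N k^2) cross-correlation with reflective padding: the convolution
# oracle for the structure-tensor pipeline
naive_filter_reflect <- function(img, k) {
  nr <- nrow(img)
  nc <- ncol(img)
  kr <- nrow(k)
  kc <- ncol(k)
  py <- (kr - 1) / 2
  px <- (kc - 1) / 2
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1, 1 - idx, idx)
    ifelse(idx > n, 2 * n + 1 - idx, idx)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      acc <- 0
      for (i in seq_len(kr)) {
        for (j in seq_len(kc)) {
          rr <- reflect(r + i - 1 - py, nr)
          cc <- reflect(cl + j - 1 - px, nc)
          acc <- acc + k[i, j] * img[rr, cc]
        }
      }
      out[r, cl] <- acc
    }
  }
  out
}

# random multi-section voxel table for the statistics oracles
random_voxel_table <- function(n_sections = 5, n_per = 40, seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sections), function(s) {
    data.frame(
      section_id = s - 1,
      tissue = sample(c("WM", "GM"), n_per, replace = TRUE),
      diff = runif(n_per, 0, 90),
      fa = runif(n_per, 0, 1),
      md = runif(n_per, 2e-4, 1e-3),
      rd = runif(n_per, 1e-4, 9e-4),
      stain = runif(n_per),
      ampl1 = runif(n_per), ampl2 = runif(n_per), ampl3 = runif(n_per),
      width1 = runif(n_per), width2 = runif(n_per), width3 = runif(n_per)
    )
  }))
}

# the full phantom study is expensive; run it once per test session
.phantom_cache <- new.env(parent = emptyenv())
get_phantom_study <- function() {
  if (is.null(.phantom_cache$res)) {
    .phantom_cache$res <- run_phantom_study(seed = 1)
  }
  .phantom_cache$res
}
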