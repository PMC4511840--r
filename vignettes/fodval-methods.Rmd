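---
title: "Methods: histology-based validation of diffusion tensor orientations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histology-based validation of diffusion tensor orientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are.  Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The validation problem

A diffusion tensor is the simplest voxel model of water diffusion: one
dominant axis plus two orthogonal minor axes.  Whether its principal
eigenvector tracks the real fiber architecture, and whether FA/MD/RD
track microstructure, can be validated by comparing a diffusion
acquisition of a tissue block against myelin-stained sections of the same
block.  The package implements both arms of that comparison and the
statistics joining them, and ships a digital phantom so every stage runs
against known ground truth.

All in-plane orientations in the package are *axial* — an axis and its
opposite are the same thing — and live in degrees in [0, 180), measured
from the +x (column) axis toward +y (row).  Keeping one convention
everywhere is what prevents the classic 90° bookkeeping error; the one
place a 90° rotation is intentional is documented below.

## Histology arm

**Structure tensor.** The image gradient is computed by convolution with
the partial derivatives of a rotationally symmetric Gaussian (size 9 px,
σ = 2 px); the structure tensor entries are the pointwise gradient
products smoothed with the same unit-sum Gaussian.  Boundaries are
handled by reflection, and gradient products below numerical noise are
treated as isotropic (orientation undefined) rather than amplified by
`atan2`.  The *same* kernel is used for differentiation and for smoothing
the products; using a separate integration scale is a well-known variant,
but a single kernel is the configuration the rest of the defaults were
chosen around.

**Fiber vs gradient axis.** The major eigenvector of a structure tensor
points along the dominant *gradient*, i.e. across the stained stripes.
Since every downstream comparison treats the histological orientation as
the *fiber* axis, `st_orientation()` returns the major-eigenvector axis
rotated by 90° by default (`convention = "fiber"`); the literal
eigenvector axis remains available as `convention = "gradient"`.

**Scale regime.** The sampled derivative-of-Gaussian taps are
direction-dependent near the Nyquist limit: stripes of wavelength 8 px
incur a bias of ~2.5°, while at 16 px the error is below 0.7°.  The
orientation-recovery tests therefore use 16 px gratings; for real
sections the practical rule is the same — features at or below the kernel
scale are not reliably oriented, and a coarser pyramid level should be
used instead.

**Voxel FODs.** Sections are tiled into voxel-sized subimages (340 μm
default for real data; see below for the phantom).  Per tile:
staining intensity = 1 − mean gray level over valid pixels; a 180-bin,
1°-resolution orientation histogram; circular smoothing with a 23° FWHM
Gaussian (mass-conserving, wrap at 180°).  The histogram is normalized by
the count of valid, orientation-defined pixels — not the total tile pixel
count — so that damage holes do not deflate amplitudes; the valid-pixel
fraction is carried as its own column, and the literal total-pixel
divisor is available as a switch.  Voxels with valid fraction < 0.05 or
staining intensity < 0.02 are discarded and tallied (damage /
no-stained-material stages).

**Greedy axial von Mises mixture.** Up to three components are fitted by:
take the histogram argmax as center θ and its height as amplitude d (ties
break to the lowest bin); fit the concentration κ by bounded 1-D
minimization (tolerance 1e-6, κ ∈ [0.01, 100]) of the squared error over
a circular ±42° window, with the component scaled so its peak equals d;
subtract and repeat, without clipping negative residuals.  Greediness
guarantees non-increasing amplitudes; the first θ is the voxel's primary
orientation.  Component width is 1 − κ/κ_max with κ_max the maximum over
all components of the analysis run (a fixed κ_max can be supplied for
cross-run comparability).  This greedy scheme — rather than EM — is
deliberate: it is transparent, deterministic, and the third component is
known to be unreliable, so it is emitted but consumers decide whether to
use it.

## DTI arm

Tensors are fitted by ordinary least squares on log-signals (a weighted
variant, `method = "wls"` with squared-fitted-signal weights, is
available; OLS is the default), with non-positive signals clamped to the smallest
positive observation and flagged.  FA/MD/RD use the standard eigenvalue
definitions.  The principal eigenvector is projected into the sectioning
plane by discarding z; Φ_DT is the axis of the projection, the
out-of-plane angle is asin(|w_z|), and voxels beyond 45° (inclusive
threshold: 45.0 is retained) are excluded and tallied.  Eigenvalue ties
(λ₁ ≈ λ₂) flag the voxel as degenerate rather than silently picking an
eigenvector.

SNR is estimated as mean tissue signal over the standard deviation in a
signal-free corner of the b = 0 volumes.  On magnitude data that corner
is Rayleigh-distributed, so this conventional estimator overstates the
underlying Gaussian-noise SNR by 1/√(2 − π/2) ≈ 1.53.  The default
reproduces the conventional (uncorrected) estimate;
`correction = "rayleigh"` divides the corner SD by √(2 − π/2), and the
phantom calibration test uses it to verify that simulated noise at
SNR 50 is recovered within 10%.

## Alignment

Section-to-slice alignment is a planar similarity transform — one
rotation, one isotropic scale, two translations — stored canonically as
translate∘rotate∘scale about the origin in a 3×3 homogeneous matrix
(any GUI-composed similarity is representable in this form, so the
composition-order ambiguity is moot for consumers).  Landmark pairs are
fitted in closed form: with points as complex numbers the model
w = c·z + t is linear, so the least-squares similarity is exact, and two
distinct pairs pin all four degrees of freedom.  Sections are paired with
slices by rounding the section center to the nearest slice
(`round(m · spacing / thickness)`); with 300 μm section spacing against
340 μm slices this doubles a slice about every 8–9 sections.  A manual
override table can be passed wherever an assignment is consumed.

## Statistics

The axis-angle difference d(a, b) = min(|a − b|, 180 − |a − b|) is a
metric on the half-circle (the test suite checks the triangle inequality
exhaustively on the 1° grid).  Summaries report mean, median, SE and
1.96·SE per tissue and per FA bin (default width 0.05; bins under 100
voxels flagged suppressed); an optional 50° truncation reproduces the
truncated-mean view that separates the cortical 90° mismatch population
from the rest.  Correlations and regressions are computed per section and
pooled weighted by voxel count, because staining intensity varies between
sections for technical reasons; complete cases are taken per variable
pair.  Pearson correlation is used.

**Generalized Pareto tail.** The difference distribution is fitted with a
GPD (location 0) by maximum likelihood, and goodness of fit reported as
R² between the fitted per-1°-bin mass and the empirical histogram.  Plain
MLE is the default.  Because axis-angle differences cannot exceed 90°, a
hard-truncated sample biases the plain shape estimate downward
(a GPD(0.3, 8) sample truncated at 90 fits to shape ≈ 0.22); the
`upper = 90` option conditions the likelihood on the bounded support,
which removes that bias — the parameter-recovery test demonstrates
shape within 0.05 and scale within 0.5 at n = 50,000.  Use `upper = 90`
when the sample genuinely is bounded angular data; the plain fit
reproduces the conventional analysis.

**The 45° averaging bound.** If a tensor in a fiber crossing behaves like
an equal-weight axial average of the two fiber axes, its deviation from
either axis is at most 45°, approached as the crossing nears
orthogonality (where the axial mean is undefined by symmetry).
`scripts/acceptance.R` verifies this by brute force over the 1° grid of
axis pairs, approaching the orthogonal ties at half-degree resolution and
extrapolating the exactly-linear approach to its limit.  Differences
beyond 45° therefore diagnose something other than crossing-averaging —
in the phantom, the radial-tensor cortex.

## The digital phantom

The generator is the package's study-conditions definition, not a tuning
dial.  Defaults: 8 sections of 256 × 256 px at 2 μm/px (0.512 mm field of
view), an 8 × 8 × 8 voxel grid, 60 diffusion directions from
electrostatic repulsion on the whole sphere (minimal 1/r Coulomb energy,
BFGS from seeded restarts, deterministic and lexicographically ordered)
plus 6 b = 0 volumes at b = 3000 s/mm², Rician noise at SNR 50
(σ = S0/SNR applied independently per measurement), and section noise
SD 0.02 gray levels.

Four horizontal bands cover the three qualitative regimes plus
background: a unidirectional WM pathway (axis 30°, density 0.9,
λ = (1.7, 0.3, 0.3)·10⁻³ mm²/s), a WM 60° crossing (axes 0°/60°, equal
weights, density 0.6, λ = (1.4, 0.8, 0.45)·10⁻³), and a GM ribbon whose
texture is tangential (0°) while the tensor principal axis is overridden
to the radial 90° (density 0.3, λ = (1.1, 0.9, 0.85)·10⁻³).  Densities
and eigenvalues were chosen once so that staining intensity increases
with FA and decreases with MD across regions — the sign structure
expected when myelin density drives both — and are not revisited.

Stripe textures are white noise filtered with an elongated oriented
Gaussian (σ 12 × 1.5 px, aspect 8), pushed through a smooth squashing
function and scaled by fiber density; background is blank white.  Same
seed and geometry give bit-identical images and volumes.

**Phantom voxel size.** The analysis voxel for the phantom is 64 μm, not
340 μm: at the phantom's 0.512 mm field of view, 340 μm voxels would
leave ~1 voxel per section and no statistics to compute.  64 μm gives
8 × 8 voxels per section (32 × 32 px tiles, ample for stable histograms)
and 384 analyzed voxels across 8 sections — the problem size used by the
end-to-end tests and the worked example.  340 μm remains the default in
`pipeline_config()` for real acquisitions.

**What the phantom does not emulate.** Tears, ripples and vessel holes
(damage enters only through masks), susceptibility/eddy distortions
(volumes are ingested as already corrected), multi-compartment or
kurtosis signal behavior, staining chemistry, and between-section
staining drift.  Passing end-to-end tests therefore demonstrates that the
pipeline's machinery is correct and its statistics well-calibrated on
tensor-model data with Rician noise — not that real tissue obeys the
tensor model, which is precisely the question such a validation study
asks of real data.

## Numerical choices and degenerate inputs

- Histogram argmax ties break to the lowest bin index; mixture residuals
  are not clipped at zero.
- The axial von Mises density is normalized so its 180 one-degree bin
  values sum to 1; κ = 0 is exactly uniform.
- All-zero histograms yield an empty component list and a flagged voxel;
  all-equal difference samples refuse a Pareto fit.
- Isotropic structure tensors and purely through-plane eigenvectors yield
  `NA` orientations, which propagate to exclusion tallies rather than to
  fabricated angles.
- `x %% 180` can return exactly 180 for tiny negative inputs in IEEE
  arithmetic; the normalizer folds that case to 0.
- Random-restart optimizers (`electrostatic_directions`) and all noise
  draws are driven by explicit seeds; identical inputs give bytewise
  identical outputs.

## Limitations

Structure tensors are 2D: through-plane fibers appear as dots and are
handled by exclusion (the 45° filter), not modeling.  The greedy mixture
cannot separate components closer than roughly the smoothing window, and
its third component is unreliable by construction.  The GPD R² compares
binned mass, so it rewards tail shape, not mode placement — a bimodal
difference distribution (the cortical case) is a poor Pareto candidate
and shows up as a low or negative R², which is reported as computed.
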