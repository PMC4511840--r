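# fodval

Voxel-wise validation of diffusion tensor imaging (DTI) against
high-resolution myelin histology of the same tissue.

## The problem

DTI models water diffusion in each voxel as a single Gaussian process and
summarizes it by a 3×3 tensor **D**; its principal eigenvector is read as
the local fiber direction and its eigenvalues λ₁ ≥ λ₂ ≥ λ₃ yield the
scalar maps

- MD = (λ₁ + λ₂ + λ₃)/3 (mean diffusivity),
- RD = (λ₂ + λ₃)/2 (radial diffusivity),
- FA = √(3/2) · √Σ(λᵢ − MD)² / √Σλᵢ² (fractional anisotropy).

How faithfully these quantities reflect the underlying fiber architecture
— especially in crossing regions and in cortical gray matter — is an
empirical question that can be answered by comparing DTI of a tissue block
against high-resolution myelin-stained sections of the same block.  This
package implements that comparison as a tested pipeline, for
neuroanatomists and diffusion-MRI methodologists:

1. **Histology arm** — per-pixel fiber orientations from the structure
   tensor (smoothed outer product of the image gradient; eigen-analysis
   gives the stripe axis φ_ST per pixel), pooled per voxel-sized tile into
   a 180-bin fiber orientation distribution (FOD), smoothed (23° FWHM) and
   decomposed greedily into up to three axial von Mises components
   f(x) ∝ exp(κ·cos 2(x − θ)); the first center is the voxel's primary
   histological orientation.
2. **DTI arm** — log-linear least-squares tensor fit, FA/MD/RD, principal
   eigenvector projected into the sectioning plane (Φ_DT), voxels more
   than 45° out of plane excluded.
3. **Alignment** — planar similarity transforms (rotation, isotropic
   scale, translation) in homogeneous coordinates, landmark least-squares
   estimation, and a rounding rule pairing sections with slices.
4. **Statistics** — axis-angle differences d(Φ_DT, Φ_ST) =
   min(|ΔΦ|, 180 − |ΔΦ|), per-tissue and FA-binned summaries with
   1.96·SE intervals, generalized Pareto fits to the difference
   distribution, and section-wise voxel-count-weighted correlations and
   regression R².
5. **Digital phantom** — co-registered synthetic sections and DWI volumes
   with known ground truth (oriented stripe textures; mono-exponential
   tensor signals with Rician noise; electrostatic-repulsion gradient
   directions), so the whole pipeline is testable end to end, including a
   cortical regime where the stained texture is tangential while the
   tensor is radial.

## Worked example

```r
library(fodval)

res <- run_phantom_study(seed = 1)   # ~1–2 minutes
print(res$report)
```

```
Histology-DTI validation report (N = 384 voxels)
  overall angular difference: mean 36.07 deg, median 20.52 deg
  GM: mean 81.68, median 82.93 (n = 128)
  WM: mean 13.27, median 5.94 (n = 256)
  GPD GM: shape -59.520 scale 5343.130 R^2 -13.738
  GPD WM: shape 0.396 scale 8.611 R^2 0.887
  regression R^2 (FA) = 0.795
  regression R^2 (MD) = 0.781
  regression R^2 (RD) = 0.797
```

Reading the numbers: the white-matter median difference of 5.9° is
dominated by the unidirectional pathway region (median < 5°), inflated by
the 60° fiber-crossing band where the tensor cannot represent two axes.
The gray-matter band was built with tangential stained texture and a
radial tensor override, so its differences cluster near 90° — the
characteristic cortical mismatch — which drags its mean to 81.7° and
makes a Pareto tail model inappropriate there (negative R², reported, not
hidden).  The white-matter difference distribution is Pareto-like
(R² ≈ 0.89 at this small sample).  Staining intensity correlates
positively with FA (+0.87) and negatively with MD (−0.86) across regions,
the expected sign structure when myelin density drives both stain
darkness and anisotropy; the histological variables explain ≈ 80% of
FA/MD/RD variance in this noise-controlled phantom.

Plots: `plot_diff_histogram(res$records)`,
`plot_fa_binned(res$records)`, `plot_fod_fit()` for single-voxel FODs;
`tidy()`/`glance()` work on the Pareto fits.

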