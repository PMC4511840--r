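Package: fodval
Title: Voxel-Wise Validation of Diffusion Tensor Imaging Against
    Histological Fiber Orientations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating diffusion tensor imaging (DTI) against
    high-resolution myelin-stained histology of the same tissue.  Computes
    per-pixel fiber orientations from section images with the structure
    tensor method, aggregates them into voxel-level fiber orientation
    distributions fitted with greedy mixtures of axial von Mises
    components, fits diffusion tensors to diffusion-weighted volumes
    (FA/MD/RD, in-plane principal orientations, out-of-plane filtering),
    aligns sections to slices with planar similarity transforms, and
    quantifies orientation agreement and microstructure correlations with
    axial circular statistics, generalized Pareto tail fits, and
    section-wise weighted correlation and regression summaries.  A fully
    parametric digital phantom generates co-registered synthetic sections
    and diffusion volumes with known ground truth so the entire pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
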