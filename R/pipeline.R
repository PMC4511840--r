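#' Run the full phantom validation study end to end
#'
#' Generates the default three-regime phantom (8 sections of 256 x 256 px
#' at 2 um/px, a matched 8 x 8 x 8 diffusion volume at 64 um voxels,
#' 60 directions at b = 3000 s/mm^2 plus 6 b = 0, Rician noise at the
#' requested SNR), runs the histology arm (structure tensors, voxel FODs,
#' von Mises mixtures) and the DTI arm (tensor fit, scalar maps, in-plane
#' projection), joins them, and computes the statistical report.
#'
#' The 64 um analysis voxel keeps the phantom at desk scale while
#' preserving the pipeline's structure; for real acquisitions the voxel
#' size is a [pipeline_config()] parameter (340 um default).
#'
#' @param seed Integer seed controlling every random draw.
#' @param snr Diffusion SNR (default 50; `Inf` for noiseless).
#' @param n_sections Number of sections/slices (default 8).
#' @param img_px Section image side in pixels (default 256).
#' @param pixel_size_um Histology pixel size (default 2).
#' @param voxel_size_um Analysis voxel size (default 64).
#' @param geometry Phantom geometry; default [default_phantom_geometry()].
#' @param noise_sd Section gray-level noise (default 0.02).
#' @return List with `records` (joined voxel table), `report`
#'   (a [validation_report()]), `fods`, `tensors`, `truth`, `sections`,
#'   and `scheme`.
#' @export
run_phantom_study <- function(seed = 1, snr = 50, n_sections = 8,
                              img_px = 256, pixel_size_um = 2,
                              voxel_size_um = 64,
                              geometry = default_phantom_geometry(
                                fov_mm = img_px * pixel_size_um / 1000),
                              noise_sd = 0.02) {
  n_vox <- round(img_px * pixel_size_um / voxel_size_um)
  scheme <- make_scheme(seed = seed)
  sim <- simulate_dwi(geometry, scheme, n_x = n_vox, n_y = n_vox,
                      n_z = n_sections, voxel_size_um = voxel_size_um,
                      snr = snr, seed = seed)
  sections <- lapply(seq_len(n_sections), function(s) {
    render_section(geometry, img_px, img_px, pixel_size_um,
                   noise_sd = noise_sd, seed = seed + s)
  })
  fods <- dplyr::bind_rows(lapply(seq_len(n_sections), function(s) {
    section_fods(sections[[s]], pixel_size_um = pixel_size_um,
                 voxel_size_um = voxel_size_um, section_id = s - 1L)
  }))
  fods <- add_component_widths(fods)
  tensors <- fit_dti_volume(sim$dwi, scheme, sim$tissue)
  records <- build_voxel_table(fods, tensors)
  report <- validation_report(records)
  list(records = records, report = report, fods = fods, tensors = tensors,
       truth = sim$truth, sections = sections, scheme = scheme, sim = sim)
}
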