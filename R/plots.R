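#' Histogram of angular differences with the fitted Pareto overlay
#'
#' @param records Voxel table with `diff` and `tissue` columns.
#' @param bin_width Histogram bin width in degrees.
#' @return A ggplot object.
#' @export
plot_diff_histogram <- function(records, bin_width = 1) {
  fits <- lapply(split(records$diff, records$tissue), function(d) {
    if (length(d) >= 100 && stats::sd(d) > 0) fit_gpd(d, bin_width) else NULL
  })
  overlay <- dplyr::bind_rows(lapply(names(fits), function(tn) {
    f <- fits[[tn]]
    if (is.null(f)) return(NULL)
    tibble::tibble(tissue = tn,
                   x = utils::head(f$bin_edges, -1) + bin_width / 2,
                   density = f$fitted / bin_width)
  }))
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = bin_width, boundary = 0, fill = "grey70", color = NA) +
    ggplot2::facet_wrap(~tissue, scales = "free_y") +
    ggplot2::labs(x = "angular difference (degrees)", y = "density")
  if (nrow(overlay) > 0) {
    p <- p + ggplot2::geom_line(
      data = overlay, ggplot2::aes(x = .data$x, y = .data$density),
      linetype = "dashed", linewidth = 0.7)
  }
  p
}

#' FA-binned angular-difference curves with confidence ribbons
#'
#' Mean angular difference per FA bin and tissue type, with 1.96 SE
#' confidence half-widths; bins below the display threshold are omitted.
#'
#' @param records Voxel table with `diff`, `fa`, `tissue` columns.
#' @param fa_bin_width,min_bin_n Binning parameters (defaults 0.05, 100).
#' @return A ggplot object.
#' @export
plot_fa_binned <- function(records, fa_bin_width = 0.05, min_bin_n = 100) {
  curves <- summarize_differences(records, by = c("tissue", "fa_bin"),
                                  fa_bin_width = fa_bin_width,
                                  min_bin_n = min_bin_n)
  curves <- dplyr::filter(curves, !.data$suppressed)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$fa_bin + fa_bin_width / 2,
                               y = .data$mean, color = .data$tissue)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$ci95,
                   ymax = .data$mean + .data$ci95, fill = .data$tissue),
      alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::labs(x = "FA", y = "mean angular difference (degrees)",
                  size = "voxels")
}

#' Plot a fitted voxel orientation histogram and its mixture components
#'
#' @param h Smoothed 180-bin histogram.
#' @param fit Component table from [fit_von_mises_mixture()].
#' @return A ggplot object.
#' @export
plot_fod_fit <- function(h, fit) {
  bins <- 0:179
  df <- tibble::tibble(x = bins, mass = h)
  comp <- dplyr::bind_rows(lapply(seq_len(nrow(fit)), function(k) {
    f <- axial_von_mises_pdf(bins, fit$theta[k], fit$kappa[k])
    tibble::tibble(x = bins, component = factor(k),
                   mass = fit$amplitude[k] * f /
                     axial_von_mises_pdf(fit$theta[k], fit$theta[k],
                                         fit$kappa[k]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mass)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(color = .data$component)) +
    ggplot2::labs(x = "orientation (degrees)", y = "histogram mass")
}

#' FA-binned curve plot for a validation report
#' @param object A [validation_report()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  plot_fa_binned_report(object)
}

plot_fa_binned_report <- function(report) {
  curves <- dplyr::filter(report$fa_curves, !.data$suppressed)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$fa_bin, y = .data$mean,
                               color = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::labs(x = "FA", y = "mean angular difference (degrees)")
}
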