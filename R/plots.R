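# Plotting: violin plots of the cohort comparison and a quick sagittal
# projection of a tractogram for visual inspection.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of the cohort comparison
#'
#' One panel per bundle; violins per segmentation method with per-subject
#' points and grey lines pairing the two measurements of each subject.
#'
#' @param object A [compare_cohort()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bundle_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, dplyr::all_of(object$methods),
                              names_to = "method", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       color = "grey70", linewidth = 0.3) +
    ggplot2::geom_violin(ggplot2::aes(fill = .data$method), alpha = 0.5,
                         trim = FALSE) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$bundle), nrow = 1) +
    ggplot2::labs(x = NULL, y = object$metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Sagittal projection of a tractogram
#'
#' Plots the (y, z) projection of (a sample of) the streamlines, colored by
#' label when labels are present. A quick-look tool for phantoms and
#' segmented bundles.
#'
#' @param t A [tractogram()].
#' @param max_streamlines Cap on plotted streamlines (sampled
#'   deterministically).
#' @return A ggplot object.
#' @export
plot_tractogram <- function(t, max_streamlines = 300) {
  stopifnot(inherits(t, "tractogram"))
  n <- n_streamlines(t)
  keep <- if (n > max_streamlines) {
    as.integer(round(seq(1, n, length.out = max_streamlines)))
  } else {
    seq_len(n)
  }
  df <- as_tibble(subset_tractogram(t, keep))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z,
                                        group = .data$id))
  p <- if ("label" %in% names(df)) {
    p + ggplot2::geom_path(ggplot2::aes(color = .data$label),
                           alpha = 0.4, linewidth = 0.2)
  } else {
    p + ggplot2::geom_path(alpha = 0.4, linewidth = 0.2)
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = "y (posterior - anterior, mm)",
                  y = "z (inferior - superior, mm)") +
    ggplot2::theme_minimal()
}
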