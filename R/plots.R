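#' Heatmap of an AUROC table
#'
#' @param object An `auroc_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auroc_table <- function(object, ...) {
  df <- tidy.auroc_table(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$target_cluster, .data$reference_cluster,
                                   fill = .data$auroc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "AUROC") +
    ggplot2::labs(x = "target cluster", y = "reference cluster",
                  title = attr(object, "direction")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Spatial map of cell calls
#'
#' Plots cell positions colored by called cluster, faceted by slice; failed
#' calls are greyed out.
#'
#' @param object A `spatial_calls` tibble from [call_cells()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(data = dplyr::filter(object, !.data$passed),
                        color = "grey80", size = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$passed),
                        ggplot2::aes(color = .data$best_cluster), size = 0.4) +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::guides(color = ggplot2::guide_legend(
      override.aes = list(size = 2), ncol = 2)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", color = "cluster") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Global-versus-local marker discrimination plot
#'
#' Scatter of on-target (global) against best-vs-next (local) marker AUROCs,
#' one point per marker set; the gap between the two axes is the signature of
#' marker sets that identify a cluster globally but cannot separate it from
#' its closest neighbor.
#'
#' @param marker_stats Tibble from [marker_local_aurocs()].
#' @return A ggplot object.
#' @export
plot_marker_gap <- function(marker_stats) {
  ggplot2::ggplot(marker_stats,
                  ggplot2::aes(.data$global_auroc, .data$local_auroc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "global (one-vs-all) marker AUROC",
                  y = "local (best-vs-next) marker AUROC") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Coordinated-expression subsampling curves
#'
#' @param curves Tibble from [subsample_curves()].
#' @return A ggplot object.
#' @export
plot_subsample_curves <- function(curves) {
  df <- curves |>
    dplyr::filter(!.data$skipped) |>
    tidyr::pivot_longer(c("mean_rho", "mean_percentile", "prop_top"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fraction of pairs retained", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}
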