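# ggplot2 visualizations.

#' Plot dF/F traces
#'
#' Stacked single-cell traces with stimulus epochs shaded — the standard way
#' to eyeball response patterns.
#'
#' @param normalized A `ca_normalized` (or `ca_recording`, plotted raw).
#' @param cells Optional cell ids to plot (default: first `n_max`).
#' @param n_max Maximum number of cells to facet (default 12).
#' @return A ggplot object.
#' @export
plot_traces <- function(normalized, cells = NULL, n_max = 12) {
  df <- tidy_traces(normalized)
  ids <- cells %||% utils::head(unique(df$cell_id), n_max)
  df <- dplyr::filter(df, .data$cell_id %in% ids)
  proto <- normalized$protocol
  shade <- tibble::tibble(
    stimulus = c("GnRH", "KCl"),
    xmin = c(proto$gnrh[1], proto$kcl[1]),
    xmax = c(proto$gnrh[2], proto$kcl[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$stimulus),
                       alpha = 0.25, inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cell_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = if (inherits(normalized, "ca_normalized"))
                    expression(Delta * F / F) else "F (a.u.)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise correlation matrix
#'
#' @param R Correlation matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(R) {
  df <- tibble::as_tibble(R, rownames = "cell_a") |>
    tidyr::pivot_longer(-"cell_a", names_to = "cell_b", values_to = "r")
  df$cell_a <- factor(df$cell_a, levels = rownames(R))
  df$cell_b <- factor(df$cell_b, levels = colnames(R))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_a, .data$cell_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Group summaries with per-animal points
#'
#' @param experiment A `ca_experiment` from [run_experiment()].
#' @param metrics Metrics to facet (default: the main published ones).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(experiment,
                               metrics = c("frac_responder",
                                           "frac_spontaneous",
                                           "frac_oscillatory",
                                           "mean_mif", "mean_auc",
                                           "mean_n_osc")) {
  stopifnot(inherits(experiment, "ca_experiment"))
  df <- experiment$animals |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7, size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot ca_recording
#' @export
autoplot.ca_recording <- function(object, ...) plot_traces(object, ...)

#' @method autoplot ca_normalized
#' @export
autoplot.ca_normalized <- function(object, ...) plot_traces(object, ...)

#' @method autoplot ca_experiment
#' @export
autoplot.ca_experiment <- function(object, ...) plot_group_summary(object, ...)
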