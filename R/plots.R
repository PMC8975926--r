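#' Accuracy grid plot for cross-validation results
#'
#' Tile heat map of mean accuracy per selection method x classifier, the
#' standard display for comparing the selection / classifier grid against
#' the 50% balanced baseline.
#'
#' @param object a `cv_result` tibble.
#' @param metric `"accuracy"` or `"auroc"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cv_result <- function(object, metric = c("accuracy", "auroc"), ...) {
  metric <- match.arg(metric)
  grid <- summarize_cv(object)
  col <- if (metric == "accuracy") "mean_accuracy" else "mean_auroc"
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$classifier,
                                     y = .data$selection,
                                     fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[col]])), colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0.4, 1)) +
    ggplot2::labs(x = "classifier", y = "feature selection",
                  fill = paste("mean", metric))
}

#' Fisher cutoff-scan heat map
#'
#' Tiles of log10 p across the phenotype x anxiety cutoff grid; values are
#' capped at -10 for display, masked cells are blanked.
#'
#' @param object a `cutoff_heatmap`.
#' @param cap display floor on log10 p (default -10).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cutoff_heatmap <- function(object, cap = -10, ...) {
  dat <- dplyr::mutate(object,
                       shown = pmax(.data$log10_p, cap),
                       shown = ifelse(.data$masked, NA_real_, .data$shown))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$x_cutoff),
                                    y = factor(.data$y_cutoff),
                                    fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "grey85") +
    ggplot2::labs(x = "phenotype cutoff", y = "anxiety score cutoff",
                  fill = "log10 p")
}

#' Phase-shift distribution of chronotype fits
#'
#' @param object a `chronotype_fits` tibble.
#' @param ... unused.
#' @return a ggplot (per-gene histogram of fitted phase shifts).
#' @export
autoplot.chronotype_fits <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase_shift_h)) +
    ggplot2::geom_histogram(binwidth = 0.5, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "phase shift (h, positive = advanced)", y = "subjects")
}

#' Bootstrap edge-confidence plot for an MI network
#'
#' @param object an `mi_network`.
#' @param top_n edges shown (default 20, by confidence).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mi_network <- function(object, top_n = 20, ...) {
  ed <- utils::head(object$edges, top_n) |>
    dplyr::mutate(pair = paste(.data$node1, .data$node2, sep = " - "))
  ggplot2::ggplot(ed, ggplot2::aes(x = stats::reorder(.data$pair,
                                                      .data$confidence),
                                   y = .data$confidence,
                                   fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bootstrap edge confidence",
                  fill = "kept (full data)")
}
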