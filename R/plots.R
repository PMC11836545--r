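#' Blood-vs-nerve clone overlap scatter plot
#'
#' One dot per clone key, blood frequency on x, nerve frequency on y,
#' both on log axes with zero frequencies pinned to a pseudo-frequency
#' floor so restricted clones remain visible along the axes. Dotted lines
#' mark the HEC cut-off.
#'
#' @param records Overlap tibble from [pair_overlap()].
#' @param hec_threshold Cut-off drawn as dotted lines (default 0.005).
#' @param pseudo Pseudo-frequency for zero values (default 1e-5).
#' @return A ggplot object.
#' @export
plot_overlap <- function(records, hec_threshold = 0.005, pseudo = 1e-5) {
  df <- mutate(records,
               x = pmax(.data$freq_blood, pseudo),
               y = pmax(.data$freq_nerve, pseudo))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = hec_threshold, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = hec_threshold, linetype = "dotted") +
    ggplot2::scale_x_log10(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::scale_y_log10(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "frequency in blood", y = "frequency in nerve",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rank-abundance plot of one or more repertoires
#'
#' @param clones A clone tibble (faceted by `sample_id` when present).
#' @param hec_threshold HEC cut-off line (default 0.005).
#' @return A ggplot object.
#' @export
plot_repertoire <- function(clones, hec_threshold = 0.005) {
  grouping <- intersect("sample_id", names(clones))
  df <- clones |>
    group_by(across(all_of(grouping))) |>
    arrange(desc(.data$frequency), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$frequency)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = hec_threshold, linetype = "dotted") +
    ggplot2::scale_y_log10(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "clone rank", y = "clone frequency") +
    ggplot2::theme_minimal()
  if (length(grouping)) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id))
  p
}

#' @rdname dynamic_threshold
#' @param object,x A `threshold_result`.
#' @param ... Ignored.
#' @export
autoplot.threshold_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$distance, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::labs(x = "CDR3 Hamming distance", y = "density",
                  title = sprintf("threshold = %d (%s)",
                                  object$threshold, object$modality)) +
    ggplot2::theme_minimal()
  if (!is.na(object$valley)) {
    p <- p + ggplot2::geom_vline(xintercept = object$valley,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @rdname detection_curve
#' @param object A `detection_curve` tibble.
#' @param ... Ignored.
#' @export
autoplot.detection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cells of the clone in the sample",
                  y = "detection probability") +
    ggplot2::theme_minimal()
}
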