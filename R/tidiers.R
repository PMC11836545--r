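#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` returns the per-element table of a result object (density grid
#' of a `threshold_result`; edge list of a `clone_graph`); `glance()`
#' returns a one-row summary.
#'
#' @param x A `threshold_result` or `clone_graph`.
#' @param ... Ignored.
#' @return A tibble.
#' @name nervetcr-tidiers
NULL

#' @rdname nervetcr-tidiers
#' @export
tidy.threshold_result <- function(x, ...) {
  x$grid
}

#' @rdname nervetcr-tidiers
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(threshold = x$threshold, valley = as.numeric(x$valley),
         modality = x$modality, n_distances = x$n_distances)
}

#' @rdname nervetcr-tidiers
#' @export
tidy.clone_graph <- function(x, ...) {
  x$edges
}

#' @rdname nervetcr-tidiers
#' @export
glance.clone_graph <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_clusters = x$n_clusters, threshold = x$threshold,
         n_nerve_linked = if (is.null(x$n_nerve_linked)) NA_integer_
                          else x$n_nerve_linked)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
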