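#' Hamming distance between CDR3 amino-acid sequences
#'
#' Position-wise mismatch count between equal-length sequences; undefined
#' (`NA`) for unequal lengths -- pure Hamming semantics, no alignment.
#' Vectorised over pairs (inputs recycle like arithmetic).
#'
#' @param a,b Character vectors of amino-acid sequences.
#' @return Integer vector of distances, `NA` where lengths differ.
#' @examples
#' hamming_distance("CASSLGTDTQYF", "CASSPGTDTQYF")  # 1
#' hamming_distance("CASS", "CASSL")                 # NA
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  as.integer(mapply(hamming1, a, b, USE.NAMES = FALSE))
}

#' All pairwise CDR3 distances for a clone set
#'
#' Evaluates every unordered pair of clones. Pairs of unequal CDR3 length
#' are recorded with `NA` distance (undefined) and are excluded from
#' density estimation and clustering. O(n^2) in the number of clones.
#'
#' @param clones A clone tibble (column `cdr3_aa`), at least one row.
#' @param include_undefined Keep unequal-length pairs as `NA` rows
#'   (default TRUE).
#' @return A tibble `i`, `j`, `distance` (row indices into `clones`),
#'   with attribute `lengths` (per-clone CDR3 lengths).
#' @export
distance_set <- function(clones, include_undefined = TRUE) {
  if (nrow(clones) == 0) contract_error("distance_set() needs at least one clone")
  ds <- as_tibble(cpp_hamming_pairs(clones$cdr3_aa, include_undefined))
  attr(ds, "lengths") <- nchar(clones$cdr3_aa)
  ds
}

#' Dynamic CDR3 clustering threshold from the distance density
#'
#' A Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
#' evaluated on a grid of step 0.05 over `[0, max distance]`) is fitted to
#' the defined pairwise Hamming distances of a sample. Repertoires give a
#' bimodal distance distribution -- a low mode of related clones and a high
#' mode of unrelated ones -- and the grid minimum between the two highest
#' density peaks is the clustering threshold, floored at 3 amino acids.
#' When fewer than two peaks are found the fallback threshold of 3 is
#' used.
#'
#' @param distances A [distance_set()] tibble or an integer vector of
#'   distances; at least 2 defined distances are required.
#' @param min_threshold Threshold floor (default 3).
#' @param grid_step Density grid step (default 0.05).
#' @param min_bandwidth Lower bound on the kernel bandwidth (default 1).
#'   Hamming distances sit on an integer lattice; Silverman's rule on such
#'   strongly discrete data can under-smooth below the lattice spacing and
#'   turn every integer into its own density peak. Flooring the bandwidth
#'   at the spacing recovers the intended coarse bimodal shape.
#' @return A `threshold_result` object: `threshold` (integer),
#'   `valley` (grid minimum, or `NA`), `modality` (`"bimodal"` or
#'   `"unimodal_fallback"`), plus the density grid for plotting.
#' @seealso [autoplot.threshold_result()], [tidy.threshold_result()]
#' @export
dynamic_threshold <- function(distances, min_threshold = 3L, grid_step = 0.05,
                              min_bandwidth = 1) {
  if (is.data.frame(distances)) distances <- distances$distance
  d <- distances[!is.na(distances)]
  if (length(d) < 2) {
    contract_error("dynamic_threshold() needs at least 2 defined distances")
  }
  if (max(d) == min(d)) {
    res <- list(threshold = as.integer(min_threshold), valley = NA_real_,
                modality = "unimodal_fallback",
                grid = tibble(distance = numeric(), density = numeric()),
                n_distances = length(d))
    class(res) <- "threshold_result"
    return(res)
  }
  n_grid <- max(64L, ceiling(max(d) / grid_step) + 1L)
  bw <- max(stats::bw.nrd0(d), min_bandwidth)
  dens <- density(d, bw = bw, kernel = "gaussian",
                  from = 0, to = max(d), n = n_grid)
  y <- dens$y
  x <- dens$x
  # strict local maxima of the gridded density (endpoints included)
  left <- c(-Inf, y[-length(y)])
  right <- c(y[-1], -Inf)
  peaks <- which(y > left & y > right)
  if (length(peaks) >= 2) {
    top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    valley_idx <- lo + which.min(y[seq(lo, hi)]) - 1L
    valley <- floor(x[valley_idx])
    threshold <- max(as.integer(valley), as.integer(min_threshold))
    modality <- "bimodal"
  } else {
    valley <- NA_real_
    threshold <- as.integer(min_threshold)
    modality <- "unimodal_fallback"
  }
  res <- list(threshold = threshold, valley = valley, modality = modality,
              grid = tibble(distance = x, density = y),
              n_distances = length(d))
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("CDR3 clustering threshold: %d (%s", x$threshold, x$modality))
  if (!is.na(x$valley)) cat(sprintf(", density valley at %g", x$valley))
  cat(sprintf("; %d distances)\n", x$n_distances))
  invisible(x)
}

#' Group clones into clusters of related CDR3s
#'
#' Clones whose CDR3 Hamming distance is within the threshold are
#' connected; clusters are the connected components of that relation
#' (singletons allowed). The edge rule is `distance <= threshold` by
#' default; set `strict = TRUE` for `<`. Distance is computed on the CDR3
#' alone, so identical CDR3s with different V genes land in one cluster at
#' distance 0. Unequal-length pairs are never connected.
#'
#' @param clones A clone tibble.
#' @param threshold Integer threshold, or a `threshold_result`; `NULL`
#'   (default) derives the dynamic threshold from the clones themselves.
#' @param strict Use `distance < threshold` instead of `<=`.
#' @return A `clone_graph` object: `nodes` (clones plus `node_id`,
#'   `cluster_id`), `edges` (`i`, `j`, `distance`), `threshold`, and the
#'   underlying [igraph] graph.
#' @export
build_clusters <- function(clones, threshold = NULL, strict = FALSE) {
  if (nrow(clones) == 0) contract_error("build_clusters() needs at least one clone")
  thr_obj <- NULL
  if (is.null(threshold)) {
    thr_obj <- dynamic_threshold(cpp_hamming_dists(clones$cdr3_aa))
    threshold <- thr_obj$threshold
  } else if (inherits(threshold, "threshold_result")) {
    thr_obj <- threshold
    threshold <- thr_obj$threshold
  }
  max_d <- if (strict) as.integer(threshold) - 1L else as.integer(threshold)
  edges <- as_tibble(cpp_hamming_edges(clones$cdr3_aa, max_d))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges else tibble(i = integer(), j = integer()),
    directed = FALSE,
    vertices = tibble(name = seq_len(nrow(clones)))
  )
  comp <- igraph::components(g)
  nodes <- clones |>
    mutate(node_id = row_number(),
           cluster_id = unname(comp$membership[as.character(row_number())]))
  res <- list(nodes = nodes, edges = edges, threshold = as.integer(threshold),
              threshold_result = thr_obj, graph = g,
              n_clusters = comp$no)
  class(res) <- "clone_graph"
  res
}

#' @export
print.clone_graph <- function(x, ...) {
  cat(sprintf("clone graph: %d nodes, %d edges, %d clusters (threshold %d)\n",
              nrow(x$nodes), nrow(x$edges), x$n_clusters, x$threshold))
  if (!is.null(x$n_nerve_linked)) {
    cat(sprintf("nerve-restricted nodes with a blood edge: %d of %d\n",
                x$n_nerve_linked, sum(x$nodes$origin == "nerve", na.rm = TRUE)))
  }
  invisible(x)
}

#' Relatedness network between nerve-restricted and blood clones
#'
#' Tests whether nerve-tissue-restricted clones are sequence-related to
#' blood clones: nodes are the subject's nerve-restricted clones (keys
#' absent from blood) at frequency >= `min_freq` plus all blood clones at
#' frequency >= `min_freq`; any two nodes whose CDR3s are equal length and
#' within `max_mismatch` substitutions are connected. An absence of
#' nerve--blood edges ("no prominent clusters") indicates the nerve
#' repertoire is distinct from the circulating one.
#'
#' @param blood,nerve Clone tibbles for one subject.
#' @param min_freq Frequency floor for inclusion (default 0.001, i.e.
#'   0.1%).
#' @param max_mismatch Maximum CDR3 mismatches for an edge (default 3).
#' @return A `clone_graph` whose nodes carry `origin` (`"blood"` /
#'   `"nerve"`), `count` and `frequency`, with `n_nerve_linked` = number
#'   of nerve nodes having at least one edge to a blood node. Empty node
#'   set gives an empty graph with a warning.
#' @export
cross_compartment_network <- function(blood, nerve, min_freq = 0.001,
                                      max_mismatch = 3L) {
  key <- c("v_call", "j_call", "cdr3_aa")
  nerve_restricted <- anti_join(nerve, blood, by = key)
  nn <- filter(nerve_restricted, .data$frequency >= min_freq) |>
    mutate(origin = "nerve")
  bb <- filter(blood, .data$frequency >= min_freq) |>
    mutate(origin = "blood")
  nodes <- bind_rows(nn, bb)
  if (nrow(nodes) == 0) {
    warning("cross_compartment_network(): no clones pass min_freq; empty graph")
    res <- list(nodes = mutate(nodes, node_id = integer(), cluster_id = integer()),
                edges = tibble(i = integer(), j = integer(), distance = integer()),
                threshold = as.integer(max_mismatch), threshold_result = NULL,
                graph = igraph::make_empty_graph(directed = FALSE),
                n_clusters = 0L, n_nerve_linked = 0L)
    class(res) <- "clone_graph"
    return(res)
  }
  g <- build_clusters(nodes, threshold = as.integer(max_mismatch))
  is_nerve <- g$nodes$origin == "nerve"
  linked <- unique(c(
    g$edges$i[is_nerve[g$edges$i] & !is_nerve[g$edges$j]],
    g$edges$j[is_nerve[g$edges$j] & !is_nerve[g$edges$i]]
  ))
  g$n_nerve_linked <- length(linked)
  g
}

#' Export a clone graph
#'
#' `write_edge_list()` writes a `source`, `target`, `distance` TSV;
#' `write_clone_graphml()` writes GraphML with node attributes (`origin`
#' when present, `count`, `frequency`, `cluster_id`).
#'
#' @param graph A `clone_graph`.
#' @param path Output file path.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(
    tibble(source = graph$edges$i, target = graph$edges$j,
           distance = graph$edges$distance),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_clone_graphml <- function(graph, path) {
  g <- graph$graph
  nodes <- graph$nodes
  for (col in intersect(c("origin", "v_call", "j_call", "cdr3_aa"), names(nodes))) {
    g <- igraph::set_vertex_attr(g, col, value = as.character(nodes[[col]]))
  }
  for (col in intersect(c("count", "frequency", "cluster_id"), names(nodes))) {
    g <- igraph::set_vertex_attr(g, col, value = as.numeric(nodes[[col]]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
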