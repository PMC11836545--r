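# CDR3 Hamming distances, the dynamic density-valley threshold, clustering,
# and the cross-compartment relatedness network.

test_that("hamming_distance matches a per-position oracle", {
  expect_equal(hamming_distance("CASSLGTDTQYF", "CASSLGTDTQYF"), 0L)
  expect_equal(hamming_distance("CASSLGTDTQYF", "CASSPGTDTQYF"), 1L)
  expect_true(is.na(hamming_distance("CASS", "CASSL")))

  set.seed(42)
  a <- random_aa(2000, sample(9:14, 2000, TRUE))
  b <- random_aa(2000, sample(9:14, 2000, TRUE))
  expect_equal(hamming_distance(a, b),
               mapply(oracle_hamming, a, b, USE.NAMES = FALSE))
})

test_that("distance_set enumerates all pairs and marks undefined ones", {
  clones <- make_clones(c("CASSLGTDTQYF", "CASSPGTDTQYF", "CASSLGTDTQYW"))
  ds <- distance_set(clones)
  expect_equal(nrow(ds), 3L)              # C(3,2)
  expect_true(all(!is.na(ds$distance)))

  mixed <- make_clones(c("CASSAAAATQYF", "CASSCCCCTQYF", "CASSAAAAGGTQYF"))
  dsm <- distance_set(mixed)
  expect_equal(sum(!is.na(dsm$distance)), 1L)
  expect_equal(sum(is.na(dsm$distance)), 2L)

  one <- make_clones("CASSLGTDTQYF")
  expect_equal(nrow(distance_set(one)), 0L)
  expect_error(dynamic_threshold(distance_set(one)),
               class = "nervetcr_contract_error")
})

test_that("dynamic threshold finds the density valley, floored at 3", {
  d <- bimodal_mixture()
  res <- dynamic_threshold(d)
  expect_equal(res$modality, "bimodal")
  expect_true(res$threshold >= 3L)
  expect_equal(res$threshold, max(oracle_histogram_valley(d), 3L),
               tolerance = 1)

  # unimodal input falls back to 3
  set.seed(1)
  uni <- 8L + rbinom(500, 4, 0.5)
  res_uni <- dynamic_threshold(uni)
  expect_equal(res_uni$threshold, 3L)
  expect_equal(res_uni$modality, "unimodal_fallback")

  # clearly bimodal with the valley at 2: the 3-amino-acid floor applies
  low <- c(rep(0L, 300), rep(1L, 80), rep(2L, 5), rep(3L, 60), rep(4L, 280))
  res_low <- dynamic_threshold(low)
  expect_equal(res_low$modality, "bimodal")
  expect_true(res_low$valley < 3)
  expect_equal(res_low$threshold, 3L)

  # threshold is stable under duplicating every distance
  res_dup <- dynamic_threshold(rep(d, 2L))
  expect_true(abs(res_dup$threshold - res$threshold) <= 1L)
  expect_equal(oracle_histogram_valley(rep(d, 2L)), oracle_histogram_valley(d))

  # glance/tidy expose the result
  g <- glance(res)
  expect_equal(g$threshold, res$threshold)
  expect_equal(nrow(tidy(res)), nrow(res$grid))
})

test_that("clusters are the connected components of the threshold relation", {
  # chain a-b (d=2), b-c (d=2), a-c (d=4): one component at threshold 3
  chain <- make_clones(c("CASSAAAAAQYF", "CASSAAGGAQYF", "CASSAAGGCCYF"))
  cg <- build_clusters(chain, threshold = 3L)
  expect_equal(cg$n_clusters, 1L)
  expect_equal(nrow(cg$edges), 2L)   # the d=4 pair is not an edge

  far <- make_clones(c("CAAAAAAAAAYF", "CSSSSSSSSSYF", "CGGGGGGGGGYF"))
  cg_far <- build_clusters(far, threshold = 3L)
  expect_equal(cg_far$n_clusters, 3L)

  # identical CDR3s under different V genes: distance 0, same cluster
  twins <- make_clones(c("CASSLGTDTQYF", "CASSLGTDTQYF"),
                       v_call = c("TRBV-T01", "TRBV-T02"))
  expect_equal(build_clusters(twins, threshold = 3L)$n_clusters, 1L)

  # property: components equal the brute-force transitive closure, and are
  # invariant under permutation of the input order
  set.seed(20250218)
  cdr3 <- paste0("CASS", random_aa(200, sample(c(5L, 6L, 7L), 200, TRUE)), "F")
  clones <- make_clones(cdr3)
  for (thr in c(2L, 3L, 5L)) {
    cg <- build_clusters(clones, threshold = thr)
    oracle <- oracle_components(cdr3, thr)
    # same partition: co-membership matrices agree
    expect_equal(outer(cg$nodes$cluster_id, cg$nodes$cluster_id, "=="),
                 outer(oracle, oracle, "=="))
  }
  perm <- sample(200)
  cg_p <- build_clusters(clones[perm, ], threshold = 3L)
  cg_o <- build_clusters(clones, threshold = 3L)
  expect_equal(outer(cg_p$nodes$cluster_id, cg_p$nodes$cluster_id, "=="),
               outer(cg_o$nodes$cluster_id, cg_o$nodes$cluster_id, "==")[perm, perm])

  # strict mode uses < threshold
  strict <- build_clusters(chain, threshold = 2L, strict = TRUE)
  expect_equal(nrow(strict$edges), 0L)
})

test_that("cross-compartment network links related clones across compartments", {
  blood <- make_clones(c("CASSABCDEFQF", "CASSZZZZZZQF"), counts = c(5L, 5L),
                       compartment = "blood")
  # one nerve clone copied from blood with 2 substitutions, one unrelated length
  nerve <- make_clones(c("CASSABGGEFQF", "CASSLONGERRRRQF"), counts = c(5L, 5L),
                       compartment = "nerve")
  net <- cross_compartment_network(blood, nerve)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$n_nerve_linked, 1L)
  expect_equal(sort(unique(net$nodes$origin)), c("blood", "nerve"))

  expect_warning(net0 <- cross_compartment_network(blood, nerve, min_freq = 1.0),
                 "min_freq")
  expect_equal(nrow(net0$nodes), 0L)

  # graph exports are written
  tmp_edges <- withr::local_tempfile(fileext = ".tsv")
  tmp_gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tmp_edges)
  expect_equal(nrow(readr::read_tsv(tmp_edges, show_col_types = FALSE)), 1L)
  write_clone_graphml(net, tmp_gml)
  g_back <- igraph::read_graph(tmp_gml, format = "graphml")
  expect_equal(igraph::vcount(g_back), nrow(net$nodes))
  expect_setequal(igraph::vertex_attr(g_back, "origin"), net$nodes$origin)
})

test_that("independently generated nerve-restricted CDR3s do not cluster with blood", {
  zero_runs <- 0L
  runs <- 5L
  for (s in seq_len(runs)) {
    cfg <- load_scenario("B", seed = 20250218 + s)
    pr <- make_paired_repertoires(cfg, subject_id = "S1")
    net <- cross_compartment_network(dplyr::mutate(pr$blood, count = 1L),
                                     dplyr::mutate(pr$nerve, count = 1L))
    if (net$n_nerve_linked == 0L) zero_runs <- zero_runs + 1L
    # verified against the all-pairs oracle: restricted nodes vs blood nodes
    nerve_cdr3 <- net$nodes$cdr3_aa[net$nodes$origin == "nerve"]
    blood_cdr3 <- net$nodes$cdr3_aa[net$nodes$origin == "blood"]
    oracle_links <- sum(vapply(nerve_cdr3, function(x) {
      any(vapply(blood_cdr3, function(y) {
        d <- oracle_hamming(x, y); !is.na(d) && d <= 3
      }, logical(1)))
    }, logical(1)))
    expect_equal(net$n_nerve_linked, oracle_links)
  }
  expect_true(zero_runs >= runs - 1L)
})
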