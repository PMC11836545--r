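# The synthetic-data generator: frequency model, paired repertoires, read
# simulation, and contamination injection.

test_that("clone frequency draws are normalised and land in the expanded-clone regime", {
  set.seed(20250218)
  expect_equal(sample_clone_frequencies(1), 1)
  f <- sample_clone_frequencies(200)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f > 0))

  # seeded regression: defaults give a plausible blood repertoire --
  # between 1 and 30 HECs and no clone above 10%
  set.seed(20250218)
  f <- sample_clone_frequencies(5000, shape = 2.0)
  n_hec <- sum(f >= 0.005)
  expect_gte(n_hec, 1L)
  expect_lte(n_hec, 30L)
  expect_lt(max(f), 0.10)

  expect_error(sample_clone_frequencies(10, shape = 1),
               class = "nervetcr_contract_error")
  set.seed(1)
  fl <- sample_clone_frequencies(100, shape = 1.5, model = "lognormal")
  expect_equal(sum(fl), 1, tolerance = 1e-9)
})

test_that("paired repertoires realise the configured restricted/shared structure", {
  cfg <- load_scenario("B")
  pr <- make_paired_repertoires(cfg, subject_id = "S1")
  key <- c("v_call", "j_call", "cdr3_aa")
  expect_equal(nrow(pr$nerve), 150L)
  expect_equal(sum(pr$blood$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(pr$nerve$frequency), 1, tolerance = 1e-9)

  restricted <- dplyr::anti_join(pr$nerve, pr$blood, by = key)
  expect_equal(nrow(dplyr::filter(restricted, frequency >= 0.005)), 54L)
  shared <- dplyr::inner_join(
    dplyr::select(pr$nerve, dplyr::all_of(key), freq_n = frequency),
    dplyr::select(pr$blood, dplyr::all_of(key), freq_b = frequency), by = key)
  expect_equal(sum(shared$freq_n >= 0.005 & shared$freq_b >= 0.005), 2L)
  # junction convention: C ... F/W, valid lengths
  expect_true(all(grepl("^C.*[FW]$", pr$nerve$cdr3_aa)))

  # determinism: the same seed reproduces the repertoires exactly
  pr2 <- make_paired_repertoires(cfg, subject_id = "S1")
  expect_identical(pr, pr2)

  # no restricted/shared HECs configured: nerve keys are a subset of blood's
  cfg0 <- tiny_scenario(n_nerve_restricted_hecs = 0L, n_shared_hecs = 0L)
  pr0 <- make_paired_repertoires(cfg0, subject_id = "S1")
  expect_equal(nrow(dplyr::anti_join(pr0$nerve, pr0$blood, by = key)), 0L)
})

test_that("read simulation conserves depth and respects constructibility", {
  cfg <- tiny_scenario()
  pr <- make_paired_repertoires(cfg, subject_id = "S1")
  sim <- simulate_reads(pr$nerve, cfg, mid = "ACGTACGT", seed = 5)
  expect_equal(nrow(sim$reads), cfg$nerve_depth_reads)
  expect_equal(nrow(sim$truth), cfg$nerve_depth_reads)
  # multinomial counts per clone sum to depth
  expect_equal(sum(table(sim$truth$cdr3_aa)), cfg$nerve_depth_reads)
  # every read starts with the MID (error rate 0 here)
  expect_true(all(substr(sim$reads$sequence, 1, 8) == "ACGTACGT"))

  expect_equal(nrow(simulate_reads(pr$nerve, cfg, mid = "ACGTACGT",
                                   depth = 0)$reads), 0L)

  alien <- make_clones("CQQQQQQQQQQW")  # not buildable from the toy germline
  expect_error(simulate_reads(alien, cfg, mid = "ACGTACGT", depth = 10),
               "constructible", class = "nervetcr_contract_error")
})

test_that("realised read frequencies converge to the true frequencies", {
  cfg <- tiny_scenario(blood_depth_reads = 100000L)
  pr <- make_paired_repertoires(cfg, subject_id = "S1")
  sim <- simulate_reads(pr$blood, cfg, mid = "ACGTACGT", seed = 9)
  obs <- sim$truth |>
    dplyr::count(cdr3_aa) |>
    dplyr::mutate(freq = n / sum(n))
  joined <- dplyr::inner_join(pr$blood, obs, by = "cdr3_aa")
  big <- dplyr::filter(joined, frequency >= 0.005)
  expect_true(all(abs(big$freq - big$frequency) < 0.01))
})

test_that("contamination injection creates removable trace reads and nothing else", {
  cfg <- tiny_scenario(contamination_rate = 0.002, seq_error_rate = 0,
                       n_public_clones = 2L)
  st <- simulate_study(cfg, n_subjects = 2)
  prov <- st$truth$provenance
  expect_gt(sum(prov$contaminant), 0)
  # injected keys come in at <= 2 reads per key and sample
  per_key <- prov |>
    dplyr::filter(contaminant) |>
    dplyr::count(sample_id, v_call, j_call, cdr3_aa)
  expect_true(all(per_key$n <= 2L))
  # rate 0 leaves the study untouched
  st0 <- simulate_study(tiny_scenario(), n_subjects = 2)
  expect_equal(sum(st0$truth$provenance$contaminant), 0L)

  # the pipeline removes every injected contaminant and keeps public clones
  res <- process_reads(st$reads, st$mids, st$germline,
                       sample_info = st$sample_info)
  contam_keys <- dplyr::distinct(dplyr::filter(prov, contaminant),
                                 sample_id, v_call, j_call, cdr3_aa)
  leftover <- dplyr::semi_join(res$clones, contam_keys,
                               by = c("sample_id", "v_call", "j_call", "cdr3_aa"))
  expect_equal(nrow(leftover), 0L)
  removed_public <- dplyr::filter(res$contamination_report,
                                  verdict == "removed_contaminant") |>
    dplyr::semi_join(
      dplyr::anti_join(dplyr::distinct(st$truth$repertoires,
                                       sample_id, v_call, j_call, cdr3_aa),
                       contam_keys, by = c("v_call", "j_call", "cdr3_aa")),
      by = c("sample_id", "v_call", "j_call", "cdr3_aa"))
  expect_equal(nrow(removed_public), 0L)
})
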