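# Read pipeline stages: demultiplexing, pair merging, annotation, clone
# calling, contamination screening, and the end-to-end recovery property.

toy <- toy_germline()

test_that("demultiplexing is exact-match with conserved read counts", {
  mids <- tibble::tibble(mid = c("ACGTACGT", "TTTTCCCC"),
                         subject_id = c("A", "B"), sample_id = c("a1", "b1"))
  payload <- "TGTGCCAGCAGCAATGAGCAGTTT"
  reads <- tibble::tibble(
    read_id = c("hit", "near", "miss"),
    sequence = c(paste0("ACGTACGT", payload),
                 paste0("ACGTACGA", payload),   # 1 mismatch in MID
                 paste0("GGGGGGGG", payload)),
    quality = strrep("I", nchar(payload) + 8)
  )
  dmx <- demultiplex(reads, mids)
  expect_equal(dmx$assigned$read_id, "hit")
  expect_equal(dmx$assigned$sequence, payload)     # MID stripped, payload kept
  expect_equal(nchar(dmx$assigned$quality), nchar(payload))
  expect_equal(dmx$unassigned$read_id, c("near", "miss"))
  expect_equal(nrow(dmx$assigned) + nrow(dmx$unassigned), nrow(reads))

  # 1-mismatch mode rescues the near read (MID distance >= 3 keeps it unique)
  dmx1 <- demultiplex(reads, mids, max_mismatch = 1L)
  expect_setequal(dmx1$assigned$read_id, c("hit", "near"))

  empty <- demultiplex(reads[0, ], mids)
  expect_equal(nrow(empty$assigned), 0L)
  expect_equal(nrow(empty$unassigned), 0L)
})

test_that("pair merging reconstructs the template and resolves conflicts by quality", {
  set.seed(7)
  template <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  r1 <- substr(template, 1, 60)
  r2 <- reverse_complement(substr(template, 41, 100))  # exact 20 nt overlap
  reads <- tibble::tibble(read_id = "p1", sequence = r1, quality = strrep("I", 60),
                          sequence2 = r2, quality2 = strrep("I", 60))
  asm <- assemble_pairs(reads)
  expect_equal(nrow(asm$merged), 1L)
  expect_equal(asm$merged$sequence, template)
  expect_equal(asm$merged$overlap_len, 20L)

  # disagreement inside the overlap: Phred 40 (mate 2) beats Phred 20 (mate 1)
  pos <- 50L
  r1_bad <- r1
  truth_base <- substr(template, pos, pos)
  substr(r1_bad, pos, pos) <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  q1 <- strrep("I", 60)
  substr(q1, pos, pos) <- phred_string(20L)
  conflicted <- tibble::tibble(read_id = "p2", sequence = r1_bad, quality = q1,
                               sequence2 = r2, quality2 = strrep("I", 60))
  asm2 <- assemble_pairs(conflicted)
  expect_equal(substr(asm2$merged$sequence, pos, pos), truth_base)

  # no qualifying overlap -> unmerged
  alien <- tibble::tibble(read_id = "p3",
                          sequence = strrep("A", 40), quality = strrep("I", 40),
                          sequence2 = strrep("C", 40), quality2 = strrep("I", 40))
  asm3 <- assemble_pairs(alien)
  expect_equal(nrow(asm3$merged), 0L)
  expect_equal(asm3$unmerged$read_id, "p3")

  expect_error(assemble_pairs(dplyr::select(reads, -sequence2, -quality2)),
               class = "nervetcr_contract_error")
})

test_that("annotation recovers generator V/J calls and junctions; garbage fails", {
  set.seed(11)
  v <- toy[toy$gene_name == "TRBV-T01", ]
  j <- toy[toy$gene_name == "TRBJ-T02", ]
  middle_nt <- "GGCACTGATACG"  # GTDT
  seq <- paste0(v$sequence, middle_nt, j$sequence)
  reads <- tibble::tibble(read_id = "synth", sequence = seq,
                          quality = strrep("I", nchar(seq)))
  ann <- annotate_reads(reads, toy)
  expect_equal(ann$status, "ok")
  expect_equal(ann$v_call, "TRBV-T01")
  expect_equal(ann$j_call, "TRBJ-T02")
  expect_equal(ann$junction_aa, "CASSGTDTTQYF")
  expect_true(ann$productive)

  random_reads <- tibble::tibble(
    read_id = sprintf("rand%d", 1:5),
    sequence = vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    }, character(1)),
    quality = strrep("I", 150)
  )
  ann_rand <- annotate_reads(random_reads, toy)
  expect_true(all(ann_rand$status != "ok"))
})

test_that("the CDR3 quality filter looks only inside the junction", {
  v <- toy[toy$gene_name == "TRBV-T03", ]
  j <- toy[toy$gene_name == "TRBJ-T01", ]
  seq <- paste0(v$sequence, "GCTTCC", j$sequence)
  qual <- strrep(phred_string(35L), nchar(seq))
  reads <- tibble::tibble(read_id = "q1", sequence = seq, quality = qual)
  ann <- annotate_reads(reads, toy)
  expect_true(ann$cdr3_quality_pass)       # all junction Phred 35 -> pass

  # one junction base at Phred 29 -> fail (strict < 30)
  q_bad <- qual
  substr(q_bad, ann$junction_start, ann$junction_start) <- phred_string(29L)
  ann_bad <- annotate_reads(dplyr::mutate(reads, quality = q_bad), toy)
  expect_false(ann_bad$cdr3_quality_pass)

  # Phred 2 upstream of the junction only -> still a pass
  q_up <- qual
  substr(q_up, 1, 1) <- phred_string(2L)
  ann_up <- annotate_reads(dplyr::mutate(reads, quality = q_up), toy)
  expect_true(ann_up$cdr3_quality_pass)
})

test_that("clone calling groups by V gene, J gene and exact CDR3", {
  rear <- tibble::tibble(
    sequence_id = sprintf("r%d", 1:6),
    subject_id = "X", sample_id = "s1", mid = NA_character_,
    v_call = c("TRBV-T01", "TRBV-T01", "TRBV-T01", "TRBV-T02",
               "TRBV-T01*01", "TRBV-T03"),
    j_call = "TRBJ-T01",
    junction = NA_character_,
    junction_aa = c("CASSLNEQF", "CASSLNEQF", "CASSLNEQF", "CASSLNEQF",
                    "CASSLNEQF", "CASRGNEQF"),
    cdr3_quality_pass = TRUE, productive = TRUE
  )
  clones <- call_clones(rear)
  # identical key x3 plus the allele-trimmed TRBV-T01*01 read -> count 4;
  # same CDR3 under TRBV-T02 is a distinct clone
  expect_equal(nrow(clones), 3L)
  k1 <- dplyr::filter(clones, v_call == "TRBV-T01")
  expect_equal(k1$count, 4L)
  expect_equal(sum(clones$frequency), 1, tolerance = 1e-9)
  expect_equal(sort(clones$count, decreasing = TRUE), c(4L, 1L, 1L))

  expect_equal(nrow(call_clones(rear[0, ])), 0L)
})

test_that("contamination screen removes trace carry-over but keeps public clones", {
  clones <- dplyr::bind_rows(
    make_clones("CASSLNEQF", 5000L, sample_id = "x1", subject_id = "X"),
    dplyr::bind_rows(
      make_clones("CASSLNEQF", 2L, sample_id = "y1", subject_id = "Y"),
      make_clones("CASSGGGGTQYF", 998L, sample_id = "y1", subject_id = "Y",
                  j_call = "TRBJ-T02")
    ) |> normalize_repertoire(),
    make_clones("CATSPUBLICF", 40L, sample_id = "x2", subject_id = "X"),
    make_clones("CATSPUBLICF", 60L, sample_id = "y2", subject_id = "Y")
  )
  res <- contamination_check(clones)
  removed <- dplyr::filter(res$report, verdict == "removed_contaminant")
  expect_equal(removed$sample_id, "y1")
  expect_equal(removed$cdr3_aa, "CASSLNEQF")
  # the contaminated sample is renormalised after removal
  y1 <- dplyr::filter(res$clones, sample_id == "y1")
  expect_equal(nrow(y1), 1L)
  expect_equal(y1$frequency, 1)
  # balanced cross-subject key is retained and flagged public
  expect_true(all(dplyr::filter(res$report, cdr3_aa == "CATSPUBLICF")$verdict == "public"))
  expect_equal(nrow(dplyr::filter(res$clones, cdr3_aa == "CATSPUBLICF")), 2L)
  # a key seen in one subject only is untouched and unreported
  expect_false("CASSGGGGTQYF" %in% res$report$cdr3_aa)

  expect_warning(contamination_check(make_clones("CASSLNEQF", 5L)), "2 subjects")
})

test_that("pipeline stage counts are conserved and deterministic", {
  cfg <- tiny_scenario(seq_error_rate = 0.002)
  st <- simulate_study(cfg, n_subjects = 2)
  res <- process_reads(st$reads, st$mids, st$germline, sample_info = st$sample_info)
  rep <- tibble::deframe(res$report)
  expect_equal(rep[["assigned"]] + rep[["unassigned"]], rep[["input"]])
  expect_equal(rep[["annotated"]] + rep[["annotation_failed"]], rep[["assigned"]])
  expect_true(rep[["productive"]] <= rep[["annotated"]])
  expect_true(rep[["cdr3_quality_passed"]] <= rep[["productive"]])
  expect_equal(sum(res$clones$count), rep[["cdr3_quality_passed"]])

  # byte-identical determinism: same seed, same everything
  st2 <- simulate_study(cfg, n_subjects = 2)
  expect_identical(st$reads, st2$reads)
  res2 <- process_reads(st2$reads, st2$mids, st2$germline,
                        sample_info = st2$sample_info)
  expect_identical(res$clones, res2$clones)
})

test_that("error-free reads at depth are recovered exactly with in-interval frequencies", {
  cfg <- tiny_scenario()
  st <- simulate_study(cfg, n_subjects = 2)
  res <- process_reads(st$reads, st$mids, st$germline, sample_info = st$sample_info)
  truth <- st$truth$repertoires
  by_key <- c("sample_id", "v_call", "j_call", "cdr3_aa")
  expect_equal(nrow(dplyr::anti_join(res$clones, truth, by = by_key)), 0L)
  expect_equal(nrow(dplyr::anti_join(truth, res$clones, by = by_key)), 0L)

  joined <- dplyr::inner_join(
    dplyr::select(res$clones, dplyr::all_of(by_key), count),
    dplyr::select(truth, dplyr::all_of(by_key), true_freq = frequency),
    by = by_key
  ) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(depth = sum(count)) |>
    dplyr::ungroup()
  lo <- qbinom(0.005, joined$depth, joined$true_freq)
  hi <- qbinom(0.995, joined$depth, joined$true_freq)
  expect_true(all(joined$count >= lo & joined$count <= hi))
})
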