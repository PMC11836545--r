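# I/O layer: FASTQ, AIRR TSV, clone tables, germline FASTA, MID maps.

test_that("FASTQ decoding, validation and round-trips work", {
  expect_equal(phred_scores("II"), c(40L, 40L))
  expect_equal(phred_string(c(40, 40)), "II")

  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "GGTTAA", "+", "IIIFFI"), tmp)
  reads <- read_fastq(tmp)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$sequence, c("ACGT", "GGTTAA"))

  # seeded synthetic round-trip: write then read is the identity
  set.seed(1)
  synth <- tibble::tibble(
    read_id = sprintf("r%03d", 1:50),
    sequence = vapply(1:50, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE), collapse = "")
    }, character(1)),
    quality = vapply(1:50, function(i) phred_string(sample(2:40, 40, TRUE)),
                     character(1))
  )
  out <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(synth, out)
  expect_equal(read_fastq(out), synth)

  # truncated record and length mismatch are format errors naming the record
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(read_fastq(bad), "record 2", class = "nervetcr_format_error")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), "length", class = "nervetcr_format_error")

  # empty file is an empty tibble
  writeLines(character(0), bad)
  expect_equal(nrow(read_fastq(bad)), 0L)
})

test_that("AIRR reader applies defaults and flags unproductive junctions", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence_id\tv_call\tj_call\tjunction_aa",
    "r1\tTRBV-T01\tTRBJ-T01\tCASSLNEQF",
    "r2\tTRBV-T02\tTRBJ-T02\tCASS*TQYF",
    "r3\tTRBV-T03\tTRBJ-T01\tCASRGNEQF"
  ), tmp)
  r <- read_airr(tmp)
  expect_equal(nrow(r), 3L)
  expect_equal(r$productive, c(TRUE, FALSE, TRUE))   # stop codon rule
  expect_true(all(r$cdr3_quality_pass))              # default when absent

  writeLines(c("sequence_id\tj_call\tjunction_aa", "r1\tJ\tCASSF"), tmp)
  expect_error(read_airr(tmp), "v_call", class = "nervetcr_format_error")

  writeLines("sequence_id\tv_call\tj_call\tjunction_aa", tmp)
  expect_equal(nrow(read_airr(tmp)), 0L)

  # written rearrangements round-trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_airr(r, out)
  expect_equal(read_airr(out), r)
})

test_that("clone tables round-trip losslessly and stay normalised", {
  clones <- make_clones(c("CASSLNEQF", "CASSGTQYF"), counts = c(3L, 1L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(clones, tmp)
  back <- read_clone_table(tmp)
  expect_equal(back$cdr3_aa, clones$cdr3_aa)
  expect_equal(back$count, clones$count)
  expect_equal(back$frequency, clones$frequency)
  expect_equal(sum(back$frequency), 1, tolerance = 1e-9)

  # empty repertoire -> header-only file
  write_clone_table(clones[0, ], tmp)
  expect_equal(nrow(read_clone_table(tmp)), 0L)
  expect_equal(length(readLines(tmp)), 1L)
})

test_that("germline FASTA validation enforces the anchor-codon invariants", {
  g <- toy_germline()
  expect_equal(sum(g$segment_type == "V"), 8L)
  expect_equal(sum(g$segment_type == "J"), 4L)
  # anchors translate to C (V) and F/W (J)
  anchor_aa <- vapply(seq_len(nrow(g)), function(i) {
    translate_dna(substr(g$sequence[i], g$anchor_offset[i] + 1,
                         g$anchor_offset[i] + 3))
  }, character(1))
  expect_true(all(anchor_aa[g$segment_type == "V"] == "C"))
  expect_true(all(anchor_aa[g$segment_type == "J"] %in% c("F", "W")))

  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">badV|V|0", "GGGAAATTT"), tmp)  # anchor codon GGG -> G
  expect_error(read_germline_fasta(tmp), "badV", class = "nervetcr_contract_error")

  writeLines(c(">dup|V|0", "TGTAAATTT", ">dup|V|0", "TGTAAATTT"), tmp)
  expect_error(read_germline_fasta(tmp), "duplicate",
               class = "nervetcr_contract_error")

  # writer/reader are mutually inverse
  out <- withr::local_tempfile(fileext = ".fasta")
  write_germline_fasta(g, out)
  expect_equal(read_germline_fasta(out), g)
})

test_that("MID maps require length-8, unique, well-separated tags", {
  good <- tibble::tibble(mid = c("ACGTACGT", "TTTTCCCC"),
                         subject_id = c("A", "B"),
                         sample_id = c("a1", "b1"))
  expect_silent(validate_mid_map(good))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mid_map(good, tmp)
  expect_equal(read_mid_map(tmp), good)

  expect_error(validate_mid_map(dplyr::mutate(good, mid = c("ACGT", "TTTTCCCC"))),
               "8 bases", class = "nervetcr_contract_error")
  close_pair <- dplyr::mutate(good, mid = c("ACGTACGT", "ACGTACGA"))
  expect_error(validate_mid_map(close_pair), "Hamming",
               class = "nervetcr_contract_error")
})

test_that("translation matches the reference genetic code", {
  skip_if_not_installed("Biostrings")
  codons <- names(Biostrings::GENETIC_CODE)
  expect_equal(unname(translate_dna(codons)),
               unname(as.character(Biostrings::GENETIC_CODE)))
  expect_equal(translate_dna("TGTGCCAGCAGC"), "CASS")
  expect_true(is.na(translate_dna("AC")))
})
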