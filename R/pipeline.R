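#' Assign reads to samples by their 8 bp MID
#'
#' A read is assigned iff its first 8 bases match a registered MID with at
#' most `max_mismatch` mismatches (default 0; the MID map guarantees
#' pairwise distance >= 3, so up to 1 mismatch remains unambiguous). The MID
#' prefix and its qualities are stripped from assigned reads; unmatched
#' reads are returned unmodified in the `unassigned` component.
#'
#' @param reads A read tibble (see [read_fastq()]).
#' @param mids A validated MID map tibble.
#' @param max_mismatch Allowed mismatches in the MID, 0 or 1.
#' @return A list with `assigned` (read tibble plus `sample_id`,
#'   `subject_id`, `mid` columns) and `unassigned` (read tibble).
#' @export
demultiplex <- function(reads, mids, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  mids <- validate_mid_map(mids)
  if (nrow(reads) == 0) {
    return(list(assigned = mutate(reads, sample_id = character(0),
                                  subject_id = character(0), mid = character(0)),
                unassigned = reads))
  }
  prefix <- substr(reads$sequence, 1L, 8L)
  hit <- match(prefix, mids$mid)
  if (max_mismatch == 1L) {
    todo <- which(is.na(hit) & nchar(reads$sequence) >= 8L)
    for (i in todo) {
      d <- vapply(mids$mid, function(m) hamming1(prefix[i], m), integer(1))
      ok <- which(d <= 1L)
      if (length(ok) == 1L) hit[i] <- ok
    }
  }
  assigned <- reads[!is.na(hit), , drop = FALSE]
  idx <- hit[!is.na(hit)]
  assigned$mid <- mids$mid[idx]
  assigned$sample_id <- mids$sample_id[idx]
  assigned$subject_id <- mids$subject_id[idx]
  assigned$sequence <- substr(assigned$sequence, 9L, nchar(assigned$sequence))
  assigned$quality <- substr(assigned$quality, 9L, nchar(assigned$quality))
  list(assigned = as_tibble(assigned),
       unassigned = as_tibble(reads[is.na(hit), , drop = FALSE]))
}

#' Merge overlapping read pairs
#'
#' A simplified maximal-overlap merger: candidate 3' overlaps between read 1
#' and the reverse complement of read 2 of length >= `min_overlap` are
#' scored as matches minus mismatches; the best-scoring overlap whose
#' mismatch rate is <= `max_mismatch_rate` wins (ties to the longer
#' overlap). The consensus takes, at each overlap position, the base with
#' the higher Phred score; agreeing bases keep the maximum of the two
#' scores. Pairs with no qualifying overlap are returned unmerged.
#'
#' @param reads A paired read tibble with `sequence2`/`quality2` columns.
#' @param min_overlap Minimum overlap length (>= 5; default 10).
#' @param max_mismatch_rate Maximum fraction of mismatching overlap
#'   positions (default 0.1).
#' @return A list with `merged` (single-end read tibble with `overlap_len`,
#'   `overlap_mismatches`) and `unmerged` (the original rows that failed).
#' @export
assemble_pairs <- function(reads, min_overlap = 10L, max_mismatch_rate = 0.1) {
  if (!all(c("sequence2", "quality2") %in% names(reads)) ||
      anyNA(reads$sequence2)) {
    contract_error("assemble_pairs() requires mate sequences (sequence2/quality2)")
  }
  stopifnot(min_overlap >= 5L, max_mismatch_rate >= 0, max_mismatch_rate <= 1)
  if (nrow(reads) == 0) {
    merged <- select(reads, -all_of(c("sequence2", "quality2")))
    merged$overlap_len <- integer(0)
    merged$overlap_mismatches <- integer(0)
    return(list(merged = merged, unmerged = reads))
  }
  res <- cpp_merge_pairs(reads$sequence, reads$quality,
                         reads$sequence2, reads$quality2,
                         as.integer(min_overlap), max_mismatch_rate)
  ok <- res$merged
  merged <- reads[ok, , drop = FALSE]
  merged$sequence <- res$sequence[ok]
  merged$quality <- res$quality[ok]
  merged$overlap_len <- res$overlap_len[ok]
  merged$overlap_mismatches <- res$overlap_mismatches[ok]
  merged <- select(merged, -all_of(c("sequence2", "quality2")))
  list(merged = as_tibble(merged),
       unmerged = as_tibble(reads[!ok, , drop = FALSE]))
}

#' Annotate reads with V/J calls and the junction
#'
#' Each read is scanned against every V and J reference entry with an
#' ungapped sliding alignment (+1 match / -1 mismatch over the aligned
#' span); the best-scoring placement per segment wins, with ties broken by
#' gene-name order then offset, so annotation is deterministic. The
#' junction runs from the first base of the V anchor (conserved cysteine)
#' codon through the last base of the J anchor (conserved F/W) codon and is
#' translated in the V reading frame.
#'
#' A read fails annotation (`status != "ok"`) when either segment's aligned
#' identity is below `min_identity`, an anchor falls outside the read, or
#' the J anchor does not lie downstream of the V anchor. Failed reads are
#' retained in the output with `NA` calls so that stage counts are
#' conserved; downstream clone calling excludes them.
#'
#' `junction_aa` is the translation of `junction` when its length is a
#' multiple of 3; `productive` is `FALSE` for out-of-frame junctions or
#' translations containing a stop. `cdr3_quality_pass` is `TRUE` iff every
#' base inside the junction has Phred >= `min_q`; bases outside the
#' junction never affect the verdict.
#'
#' @param reads A demultiplexed (and, for paired data, merged) read tibble.
#' @param germline A validated germline tibble.
#' @param min_identity Identity floor for each segment call (default 0.8).
#' @param min_overlap Minimum aligned span per segment (default 20).
#' @param min_q Minimum Phred score inside the junction (default 30).
#' @return A rearrangement tibble: one row per input read with columns
#'   `sequence_id`, `subject_id`, `sample_id`, `mid`, `v_call`, `j_call`,
#'   `junction`, `junction_aa`, `cdr3_quality_pass`, `productive`,
#'   `v_identity`, `j_identity`, `junction_start`, `junction_end`, `status`.
#' @export
annotate_reads <- function(reads, germline, min_identity = 0.8,
                           min_overlap = 20L, min_q = 30L) {
  germline <- validate_germline(germline)
  vref <- filter(germline, .data$segment_type == "V")
  jref <- filter(germline, .data$segment_type == "J")
  if (nrow(vref) == 0 || nrow(jref) == 0) {
    contract_error("germline reference must contain at least one V and one J entry")
  }
  n <- nrow(reads)
  col_or_na <- function(nm) {
    if (nm %in% names(reads)) reads[[nm]] else rep(NA_character_, n)
  }
  out <- tibble(
    sequence_id = reads$read_id,
    subject_id = col_or_na("subject_id"),
    sample_id = col_or_na("sample_id"),
    mid = col_or_na("mid")
  )
  if (n == 0) {
    return(mutate(out, v_call = character(0), j_call = character(0),
                  junction = character(0), junction_aa = character(0),
                  cdr3_quality_pass = logical(0), productive = logical(0),
                  v_identity = double(0), j_identity = double(0),
                  junction_start = integer(0), junction_end = integer(0),
                  status = character(0)))
  }
  vres <- cpp_scan_reference(reads$sequence, vref$sequence, min_identity,
                             as.integer(min_overlap))
  jres <- cpp_scan_reference(reads$sequence, jref$sequence, min_identity,
                             as.integer(min_overlap))
  # 1-based junction span on the read
  v_anchor_start <- vres$offset + vref$anchor_offset[vres$ref] + 1L
  j_anchor_end <- jres$offset + jref$anchor_offset[jres$ref] + 3L
  read_len <- nchar(reads$sequence)
  ok <- !is.na(vres$ref) & !is.na(jres$ref) &
    !is.na(v_anchor_start) & !is.na(j_anchor_end) &
    v_anchor_start >= 1L & j_anchor_end <= read_len &
    j_anchor_end > v_anchor_start
  status <- dplyr::case_when(
    is.na(vres$ref) & is.na(jres$ref) ~ "no_vj_call",
    is.na(vres$ref) ~ "no_v_call",
    is.na(jres$ref) ~ "no_j_call",
    !ok ~ "anchor_out_of_bounds",
    .default = "ok"
  )
  junction <- ifelse(ok, substr(reads$sequence, v_anchor_start, j_anchor_end),
                     NA_character_)
  junction_aa <- translate_dna(junction)
  in_frame <- !is.na(junction) & nchar(junction) %% 3L == 0L
  productive <- in_frame & !is.na(junction_aa) &
    !grepl("*", junction_aa, fixed = TRUE)
  min_phred <- cpp_min_phred(reads$quality,
                             ifelse(ok, v_anchor_start, NA_integer_),
                             ifelse(ok, j_anchor_end, NA_integer_))
  out$v_call <- ifelse(ok, vref$gene_name[vres$ref], NA_character_)
  out$j_call <- ifelse(ok, jref$gene_name[jres$ref], NA_character_)
  out$junction <- junction
  out$junction_aa <- junction_aa
  out$cdr3_quality_pass <- ifelse(ok, min_phred >= min_q, NA)
  out$productive <- ifelse(ok, productive, NA)
  out$v_identity <- vres$identity
  out$j_identity <- jres$identity
  out$junction_start <- ifelse(ok, v_anchor_start, NA_integer_)
  out$junction_end <- ifelse(ok, j_anchor_end, NA_integer_)
  out$status <- status
  out
}

#' Call clones from annotated rearrangements
#'
#' Reads are grouped into clones on the (V gene name, J gene name, CDR3
#' amino-acid sequence) key -- 100% amino-acid identity within a key.
#' Allele suffixes (text after `*`) are trimmed from V/J calls and CDR3s
#' are upper-cased before grouping, so clones are keyed by gene, not
#' allele. Only annotated, productive, CDR3-quality-passed reads
#' contribute. Frequencies are normalised per sample.
#'
#' @param rearrangements A rearrangement tibble ([annotate_reads()] or
#'   [read_airr()] output).
#' @param sample_info Optional tibble (`sample_id`, `subject_id`,
#'   `compartment`) attaching compartment labels to samples.
#' @return A clone tibble: `sample_id`, `subject_id`, `compartment`,
#'   `v_call`, `j_call`, `cdr3_aa`, `count`, `frequency`. Zero usable reads
#'   give an empty tibble, not an error.
#' @export
call_clones <- function(rearrangements, sample_info = NULL) {
  r <- rearrangements
  if (!"status" %in% names(r)) r$status <- "ok"
  usable <- filter(r, .data$status == "ok",
                   !is.na(.data$v_call), !is.na(.data$j_call),
                   !is.na(.data$junction_aa),
                   .data$productive %in% TRUE,
                   .data$cdr3_quality_pass %in% TRUE)
  clones <- usable |>
    mutate(v_call = sub("\\*.*$", "", .data$v_call),
           j_call = sub("\\*.*$", "", .data$j_call),
           cdr3_aa = toupper(.data$junction_aa)) |>
    count(.data$sample_id, .data$subject_id, .data$v_call, .data$j_call,
          .data$cdr3_aa, name = "count") |>
    normalize_repertoire() |>
    arrange(.data$sample_id, desc(.data$frequency), .data$v_call,
            .data$j_call, .data$cdr3_aa)
  if (!is.null(sample_info)) {
    clones <- left_join(clones, select(sample_info, all_of(c("sample_id", "compartment"))),
                        by = "sample_id")
  } else if (!"compartment" %in% names(clones)) {
    clones$compartment <- NA_character_
  }
  select(clones, all_of(c("sample_id", "subject_id", "compartment", "v_call",
                          "j_call", "cdr3_aa", "count", "frequency")))
}

#' Screen clone tables for cross-subject contamination
#'
#' Trace carry-over between samples of different individuals shows up as a
#' clone key present at a very low count in one subject while another
#' subject carries the same key at a vastly higher count. For every clone
#' key shared across subjects: an occurrence with count <=
#' `low_count_ceiling` is removed when some other subject carries the key
#' at >= `ratio_threshold` times that count; otherwise the occurrence is
#' retained and flagged `"public"`. Frequencies are renormalised after
#' removal.
#'
#' @param clones A clone tibble spanning at least two subjects.
#' @param ratio_threshold Donor-to-recipient count ratio that marks
#'   contamination (default 100).
#' @param low_count_ceiling Only occurrences at or below this count can be
#'   removed (default 2).
#' @return A list with `clones` (cleaned, renormalised) and `report` (one
#'   row per cross-subject occurrence with its verdict).
#' @export
contamination_check <- function(clones, ratio_threshold = 100,
                                low_count_ceiling = 2L) {
  subjects <- unique(clones$subject_id)
  if (length(subjects) < 2) {
    warning("contamination_check(): fewer than 2 subjects; nothing to compare")
    return(list(clones = clones,
                report = tibble(sample_id = character(), subject_id = character(),
                                v_call = character(), j_call = character(),
                                cdr3_aa = character(), count = integer(),
                                max_other_subject_count = integer(),
                                verdict = character())))
  }
  key_cols <- c("v_call", "j_call", "cdr3_aa")
  cross <- clones |>
    group_by(across(all_of(key_cols))) |>
    filter(dplyr::n_distinct(.data$subject_id) > 1) |>
    mutate(max_other_subject_count = {
      cnt <- .data$count
      subj <- .data$subject_id
      vapply(seq_along(cnt), function(i) {
        other <- cnt[subj != subj[i]]
        if (length(other)) max(other) else 0L
      }, integer(1))
    }) |>
    ungroup() |>
    mutate(verdict = if_else(
      .data$count <= low_count_ceiling &
        .data$max_other_subject_count >= ratio_threshold * .data$count,
      "removed_contaminant", "public"))
  report <- select(cross, all_of(c("sample_id", "subject_id", key_cols,
                                   "count", "max_other_subject_count", "verdict")))
  removed <- filter(cross, .data$verdict == "removed_contaminant")
  cleaned <- clones |>
    anti_join(removed, by = c("sample_id", key_cols)) |>
    normalize_repertoire()
  list(clones = cleaned, report = arrange(report, .data$sample_id, .data$cdr3_aa))
}

#' Run the full read-to-repertoire pipeline
#'
#' Composes the pipeline stages -- optional paired-end merging, MID
#' demultiplexing, V/J + junction annotation, CDR3 quality filtering,
#' clone calling and the cross-subject contamination screen -- and keeps a
#' per-stage read-count report in which counts are conserved (input =
#' assigned + unassigned, annotated = passed + failed, ...).
#'
#' @param reads Read tibble (paired if `sequence2` present).
#' @param mids MID map tibble.
#' @param germline Germline tibble.
#' @param sample_info Optional sample metadata (see [call_clones()]).
#' @param min_q Minimum Phred inside the CDR3 (default 30).
#' @param min_identity V/J identity floor (default 0.8).
#' @param contamination Apply [contamination_check()] when more than one
#'   subject is present (default TRUE).
#' @param ... Passed to [assemble_pairs()].
#' @return A list: `clones`, `rearrangements`, `report` (stage counts),
#'   `contamination_report`.
#' @export
process_reads <- function(reads, mids, germline, sample_info = NULL,
                          min_q = 30L, min_identity = 0.8,
                          contamination = TRUE, ...) {
  report <- list()
  report$input <- nrow(reads)
  if ("sequence2" %in% names(reads) && !anyNA(reads$sequence2)) {
    asm <- assemble_pairs(reads, ...)
    reads <- asm$merged
    report$merged <- nrow(asm$merged)
    report$unmerged <- nrow(asm$unmerged)
  }
  dmx <- demultiplex(reads, mids)
  report$assigned <- nrow(dmx$assigned)
  report$unassigned <- nrow(dmx$unassigned)
  rear <- annotate_reads(dmx$assigned, germline, min_identity = min_identity,
                         min_q = min_q)
  report$annotated <- sum(rear$status == "ok")
  report$annotation_failed <- sum(rear$status != "ok")
  report$productive <- sum(rear$productive %in% TRUE)
  report$cdr3_quality_passed <- sum(rear$status == "ok" &
                                      rear$productive %in% TRUE &
                                      rear$cdr3_quality_pass %in% TRUE)
  clones <- call_clones(rear, sample_info = sample_info)
  contamination_report <- NULL
  if (contamination && length(unique(clones$subject_id)) > 1) {
    cc <- contamination_check(clones)
    clones <- cc$clones
    contamination_report <- cc$report
  }
  report_tbl <- tibble(stage = names(report),
                       reads = as.integer(unlist(report)))
  list(clones = clones, rearrangements = rear, report = report_tbl,
       contamination_report = contamination_report)
}
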