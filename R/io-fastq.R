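#' Read and write FASTQ files
#'
#' Plain-text FASTQ (4-line records, Phred+33). `read_fastq()` returns a
#' tibble of reads; when `mate_path` is given the second-in-pair sequences
#' are attached as `sequence2`/`quality2` columns matched by record order.
#'
#' Records are validated: a truncated trailing record or a sequence/quality
#' length mismatch raises a format error naming the record index, and
#' sequences are restricted to the `A C G T N` alphabet.
#'
#' @param path Path to a FASTQ file.
#' @param mate_path Optional path to the mate (R2) FASTQ file; must contain
#'   the same number of records as `path`.
#' @return A tibble with columns `read_id`, `sequence`, `quality` and, for
#'   paired input, `sequence2`, `quality2`. Quality columns are Phred+33
#'   strings; decode with [phred_scores()].
#' @seealso [write_fastq()], [phred_scores()]
#' @export
read_fastq <- function(path, mate_path = NULL) {
  reads <- parse_fastq_file(path)
  if (!is.null(mate_path)) {
    mates <- parse_fastq_file(mate_path)
    if (nrow(mates) != nrow(reads)) {
      format_error(sprintf(
        "mate file '%s' has %d records but '%s' has %d",
        mate_path, nrow(mates), path, nrow(reads)))
    }
    reads$sequence2 <- mates$sequence
    reads$quality2 <- mates$quality
  }
  reads
}

parse_fastq_file <- function(path) {
  if (!file.exists(path)) format_error(sprintf("FASTQ file not found: '%s'", path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    format_error(sprintf(
      "truncated FASTQ record %d in '%s' (file has %d lines, not a multiple of 4)",
      length(lines) %/% 4L + 1L, path, length(lines)))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    format_error(sprintf("FASTQ record %d in '%s': header does not start with '@'",
                         bad_hdr[1], path))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    format_error(sprintf("FASTQ record %d in '%s': separator line does not start with '+'",
                         bad_plus[1], path))
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    format_error(sprintf(
      "FASTQ record %d in '%s': sequence length %d != quality length %d",
      bad_len[1], path, nchar(seqs[bad_len[1]]), nchar(qual[bad_len[1]])))
  }
  bad_alpha <- which(grepl("[^ACGTN]", seqs))
  if (length(bad_alpha)) {
    format_error(sprintf("FASTQ record %d in '%s': sequence contains non-ACGTN characters",
                         bad_alpha[1], path))
  }
  tibble(
    read_id = sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[[`, character(1), 1L)),
    sequence = seqs,
    quality = qual
  )
}

#' @rdname read_fastq
#' @param reads A read tibble as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param mate_path2 Optional output path for the mates; required when
#'   `reads` carries `sequence2`.
#' @export
write_fastq <- function(reads, path, mate_path2 = NULL) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$quality),
               con, sep = "\n")
  }
  if (!is.null(mate_path2)) {
    stopifnot("sequence2" %in% names(reads))
    con2 <- file(mate_path2, "w")
    on.exit(close(con2), add = TRUE)
    if (nrow(reads) > 0) {
      writeLines(paste0("@", reads$read_id, "\n", reads$sequence2, "\n+\n", reads$quality2),
                 con2, sep = "\n")
    }
  }
  invisible(path)
}
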