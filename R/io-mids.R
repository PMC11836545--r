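#' Read and validate multiplex-identifier (MID) maps
#'
#' Each sample is tagged by an 8 bp MID at the start of read 1. The MID map
#' is a tab-separated table with columns `mid`, `subject_id`, `sample_id`.
#' Validation enforces: all MIDs length 8, unique, and pairwise Hamming
#' distance >= 3, which makes exact-match (0-mismatch) demultiplexing
#' unambiguous and 1-mismatch demultiplexing safe.
#'
#' @param path Path to a MID map TSV.
#' @return A validated MID tibble.
#' @export
read_mid_map <- function(path) {
  if (!file.exists(path)) format_error(sprintf("MID map not found: '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("mid", "subject_id", "sample_id"), names(df))
  if (length(missing)) {
    format_error(sprintf("MID map '%s' lacks column '%s'", path, missing[1]))
  }
  validate_mid_map(as_tibble(df))
}

#' @rdname read_mid_map
#' @param mids A MID tibble to validate.
#' @export
validate_mid_map <- function(mids) {
  if (any(nchar(mids$mid) != 8L)) {
    contract_error("all MIDs must be exactly 8 bases")
  }
  if (anyDuplicated(mids$mid)) contract_error("MIDs must be unique")
  if (anyDuplicated(mids$sample_id)) contract_error("sample_id values must be unique")
  n <- nrow(mids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- hamming1(mids$mid[i], mids$mid[j])
        if (d < 3L) {
          contract_error(sprintf(
            "MIDs '%s' and '%s' are Hamming distance %d apart (need >= 3)",
            mids$mid[i], mids$mid[j], d))
        }
      }
    }
  }
  mids
}

#' @rdname read_mid_map
#' @export
write_mid_map <- function(mids, path) {
  readr::write_tsv(select(mids, all_of(c("mid", "subject_id", "sample_id"))),
                   path, progress = FALSE)
  invisible(path)
}
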