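#' Read and write rearrangement tables (AIRR TSV dialect)
#'
#' Per-read rearrangement annotations travel as tab-separated tables in the
#' AIRR Rearrangement dialect: one row per read, columns `sequence_id`,
#' `v_call`, `j_call`, `junction`, `junction_aa`, `productive`, plus the
#' sample-tracking columns `subject_id`, `sample_id`, `mid` and the
#' pipeline's `cdr3_quality_pass`.
#'
#' `read_airr()` requires `sequence_id`, `v_call`, `j_call`, `junction_aa`
#' (a missing mandatory column raises a format error naming it). Missing
#' optional columns default: `cdr3_quality_pass` to `TRUE`, `productive` is
#' inferred from `junction_aa` (non-empty, no stop `*`, starts with C, ends
#' with F or W).
#'
#' @param path Path to a tab-separated rearrangement file.
#' @return A tibble of rearrangements.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) format_error(sprintf("AIRR file not found: '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("sequence_id", "v_call", "j_call", "junction_aa")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    format_error(sprintf("AIRR file '%s' lacks mandatory column '%s'",
                         path, missing[1]))
  }
  if (nrow(df) == 0) return(empty_rearrangements())
  df <- as_tibble(df)
  for (col in c("subject_id", "sample_id", "mid", "junction")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$cdr3_quality_pass <- if ("cdr3_quality_pass" %in% names(df)) {
    parse_airr_logical(df$cdr3_quality_pass, default = TRUE)
  } else TRUE
  df$productive <- if ("productive" %in% names(df)) {
    parse_airr_logical(df$productive, default = NA)
  } else NA
  inferred <- infer_productive(df$junction_aa)
  df$productive <- if_else(is.na(df$productive), inferred, df$productive)
  select(df, all_of(rearrangement_columns()))
}

rearrangement_columns <- function() {
  c("sequence_id", "subject_id", "sample_id", "mid", "v_call", "j_call",
    "junction", "junction_aa", "cdr3_quality_pass", "productive")
}

empty_rearrangements <- function() {
  tibble(sequence_id = character(), subject_id = character(),
         sample_id = character(), mid = character(), v_call = character(),
         j_call = character(), junction = character(),
         junction_aa = character(), cdr3_quality_pass = logical(),
         productive = logical())
}

# AIRR writes logicals as T/F; accept T/F, TRUE/FALSE, true/false.
parse_airr_logical <- function(x, default) {
  out <- dplyr::case_when(
    toupper(x) %in% c("T", "TRUE") ~ TRUE,
    toupper(x) %in% c("F", "FALSE") ~ FALSE,
    .default = NA
  )
  if (!is.na(default)) out[is.na(out)] <- default
  out
}

infer_productive <- function(junction_aa) {
  !is.na(junction_aa) & nchar(junction_aa) > 0 &
    !grepl("*", junction_aa, fixed = TRUE) &
    grepl("^C.*[FW]$", junction_aa)
}

#' @rdname read_airr
#' @param rearrangements A rearrangement tibble.
#' @export
write_airr <- function(rearrangements, path) {
  out <- rearrangements
  for (col in intersect(c("cdr3_quality_pass", "productive"), names(out))) {
    out[[col]] <- if_else(out[[col]], "T", "F")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
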