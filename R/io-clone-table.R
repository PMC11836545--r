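#' Read and write clone tables
#'
#' A clone table holds one row per clonotype -- the (V gene, J gene, CDR3
#' amino-acid sequence) key -- with its read count and within-repertoire
#' frequency. Files are tab-separated with `.`-decimal and round-trip
#' losslessly through this reader/writer pair. Sample metadata columns
#' (`sample_id`, `subject_id`, `compartment`) are written when present.
#'
#' @param path File path.
#' @return `read_clone_table()`: a clone tibble.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("clone table not found: '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("v_call", "j_call", "cdr3_aa", "count", "frequency")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    format_error(sprintf("clone table '%s' lacks mandatory column '%s'",
                         path, missing[1]))
  }
  df <- as_tibble(df)
  df$count <- as.integer(df$count)
  df$frequency <- as.double(df$frequency)
  df
}

#' @rdname read_clone_table
#' @param clones A clone tibble (columns `v_call`, `j_call`, `cdr3_aa`,
#'   `count`, `frequency`, optionally sample metadata).
#' @export
write_clone_table <- function(clones, path) {
  core <- c("v_call", "j_call", "cdr3_aa", "count", "frequency")
  stopifnot(all(core %in% names(clones)))
  meta <- intersect(c("sample_id", "subject_id", "compartment"), names(clones))
  readr::write_tsv(select(clones, all_of(c(meta, core))), path, progress = FALSE)
  invisible(path)
}

#' Renormalise clone frequencies within each sample
#'
#' Recomputes `frequency = count / sum(count)` within each `sample_id` (or
#' over the whole table when no `sample_id` column is present). Samples with
#' zero total keep frequency 0.
#'
#' @param clones A clone tibble.
#' @return The tibble with recomputed frequencies.
#' @export
normalize_repertoire <- function(clones) {
  grouping <- intersect("sample_id", names(clones))
  clones |>
    group_by(across(all_of(grouping))) |>
    mutate(frequency = if (sum(.data$count) > 0) .data$count / sum(.data$count) else 0) |>
    ungroup()
}
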