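#' Identify highly expanded clones (HECs)
#'
#' A clone is highly expanded when its frequency is at least `threshold` of
#' the total repertoire (inclusive; the conventional blood cut-off is 0.5%).
#' There is no established cut-off for T cells in nerve tissue, where T
#' cells do not normally reside; by default the same threshold is applied
#' there too, and [pair_overlap()] exposes it separately per compartment.
#'
#' @param clones A normalised clone tibble (single sample, or multiple --
#'   the threshold is applied per row on `frequency`).
#' @param threshold HEC frequency threshold in (0, 1); default 0.005.
#' @return The HEC rows, sorted by descending frequency then clone key.
#' @examples
#' reps <- tibble::tibble(v_call = "V1", j_call = "J1",
#'                        cdr3_aa = c("CASSA", "CASSB", "CASSC"),
#'                        count = c(60L, 50L, 49L),
#'                        frequency = c(0.006, 0.005, 0.0049))
#' find_hecs(reps)  # first two rows
#' @export
find_hecs <- function(clones, threshold = 0.005) {
  stopifnot(threshold > 0, threshold < 1)
  clones |>
    filter(.data$frequency >= threshold) |>
    arrange(desc(.data$frequency), .data$v_call, .data$j_call, .data$cdr3_aa)
}

#' Impact of a set of clones
#'
#' The impact of a set of clones is the sum of their frequencies within
#' their repertoire. The impact of a whole normalised repertoire is 1; of
#' an empty set, 0.
#'
#' @param clones Clone tibble rows drawn from one normalised repertoire.
#' @return A single number in `[0, 1]`.
#' @export
impact <- function(clones) {
  if (nrow(clones) == 0) return(0)
  sum(clones$frequency)
}

#' Classify clone sharing between paired blood and nerve repertoires
#'
#' Builds one record per clone key in the union of a subject's blood and
#' nerve repertoires, with the key's frequency in each compartment (0 where
#' absent) and a sharing category: `nerve_restricted` (nerve only),
#' `blood_restricted` (blood only) or `shared` (both). HEC flags are set
#' per compartment; `near_restricted` additionally marks clones present in
#' nerve whose blood frequency is below `near_floor` (including zero) --
#' "not detected or detected only at very low frequency in blood".
#'
#' @param blood,nerve Clone tibbles for the two compartments of one
#'   subject (same `subject_id` when present; mismatch is an error).
#' @param hec_threshold Blood HEC threshold (default 0.005).
#' @param nerve_hec_threshold Nerve HEC threshold (defaults to
#'   `hec_threshold`).
#' @param near_floor Blood-frequency floor for the `near_restricted` flag
#'   (default 0.001).
#' @return An overlap tibble: `v_call`, `j_call`, `cdr3_aa`, `freq_blood`,
#'   `freq_nerve`, `count_blood`, `count_nerve`, `category`, `hec_blood`,
#'   `hec_nerve`, `near_restricted`.
#' @export
pair_overlap <- function(blood, nerve, hec_threshold = 0.005,
                         nerve_hec_threshold = hec_threshold,
                         near_floor = 0.001) {
  subj_of <- function(x) {
    if ("subject_id" %in% names(x)) as.character(unique(stats::na.omit(x$subject_id)))
    else character()
  }
  sb <- subj_of(blood)
  sn <- subj_of(nerve)
  if (length(sb) > 1 || length(sn) > 1 ||
      (length(sb) == 1 && length(sn) == 1 && sb != sn)) {
    contract_error("pair_overlap(): blood and nerve must come from one subject")
  }
  key <- c("v_call", "j_call", "cdr3_aa")
  b <- select(blood, all_of(key), freq_blood = "frequency", count_blood = "count")
  n <- select(nerve, all_of(key), freq_nerve = "frequency", count_nerve = "count")
  rec <- full_join(b, n, by = key) |>
    mutate(
      freq_blood = tidyr::replace_na(.data$freq_blood, 0),
      freq_nerve = tidyr::replace_na(.data$freq_nerve, 0),
      count_blood = tidyr::replace_na(.data$count_blood, 0L),
      count_nerve = tidyr::replace_na(.data$count_nerve, 0L),
      category = dplyr::case_when(
        .data$freq_blood > 0 & .data$freq_nerve > 0 ~ "shared",
        .data$freq_nerve > 0 ~ "nerve_restricted",
        .default = "blood_restricted"
      ),
      hec_blood = .data$freq_blood >= hec_threshold,
      hec_nerve = .data$freq_nerve >= nerve_hec_threshold,
      near_restricted = .data$freq_nerve > 0 & .data$freq_blood < near_floor
    ) |>
    arrange(desc(.data$freq_nerve), desc(.data$freq_blood),
            .data$v_call, .data$j_call, .data$cdr3_aa)
  subject <- if (length(sb)) sb else if (length(sn)) sn else NA_character_
  attr(rec, "subject_id") <- subject
  rec
}

#' Summarise a subject's blood--nerve overlap records
#'
#' Counts and impacts per sharing category and the headline nerve-HEC
#' statistics: how many nerve HECs there are and how many of them are
#' nerve-restricted (blood frequency exactly 0) or near-restricted (blood
#' frequency below the [pair_overlap()] `near_floor`).
#'
#' @param records Overlap tibble from [pair_overlap()] for one subject.
#' @return A one-row tibble with clone counts (`n_clones`, `n_shared`,
#'   `n_nerve_restricted`, `n_blood_restricted`, `n_blood_hecs`,
#'   `n_nerve_hecs`, `n_nerve_hecs_restricted`,
#'   `n_nerve_hecs_near_restricted`) and impacts per category and
#'   compartment (`impact_*`).
#' @export
overlap_summary <- function(records) {
  tibble(
    n_clones = nrow(records),
    n_shared = sum(records$category == "shared"),
    n_nerve_restricted = sum(records$category == "nerve_restricted"),
    n_blood_restricted = sum(records$category == "blood_restricted"),
    n_blood_hecs = sum(records$hec_blood),
    n_nerve_hecs = sum(records$hec_nerve),
    n_nerve_hecs_restricted = sum(records$hec_nerve & records$freq_blood == 0),
    n_nerve_hecs_near_restricted = sum(records$hec_nerve & records$near_restricted),
    impact_shared_blood = sum(records$freq_blood[records$category == "shared"]),
    impact_shared_nerve = sum(records$freq_nerve[records$category == "shared"]),
    impact_nerve_restricted = sum(records$freq_nerve[records$category == "nerve_restricted"]),
    impact_blood_restricted = sum(records$freq_blood[records$category == "blood_restricted"]),
    impact_blood_hecs = sum(records$freq_blood[records$hec_blood]),
    impact_nerve_hecs = sum(records$freq_nerve[records$hec_nerve])
  )
}
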