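#' Parameters of the blood-sampling clone-detection model
#'
#' A venous sample is a small fraction of total blood volume; whether a
#' T-cell clone is detected depends on how many of its cells land in the
#' sample and on the chance of capturing at least one TCR-beta transcript
#' per cell. Defaults: a 2.5 mL sample of a 5 L blood volume (0.05%),
#' 1.5e6 T cells per mL (3,750,000 T cells in the sample), 21 TCR-beta
#' mRNA molecules per cell on average, and a per-cell detection
#' probability of 2.5%. The per-cell probability is a primitive parameter
#' of the model; the per-mRNA forward model ([per_cell_detection()]) is
#' provided for sensitivity analysis.
#'
#' @param total_blood_ml Total blood volume in mL (default 5000).
#' @param sample_ml Sample volume in mL (default 2.5).
#' @param tcell_per_ml T cells per mL of blood (default 1.5e6).
#' @param mrna_per_cell Mean TCR-beta mRNA molecules per cell (default 21).
#' @param per_cell_p Probability of detecting at least one transcript from
#'   a single cell (default 0.025).
#' @return A `detection_params` list.
#' @export
detection_params <- function(total_blood_ml = 5000, sample_ml = 2.5,
                             tcell_per_ml = 1.5e6, mrna_per_cell = 21L,
                             per_cell_p = 0.025) {
  stopifnot(total_blood_ml > 0, sample_ml >= 0, tcell_per_ml > 0,
            mrna_per_cell >= 1, per_cell_p >= 0, per_cell_p <= 1)
  structure(list(total_blood_ml = total_blood_ml, sample_ml = sample_ml,
                 tcell_per_ml = tcell_per_ml,
                 mrna_per_cell = as.integer(mrna_per_cell),
                 per_cell_p = per_cell_p),
            class = "detection_params")
}

#' @rdname detection_params
#' @param params A `detection_params` object.
#' @return `sample_fraction()`: the sampled fraction of total blood volume.
#' @export
sample_fraction <- function(params = detection_params()) {
  if (params$sample_ml > params$total_blood_ml) {
    contract_error("sample volume exceeds total blood volume")
  }
  params$sample_ml / params$total_blood_ml
}

#' @rdname detection_params
#' @return `sample_tcell_count()`: expected T cells in the sample.
#' @export
sample_tcell_count <- function(params = detection_params()) {
  params$sample_ml * params$tcell_per_ml
}

#' Per-cell transcript detection probability
#'
#' Forward model: if each of a cell's `m` transcripts is independently
#' captured with probability `p_mrna`, the chance of seeing at least one
#' is `1 - (1 - p_mrna)^m`. `invert_per_cell_detection()` solves for
#' `p_mrna` given a target per-cell probability:
#' `p_mrna = 1 - (1 - target)^(1/m)`.
#'
#' @param p_mrna Per-transcript capture probability in `[0, 1]`.
#' @param m Transcripts per cell.
#' @return A probability.
#' @export
per_cell_detection <- function(p_mrna, m = 21L) {
  stopifnot(all(p_mrna >= 0), all(p_mrna <= 1), all(m >= 0))
  1 - (1 - p_mrna)^m
}

#' @rdname per_cell_detection
#' @param target Desired per-cell detection probability.
#' @export
invert_per_cell_detection <- function(target, m = 21L) {
  stopifnot(all(target >= 0), all(target < 1))
  1 - (1 - target)^(1 / m)
}

#' Probability of detecting a clone present as k cells in the sample
#'
#' With `k` cells of a clone in the sample, each detected independently
#' with probability `per_cell_p`, the clone is detected with probability
#' `1 - (1 - per_cell_p)^k`: about 2.5% for a single cell, 22% for 10
#' cells and 92% for 100 cells at the default per-cell probability.
#'
#' @param k_cells Number of cells of the clone in the sample (vectorised,
#'   >= 0).
#' @param per_cell_p Per-cell detection probability (default 0.025).
#' @return Probabilities, same length as `k_cells`.
#' @export
clone_detection_prob <- function(k_cells, per_cell_p = 0.025) {
  if (any(k_cells < 0)) contract_error("k_cells must be non-negative")
  1 - (1 - per_cell_p)^k_cells
}

#' Tabulate the clone-detection curve
#'
#' @param k_values Clone sizes (cells in the sample) to tabulate.
#' @param params A [detection_params()] object.
#' @return A `detection_curve` tibble: `k`, `probability`, `percent`
#'   (rounded to the nearest percent, the conventional presentation).
#' @export
detection_curve <- function(k_values, params = detection_params()) {
  if (length(k_values) == 0) contract_error("k_values must be nonempty")
  if (any(k_values < 0)) contract_error("k_values must be non-negative")
  p <- clone_detection_prob(k_values, params$per_cell_p)
  out <- tibble(k = as.integer(k_values), probability = p,
                percent = round(100 * p))
  class(out) <- c("detection_curve", class(out))
  out
}

#' Monte-Carlo cross-check of the detection probability
#'
#' Simulates `n_reps` samples of `k_cells` independent Bernoulli
#' (`per_cell_p`) cells and returns the fraction of replicates with at
#' least one detected cell. Converges to [clone_detection_prob()];
#' intended as a simulation cross-check of the closed form.
#'
#' @param k_cells Cells of the clone in the sample.
#' @param per_cell_p Per-cell detection probability.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional integer seed (applied locally; the caller's RNG
#'   state is restored).
#' @return Estimated detection probability.
#' @export
monte_carlo_detection <- function(k_cells, per_cell_p = 0.025,
                                  n_reps = 1e5, seed = NULL) {
  stopifnot(n_reps >= 1, k_cells >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  if (k_cells == 0) return(0)
  detected <- rbinom(n_reps, size = as.integer(k_cells), prob = per_cell_p) > 0
  mean(detected)
}
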