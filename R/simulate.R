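#' Scenario configuration for the paired-repertoire simulator
#'
#' Collects every knob of the synthetic study in one validated list:
#' repertoire sizes, the number of nerve-restricted and shared highly
#' expanded clones (HECs), the clone-frequency model, sequencing depths,
#' the substitution error rate, read geometry and the cross-subject
#' contamination rate. Presets `A`, `B` and `C` (see [load_scenario()])
#' parameterise typical paired blood/nerve studies; `B` is the
#' shallow-nerve, near-zero-sharing case (150 nerve clones, 54 of 56
#' nerve HECs restricted, 5,928 nerve reads).
#'
#' @param seed Integer RNG seed.
#' @param n_blood_clones,n_nerve_clones Clones per compartment.
#' @param n_nerve_restricted_hecs Nerve HECs whose keys are absent from
#'   blood and whose CDR3s are generated independently of all blood CDR3s.
#' @param n_shared_hecs Clone keys at HEC frequency in both compartments.
#' @param blood_freq_shape Power-law exponent (> 1) of the blood
#'   clone-frequency distribution (sdlog when `freq_model = "lognormal"`).
#' @param nerve_depth_reads,blood_depth_reads Reads sequenced per sample.
#' @param seq_error_rate Per-base substitution error rate.
#' @param paired_end Simulate overlapping mate pairs instead of single
#'   full-length reads.
#' @param read_length Mate length for paired-end data.
#' @param contamination_rate Fraction of a sample's depth injected as
#'   cross-subject carry-over reads.
#' @param n_public_clones Genuinely public clone keys present in every
#'   subject's blood at balanced moderate frequency (contamination-screen
#'   specificity controls).
#' @param hec_freq_min,hec_freq_max True-frequency range from which nerve
#'   HEC frequencies are drawn.
#' @param freq_model `"power_law"` (default) or `"lognormal"`.
#' @param cdr3_len_min,cdr3_len_max CDR3 amino-acid length range.
#' @param low_clone_freq Target true frequency of each low-frequency
#'   (non-HEC) nerve clone (default 0.002, i.e. 0.2%); the HECs share the
#'   remaining repertoire mass.
#' @param restricted_cdr3_len_min Minimum CDR3 length for nerve-restricted
#'   HECs (default 16): their longer, independently drawn CDR3s keep them
#'   sequence-distinct from the blood repertoire, the structure the
#'   cross-compartment network analysis probes.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed = 20250218,
                            n_blood_clones = 5000L,
                            n_nerve_clones = 150L,
                            n_nerve_restricted_hecs = 54L,
                            n_shared_hecs = 2L,
                            blood_freq_shape = 2.0,
                            nerve_depth_reads = 5928L,
                            blood_depth_reads = 30000L,
                            seq_error_rate = 0.001,
                            paired_end = FALSE,
                            read_length = 90L,
                            contamination_rate = 0,
                            n_public_clones = 0L,
                            hec_freq_min = 0.012,
                            hec_freq_max = 0.018,
                            freq_model = "power_law",
                            cdr3_len_min = 9L,
                            cdr3_len_max = 18L,
                            restricted_cdr3_len_min = 16L,
                            low_clone_freq = 0.002) {
  cfg <- list(seed = as.integer(seed),
              n_blood_clones = as.integer(n_blood_clones),
              n_nerve_clones = as.integer(n_nerve_clones),
              n_nerve_restricted_hecs = as.integer(n_nerve_restricted_hecs),
              n_shared_hecs = as.integer(n_shared_hecs),
              blood_freq_shape = blood_freq_shape,
              nerve_depth_reads = as.integer(nerve_depth_reads),
              blood_depth_reads = as.integer(blood_depth_reads),
              seq_error_rate = seq_error_rate,
              paired_end = isTRUE(paired_end),
              read_length = as.integer(read_length),
              contamination_rate = contamination_rate,
              n_public_clones = as.integer(n_public_clones),
              hec_freq_min = hec_freq_min,
              hec_freq_max = hec_freq_max,
              freq_model = freq_model,
              cdr3_len_min = as.integer(cdr3_len_min),
              cdr3_len_max = as.integer(cdr3_len_max),
              restricted_cdr3_len_min = as.integer(restricted_cdr3_len_min),
              low_clone_freq = low_clone_freq)
  with(cfg, {
    if (n_nerve_restricted_hecs + n_shared_hecs > n_nerve_clones) {
      contract_error("n_nerve_restricted_hecs + n_shared_hecs exceeds n_nerve_clones")
    }
    if (nerve_depth_reads < 0 || blood_depth_reads < 0) {
      contract_error("sequencing depths must be >= 0")
    }
    if (freq_model == "power_law" && blood_freq_shape <= 1) {
      contract_error("power-law exponent must be > 1")
    }
    if (seq_error_rate < 0 || seq_error_rate > 1) {
      contract_error("seq_error_rate must be in [0, 1]")
    }
    n_hec <- n_nerve_restricted_hecs + n_shared_hecs
    n_low <- n_nerve_clones - n_hec
    if (n_hec > 0) {
      low_mass <- min(0.9, low_clone_freq * n_low)
      min_hec_freq <- (1 - low_mass) * hec_freq_min / (n_hec * hec_freq_max)
      if (min_hec_freq < 0.005) {
        contract_error("configured nerve HECs cannot all reach the 0.5% cut-off")
      }
    }
    if (low_clone_freq <= 0 || low_clone_freq >= 0.005) {
      contract_error("low_clone_freq must lie in (0, 0.005)")
    }
  })
  class(cfg) <- "scenario_config"
  cfg
}

#' Load a packaged scenario preset
#'
#' Presets are YAML files under `inst/extdata/scenarios`; all numeric
#' choices live in those files. `A` and `C` include some shared HECs and
#' cross-subject contamination; `B` is the shallow-nerve scenario with
#' near-zero blood sharing.
#'
#' @param name Preset name, `"A"`, `"B"` or `"C"`.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
load_scenario <- function(name, ...) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "nervetcr")
  if (!nzchar(path)) contract_error(sprintf("unknown scenario preset '%s'", name))
  params <- yaml::read_yaml(path)
  overrides <- list(...)
  params[names(overrides)] <- overrides
  do.call(scenario_config, params)
}

#' Draw skewed clone frequencies
#'
#' Clone weights are drawn from a discrete power law `P(w = k)
#' proportional to k^-shape` (k = 1..k_max, default 2000) and normalised to sum 1 --
#' the standard heavy-tailed model for clone-size distributions. With the
#' default exponent 2 and a few thousand clones this yields a handful of
#' clones above the 0.5% HEC cut-off and a maximum clone below 10%,
#' matching the expanded-clone regime of peripheral blood. A lognormal
#' alternative (`model = "lognormal"`, `shape` = sdlog) is available.
#'
#' @param n_clones Number of clones (>= 1).
#' @param shape Power-law exponent (> 1) or lognormal sdlog.
#' @param model `"power_law"` or `"lognormal"`.
#' @param k_max Upper support bound of the discrete power law.
#' @return A frequency vector of length `n_clones` summing to 1.
#' @export
sample_clone_frequencies <- function(n_clones, shape = 2.0,
                                     model = "power_law", k_max = 2000L) {
  if (n_clones < 1) contract_error("n_clones must be >= 1")
  if (model == "power_law") {
    if (shape <= 1) contract_error("power-law exponent must be > 1")
    k <- seq_len(k_max)
    cdf <- cumsum(k^(-shape))
    cdf <- cdf / cdf[k_max]
    w <- findInterval(runif(n_clones), cdf) + 1
  } else if (model == "lognormal") {
    w <- stats::rlnorm(n_clones, meanlog = 0, sdlog = shape)
  } else {
    contract_error(sprintf("unknown frequency model '%s'", model))
  }
  w / sum(w)
}

# CDR3 flank helpers: the amino acids a germline gene contributes to the
# junction (V: anchor codon to segment end; J: segment start through anchor).
v_tail_aa <- function(germline, gene) {
  row <- germline[germline$gene_name == gene & germline$segment_type == "V", ]
  if (nrow(row) != 1) contract_error(sprintf("V gene '%s' not in germline", gene))
  translate_dna(substr(row$sequence, row$anchor_offset + 1L, nchar(row$sequence)))
}

j_head_aa <- function(germline, gene) {
  row <- germline[germline$gene_name == gene & germline$segment_type == "J", ]
  if (nrow(row) != 1) contract_error(sprintf("J gene '%s' not in germline", gene))
  translate_dna(substr(row$sequence, 1L, row$anchor_offset + 3L))
}

.aa_alphabet <- setdiff(unique(unname(.codon_table)), "*")
# deterministic codon per amino acid, for re-encoding CDR3 middles
.aa2codon <- local({
  tab <- .codon_table
  vapply(split(names(tab), tab), min, character(1))
})

# Random CDR3s built as V-tail + random middle + J-head, with total length
# uniform over the configured range (subject to flank lengths).
random_cdr3s <- function(n, germline, v_calls, j_calls, len_min, len_max) {
  vt <- vapply(v_calls, function(g) v_tail_aa(germline, g), character(1))
  jh <- vapply(j_calls, function(g) j_head_aa(germline, g), character(1))
  flank <- nchar(vt) + nchar(jh)
  mid_len <- vapply(flank, function(fl) {
    lo <- max(1L, len_min - fl)
    hi <- max(lo, len_max - fl)
    sample(seq(lo, hi), 1L)
  }, integer(1))
  middles <- vapply(mid_len, function(L) {
    paste(sample(.aa_alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  paste0(vt, middles, jh)
}

# Unique random clone keys for one compartment.
random_clone_keys <- function(n, germline, len_min, len_max,
                              forbidden_cdr3 = character()) {
  v_genes <- germline$gene_name[germline$segment_type == "V"]
  j_genes <- germline$gene_name[germline$segment_type == "J"]
  out <- tibble(v_call = character(), j_call = character(), cdr3_aa = character())
  while (nrow(out) < n) {
    m <- n - nrow(out)
    cand <- tibble(
      v_call = sample(v_genes, m, replace = TRUE),
      j_call = sample(j_genes, m, replace = TRUE)
    )
    cand$cdr3_aa <- random_cdr3s(m, germline, cand$v_call, cand$j_call,
                                 len_min, len_max)
    cand <- filter(cand, !.data$cdr3_aa %in% forbidden_cdr3)
    out <- distinct(bind_rows(out, cand),
                    .data$v_call, .data$j_call, .data$cdr3_aa)
  }
  out[seq_len(n), ]
}

#' Generate a subject's paired blood and nerve repertoires
#'
#' Emulates the paired-compartment structure observed in inflamed nerve:
#' a diverse blood repertoire with power-law clone frequencies; a small
#' nerve repertoire dominated by highly expanded clones, of which exactly
#' `n_nerve_restricted_hecs` have keys absent from blood (their CDR3s
#' generated independently of every blood CDR3) and exactly
#' `n_shared_hecs` are at HEC frequency in both compartments; the
#' remaining nerve clones are low-frequency visitors drawn from the blood
#' clone pool. All CDR3s are valid junctions (C...F/W) constructible from
#' the germline reference.
#'
#' @param cfg A [scenario_config()].
#' @param germline A validated germline tibble (default [toy_germline()]).
#' @param subject_id Subject label.
#' @param seed Seed used for this subject (default `cfg$seed`).
#' @return A list with clone tibbles `blood` and `nerve` (true
#'   frequencies, `count = NA`) and `shared_keys`.
#' @export
make_paired_repertoires <- function(cfg, germline = toy_germline(),
                                    subject_id = "S1", seed = cfg$seed) {
  set.seed(seed)
  nb <- cfg$n_blood_clones
  nres <- cfg$n_nerve_restricted_hecs
  nsh <- cfg$n_shared_hecs
  nlow <- cfg$n_nerve_clones - nres - nsh
  if (nsh > nb || nlow > nb - nsh) {
    contract_error("blood repertoire too small for the configured nerve clones")
  }

  blood <- random_clone_keys(nb, germline, cfg$cdr3_len_min, cfg$cdr3_len_max)
  blood$frequency <- sample_clone_frequencies(nb, cfg$blood_freq_shape,
                                              model = cfg$freq_model)
  blood <- arrange(blood, desc(.data$frequency))

  # shared HEC keys: the most expanded blood clones, boosted to HEC level
  # when the power-law draw left them below it
  shared_idx <- seq_len(nsh)
  if (nsh > 0) {
    low <- blood$frequency[shared_idx] < 0.006
    blood$frequency[shared_idx][low] <- runif(sum(low), 0.006, 0.02)
    blood$frequency <- blood$frequency / sum(blood$frequency)
  }
  shared_keys <- blood[shared_idx, c("v_call", "j_call", "cdr3_aa")]

  # nerve: restricted HECs get CDR3s generated independently of (and
  # checked against) every blood CDR3
  restricted <- random_clone_keys(nres, germline,
                                  max(cfg$cdr3_len_min, cfg$restricted_cdr3_len_min),
                                  max(cfg$cdr3_len_max, cfg$restricted_cdr3_len_min),
                                  forbidden_cdr3 = blood$cdr3_aa)
  # Frequency allocation: low-frequency nerve clones (blood visitors) sit
  # near cfg$low_clone_freq each, well under the HEC cut-off; the HECs
  # share the remaining mass in proportion to draws from the configured
  # range. The nerve repertoire is thus HEC-dominated, the structure seen
  # in inflamed nerve tissue.
  n_hec <- nres + nsh
  low_mass <- if (n_hec == 0) 1 else min(0.9, cfg$low_clone_freq * nlow)
  if (nlow == 0) low_mass <- 0
  hec_w <- runif(n_hec, cfg$hec_freq_min, cfg$hec_freq_max)
  hec_freq <- if (n_hec > 0) (1 - low_mass) * hec_w / sum(hec_w) else numeric(0)
  low_pool <- if (nsh > 0) blood[-shared_idx, , drop = FALSE] else blood
  low_idx <- sample(nrow(low_pool), nlow, prob = low_pool$frequency)
  low_w <- runif(nlow, 0.8, 1.2)
  low_freq <- if (nlow > 0) low_mass * low_w / sum(low_w) else numeric(0)
  nerve <- bind_rows(
    mutate(restricted, frequency = hec_freq[seq_len(nres)]),
    mutate(shared_keys, frequency = hec_freq[nres + seq_len(nsh)]),
    mutate(low_pool[low_idx, c("v_call", "j_call", "cdr3_aa")],
           frequency = low_freq)
  )
  nerve$frequency <- nerve$frequency / sum(nerve$frequency)

  finish <- function(x, compartment) {
    x |>
      mutate(sample_id = paste0(subject_id, "_", compartment),
             subject_id = subject_id, compartment = compartment,
             count = NA_integer_) |>
      arrange(desc(.data$frequency), .data$v_call, .data$j_call, .data$cdr3_aa) |>
      select(all_of(c("sample_id", "subject_id", "compartment", "v_call",
                      "j_call", "cdr3_aa", "count", "frequency")))
  }
  list(blood = finish(blood, "blood"), nerve = finish(nerve, "nerve"),
       shared_keys = shared_keys)
}

# Rebuild the nucleotide template of a clone: MID + V segment + middle
# codons + J segment. The CDR3 must be constructible from the germline
# (start with the V gene's tail, end with the J gene's head).
clone_templates <- function(clones, germline, mid) {
  v_rows <- match(clones$v_call, germline$gene_name)
  j_rows <- match(clones$j_call, germline$gene_name)
  if (anyNA(v_rows) || anyNA(j_rows)) {
    contract_error("clone V/J call not present in germline reference")
  }
  vapply(seq_len(nrow(clones)), function(i) {
    vt <- v_tail_aa(germline, clones$v_call[i])
    jh <- j_head_aa(germline, clones$j_call[i])
    cdr3 <- clones$cdr3_aa[i]
    if (!startsWith(cdr3, vt) || !endsWith(cdr3, jh) ||
        nchar(cdr3) < nchar(vt) + nchar(jh)) {
      contract_error(sprintf(
        "CDR3 '%s' is not constructible from %s/%s", cdr3,
        clones$v_call[i], clones$j_call[i]))
    }
    middle <- substr(cdr3, nchar(vt) + 1L, nchar(cdr3) - nchar(jh))
    middle_nt <- if (nchar(middle)) {
      paste(.aa2codon[strsplit(middle, "")[[1]]], collapse = "")
    } else ""
    paste0(mid, germline$sequence[v_rows[i]], middle_nt,
           germline$sequence[j_rows[i]])
  }, character(1))
}

# Substitution errors with the error-to-quality coupling: an error base
# receives Phred < 30 with probability 0.9, otherwise the baseline Phred.
BASE_QUAL <- 37L
inject_errors <- function(seqs, quals, error_rate, low_q_prob = 0.9) {
  if (error_rate <= 0 || length(seqs) == 0) {
    return(list(sequence = seqs, quality = quals, n_errors = integer(length(seqs))))
  }
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      orig <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, orig), 1L)
      q <- if (runif(1) < low_q_prob) sample(2:29, 1L) else BASE_QUAL
      substr(quals[i], p, p) <- intToUtf8(q + 33L)
    }
  }
  list(sequence = seqs, quality = quals, n_errors = n_err)
}

#' Simulate sequencing reads from a repertoire
#'
#' Per-clone read counts are multinomial over the clone frequencies at the
#' configured depth. Each read is the clone's template (MID + V segment +
#' CDR3-middle codons + J segment) with independent per-base substitution
#' errors at `cfg$seq_error_rate`; an error base gets a Phred score below
#' 30 with probability 0.9 (so the CDR3 quality filter is consequential),
#' all other bases Phred 37. Paired-end mode splits the template into two
#' overlapping mates (read 2 reverse-complemented) and injects errors per
#' mate.
#'
#' @param repertoire A clone tibble with true `frequency` (one sample).
#' @param cfg A [scenario_config()].
#' @param germline Germline tibble.
#' @param mid The sample's 8 bp MID.
#' @param depth Reads to draw (defaults per compartment from `cfg`).
#' @param sample_id Sample label (defaults from the repertoire).
#' @param seed Optional seed.
#' @return A list: `reads` (read tibble; `sequence2`/`quality2` present in
#'   paired mode) and `truth` (per-read provenance: true clone key,
#'   error counts, contaminant flag).
#' @export
simulate_reads <- function(repertoire, cfg, germline = toy_germline(),
                           mid = "ACGTACGT", depth = NULL,
                           sample_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(repertoire) && nrow(repertoire) > 0) {
      repertoire$sample_id[1]
    } else "sample"
  }
  compartment <- if ("compartment" %in% names(repertoire)) repertoire$compartment[1] else NA
  if (is.null(depth)) {
    depth <- if (identical(compartment, "nerve")) cfg$nerve_depth_reads else cfg$blood_depth_reads
  }
  if (depth < 0) contract_error("depth must be >= 0")
  empty <- tibble(read_id = character(), sequence = character(),
                  quality = character())
  if (cfg$paired_end) {
    empty$sequence2 <- character(); empty$quality2 <- character()
  }
  truth0 <- tibble(read_id = character(), sample_id = character(),
                   v_call = character(), j_call = character(),
                   cdr3_aa = character(), n_errors = integer(),
                   contaminant = logical())
  if (depth == 0 || nrow(repertoire) == 0) {
    return(list(reads = empty, truth = truth0))
  }
  counts <- as.vector(rmultinom(1, depth, repertoire$frequency))
  templates <- clone_templates(repertoire, germline, mid)
  idx <- rep(seq_len(nrow(repertoire)), counts)
  seqs <- templates[idx]
  read_id <- sprintf("%s_r%06d", sample_id, seq_along(idx))
  if (cfg$paired_end) {
    L <- nchar(seqs)
    rl <- pmin(cfg$read_length, L)
    s1 <- substr(seqs, 1L, rl)
    s2 <- cpp_revcomp(substr(seqs, L - rl + 1L, L))
    q1 <- strrep(intToUtf8(BASE_QUAL + 33L), rl)
    e1 <- inject_errors(s1, q1, cfg$seq_error_rate)
    e2 <- inject_errors(s2, q1, cfg$seq_error_rate)
    reads <- tibble(read_id = read_id, sequence = e1$sequence,
                    quality = e1$quality, sequence2 = e2$sequence,
                    quality2 = e2$quality)
    n_errors <- e1$n_errors + e2$n_errors
  } else {
    q <- strrep(intToUtf8(BASE_QUAL + 33L), nchar(seqs))
    e <- inject_errors(seqs, q, cfg$seq_error_rate)
    reads <- tibble(read_id = read_id, sequence = e$sequence,
                    quality = e$quality)
    n_errors <- e$n_errors
  }
  truth <- tibble(read_id = read_id, sample_id = sample_id,
                  v_call = repertoire$v_call[idx],
                  j_call = repertoire$j_call[idx],
                  cdr3_aa = repertoire$cdr3_aa[idx],
                  n_errors = n_errors, contaminant = FALSE)
  list(reads = reads, truth = truth)
}

#' Generate sample MIDs with pairwise Hamming distance >= 3
#'
#' @param n Number of MIDs.
#' @return Character vector of 8-base MIDs.
#' @export
generate_mids <- function(n) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) contract_error("could not generate enough distinct MIDs")
    cand <- paste(sample(bases, 8L, replace = TRUE), collapse = "")
    if (all(vapply(out, function(m) hamming1(cand, m) >= 3L, logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}

#' Simulate a multi-subject paired blood/nerve study
#'
#' Generates per-subject paired repertoires ([make_paired_repertoires()]),
#' optional public clones present in every subject's blood at balanced
#' moderate frequency, MIDs, reads for every sample
#' ([simulate_reads()]) and, when `cfg$contamination_rate > 0`,
#' cross-subject contaminant reads ([inject_contamination()]). All
#' randomness derives from `cfg$seed`; the same seed reproduces the study
#' exactly.
#'
#' @param cfg A [scenario_config()].
#' @param n_subjects Number of subjects (default 3).
#' @param germline Germline tibble.
#' @return A `sim_study` list: `reads` (one pooled read tibble, MID-tagged),
#'   `mids`, `sample_info`, `truth` (`repertoires` clone tibble with true
#'   frequencies; `provenance` per-read records), `germline`, `config`.
#' @export
simulate_study <- function(cfg, n_subjects = 3L, germline = toy_germline()) {
  set.seed(cfg$seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  mids <- generate_mids(2L * n_subjects)
  mid_map <- tibble(
    mid = mids,
    subject_id = rep(subjects, each = 2L),
    sample_id = paste0(rep(subjects, each = 2L), "_", rep(c("blood", "nerve"), n_subjects))
  )
  public_keys <- if (cfg$n_public_clones > 0) {
    random_clone_keys(cfg$n_public_clones, germline,
                      cfg$cdr3_len_min, cfg$cdr3_len_max)
  } else NULL

  repertoires <- list()
  reads <- list()
  provenance <- list()
  for (s in seq_len(n_subjects)) {
    rep_pair <- make_paired_repertoires(cfg, germline, subject_id = subjects[s],
                                        seed = cfg$seed + 1000L * s)
    blood <- rep_pair$blood
    if (!is.null(public_keys)) {
      pub <- public_keys |>
        anti_join(blood, by = c("v_call", "j_call", "cdr3_aa")) |>
        mutate(sample_id = paste0(subjects[s], "_blood"),
               subject_id = subjects[s], compartment = "blood",
               count = NA_integer_,
               frequency = runif(dplyr::n(), 0.0015, 0.003))
      blood <- bind_rows(blood, pub)
      blood$frequency <- blood$frequency / sum(blood$frequency)
    }
    nerve <- rep_pair$nerve
    mid_b <- mid_map$mid[mid_map$sample_id == blood$sample_id[1]]
    mid_n <- mid_map$mid[mid_map$sample_id == nerve$sample_id[1]]
    sim_b <- simulate_reads(blood, cfg, germline, mid = mid_b,
                            depth = cfg$blood_depth_reads)
    sim_n <- simulate_reads(nerve, cfg, germline, mid = mid_n,
                            depth = cfg$nerve_depth_reads)
    repertoires[[s]] <- bind_rows(blood, nerve)
    reads[[s]] <- bind_rows(sim_b$reads, sim_n$reads)
    provenance[[s]] <- bind_rows(
      mutate(sim_b$truth, subject_id = subjects[s]),
      mutate(sim_n$truth, subject_id = subjects[s])
    )
  }
  study <- list(
    reads = bind_rows(reads),
    mids = mid_map,
    sample_info = mutate(
      distinct(mid_map, .data$sample_id, .data$subject_id),
      compartment = if_else(endsWith(.data$sample_id, "nerve"), "nerve", "blood")
    ),
    truth = list(repertoires = bind_rows(repertoires),
                 provenance = bind_rows(provenance)),
    germline = germline,
    config = cfg
  )
  class(study) <- c("sim_study", class(study))
  if (cfg$contamination_rate > 0 && n_subjects > 1) {
    study <- inject_contamination(study)
  }
  study
}

#' Inject cross-subject contaminant reads into a simulated study
#'
#' For every sample, about `rate x depth` reads of another subject's most
#' expanded blood clones are copied in, tagged with the recipient sample's
#' MID, at most 2 reads per contaminating clone key (the trace carry-over
#' regime the contamination screen is designed to remove). Keys already
#' present in the recipient subject's repertoire are skipped. Contaminant
#' reads are error-free and flagged in the provenance.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param rate Contamination rate (default from the study config).
#' @return The modified study.
#' @export
inject_contamination <- function(study, rate = study$config$contamination_rate) {
  cfg <- study$config
  info <- study$sample_info
  subjects <- unique(info$subject_id)
  if (length(subjects) < 2) contract_error("contamination needs >= 2 subjects")
  if (rate <= 0) return(study)
  extra_reads <- list()
  extra_prov <- list()
  for (i in seq_len(nrow(info))) {
    samp <- info$sample_id[i]
    subj <- info$subject_id[i]
    depth <- if (info$compartment[i] == "nerve") cfg$nerve_depth_reads else cfg$blood_depth_reads
    n_cont <- round(rate * depth)
    if (n_cont < 1) next
    donor_subj <- subjects[(match(subj, subjects) %% length(subjects)) + 1L]
    # only dominant donor clones can contaminate: their observed count in
    # the donor's own blood sample must comfortably exceed the screen's
    # ratio_threshold x 2 reads, or the carry-over would be undetectable
    min_donor_freq <- 300 / max(1, cfg$blood_depth_reads)
    donor <- study$truth$repertoires |>
      filter(.data$subject_id == donor_subj, .data$compartment == "blood",
             .data$frequency >= min_donor_freq) |>
      anti_join(filter(study$truth$repertoires, .data$subject_id == subj),
                by = c("v_call", "j_call", "cdr3_aa")) |>
      arrange(desc(.data$frequency))
    n_keys <- ceiling(n_cont / 2)
    donor <- donor[seq_len(min(n_keys, nrow(donor))), , drop = FALSE]
    counts <- rep(2L, nrow(donor))
    deficit <- sum(counts) - n_cont
    if (deficit > 0) counts[seq_len(deficit)] <- 1L
    mid <- study$mids$mid[study$mids$sample_id == samp]
    templates <- clone_templates(donor, study$germline, mid)
    idx <- rep(seq_len(nrow(donor)), counts)
    rid <- sprintf("%s_contam%04d", samp, seq_along(idx))
    reads <- tibble(read_id = rid, sequence = templates[idx],
                    quality = strrep(intToUtf8(BASE_QUAL + 33L),
                                     nchar(templates[idx])))
    if (cfg$paired_end) {
      L <- nchar(reads$sequence)
      rl <- pmin(cfg$read_length, L)
      reads$sequence2 <- cpp_revcomp(substr(reads$sequence, L - rl + 1L, L))
      reads$quality2 <- strrep(intToUtf8(BASE_QUAL + 33L), rl)
      reads$sequence <- substr(reads$sequence, 1L, rl)
      reads$quality <- strrep(intToUtf8(BASE_QUAL + 33L), rl)
    }
    extra_reads[[samp]] <- reads
    extra_prov[[samp]] <- tibble(read_id = rid, sample_id = samp,
                                 subject_id = subj,
                                 v_call = donor$v_call[idx],
                                 j_call = donor$j_call[idx],
                                 cdr3_aa = donor$cdr3_aa[idx],
                                 n_errors = 0L, contaminant = TRUE)
  }
  study$reads <- bind_rows(study$reads, bind_rows(extra_reads))
  study$truth$provenance <- bind_rows(study$truth$provenance,
                                      bind_rows(extra_prov))
  study
}
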