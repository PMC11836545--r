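# Independent oracles and small fixture builders used across the suite.

# Per-position Hamming oracle (independent of the C++ kernel).
oracle_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# Brute-force connected components: reflexive-transitive closure of the
# "distance <= threshold and equal length" relation, by label propagation.
oracle_components <- function(cdr3, threshold) {
  n <- length(cdr3)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- oracle_hamming(cdr3[i], cdr3[j])
      adj[i, j] <- !is.na(d) && d <= threshold
    }
  }
  diag(adj) <- TRUE
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(labels[nb])
      if (m < labels[i]) {
        labels[nb] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# Integer-histogram valley oracle: strict local maxima of the count
# histogram, valley = argmin between the two highest maxima (distances are
# integers, so this needs no smoothing choices at all).
oracle_histogram_valley <- function(d) {
  h <- tabulate(d + 1L, nbins = max(d) + 1L)
  left <- c(-1, h[-length(h)])
  right <- c(h[-1], -1)
  peaks <- which(h > left & h > right)
  if (length(peaks) < 2) return(NA_integer_)
  top2 <- sort(peaks[order(h[peaks], decreasing = TRUE)[1:2]])
  valley_bin <- top2[1] + which.min(h[top2[1]:top2[2]]) - 1L
  valley_bin - 1L  # bins are 1-based, distances 0-based
}

# Random amino-acid strings (no stops); `len` recycles per string.
random_aa <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# Minimal normalised clone tibble from counts.
make_clones <- function(cdr3, counts = rep(1L, length(cdr3)),
                        v_call = "TRBV-T01", j_call = "TRBJ-T01",
                        sample_id = "s1", subject_id = "X",
                        compartment = "blood") {
  tibble::tibble(sample_id = sample_id, subject_id = subject_id,
                 compartment = compartment,
                 v_call = v_call, j_call = j_call, cdr3_aa = cdr3,
                 count = as.integer(counts),
                 frequency = counts / sum(counts))
}

# The spec'd bimodal Hamming-distance mixture used for threshold validation:
# 30% Binomial(12, 0.08) + 70% (8 + Binomial(6, 0.5)).
bimodal_mixture <- function(n = 2000, seed = 20250218) {
  set.seed(seed)
  comp <- runif(n) < 0.3
  ifelse(comp, rbinom(n, 12, 0.08), 8L + rbinom(n, 6, 0.5))
}

# A tiny deterministic scenario for fast end-to-end runs.
tiny_scenario <- function(...) {
  defaults <- list(seed = 20250218, n_blood_clones = 25L, n_nerve_clones = 15L,
                   n_nerve_restricted_hecs = 4L, n_shared_hecs = 2L,
                   nerve_depth_reads = 3000L, blood_depth_reads = 5000L,
                   seq_error_rate = 0, contamination_rate = 0,
                   n_public_clones = 0L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(scenario_config, defaults)
}
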