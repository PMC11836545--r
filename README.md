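# nervetcr

Analysis of paired peripheral-blood and nerve-tissue TCRβ repertoires from
amplicon sequencing, aimed at studies of T-cell-mediated neuropathies
(e.g. chronic inflammatory demyelinating polyneuropathy, CIDP) where the
question is whether the T-cell clones expanded inside the nerve are the
same clones circulating in blood.

The package provides, as composable tidyverse-style functions over plain
tibbles:

* **Read pipeline** — paired-end merging by maximal overlap, 8 bp
  multiplex-identifier (MID) demultiplexing, ungapped V/J annotation
  against a germline reference FASTA, junction (CDR3) extraction between
  the conserved cysteine and F/W anchors, removal of reads with any CDR3
  base below Q30, clonotype calling on the (V gene, J gene, CDR3 amino
  acid) key, and a cross-subject contamination screen.
* **Repertoire statistics** — highly expanded clones (HECs, frequency
  ≥ 0.5% of the repertoire), the *impact* of a clone set (the sum of its
  frequencies), and paired blood–nerve overlap classification
  (`nerve_restricted` / `blood_restricted` / `shared`, with per-compartment
  HEC flags).
* **CDR3 clustering** — pairwise Hamming distances between equal-length
  CDR3s, a dynamic clustering threshold taken at the density valley between
  the two modes of the distance distribution (never below 3 amino acids),
  connected-component clusters, and a cross-compartment relatedness network
  linking nerve-restricted and blood clones within ≤ 3 mismatches.
* **Detection model** — the probability of catching a clone's transcripts
  in a small blood draw. A sample of volume *v* from total blood volume *V*
  contains a fraction *v/V* of circulating T cells; with per-cell detection
  probability *q*, a clone contributing *k* cells to the sample is detected
  with probability `1 − (1 − q)^k`.
* **Synthetic data** — a seeded generator for multi-subject paired
  blood/nerve studies (power-law clone frequencies, nerve repertoires
  dominated by tissue-restricted HECs, multinomial read sampling,
  substitution errors coupled to low base qualities, cross-subject
  contamination), with full ground truth so every stage is testable
  end to end.

## Worked example

Simulate a two-subject study under scenario preset **B** — a shallow nerve
sample (5,928 reads) dominated by nerve-restricted expanded clones — run the
pipeline, and summarise one subject's blood–nerve overlap:

```r
library(nervetcr)
library(dplyr)

cfg   <- load_scenario("B")
study <- simulate_study(cfg, n_subjects = 2)
res   <- process_reads(study$reads, study$mids, study$germline,
                       sample_info = study$sample_info)

blood <- filter(res$clones, subject_id == "S01", compartment == "blood")
nerve <- filter(res$clones, subject_id == "S01", compartment == "nerve")
sm <- overlap_summary(pair_overlap(blood, nerve))
sm[, c("n_nerve_hecs", "n_nerve_hecs_restricted", "impact_nerve_hecs")]
#> # A tibble: 1 × 3
#>   n_nerve_hecs n_nerve_hecs_restricted impact_nerve_hecs
#>          <int>                   <int>             <dbl>
#> 1           56                      54             0.812
```

56 nerve clones sit at or above the 0.5% HEC cut-off; 54 of them are never
seen in the paired blood sample, and together the nerve HECs account for
~81% of all nerve reads — an HEC-dominated, tissue-restricted repertoire.
The detection model quantifies why that is unlikely to be a pure sampling
artefact of the blood draw:

```r
detection_curve(c(1, 10, 100))
#> # A tibble: 3 × 3
#>       k probability percent
#>   <int>       <dbl>   <dbl>
#> 1     1      0.0250       3
#> 2    10      0.224       22
#> 3   100      0.920       92
```

A clone contributing even 100 cells to a 2.5 mL draw would be detected with
~92% probability, so expanded blood clones are reliably visible; clones seen
only in nerve are genuinely absent or very rare in circulation.
`run_full_analysis()` strings all stages together and writes every stage's
table, networks and a reproducibility manifest to an output directory;
`inst/scripts/nervetcr-run.R` wraps it for the shell.

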