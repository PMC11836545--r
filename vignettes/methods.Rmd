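---
title: "Methods: paired blood–nerve TCRβ repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired blood-nerve TCRbeta repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervetcr)
library(dplyr)
```

## The scientific question

In immune-mediated neuropathies such as CIDP, T cells infiltrate peripheral
nerve. Whether those infiltrating clones mirror the circulating repertoire
or form a nerve-specific population matters mechanistically (selective
retention and local clonal expansion versus passive spill-over) and
therapeutically (a drug that blocks lymphocyte egress cannot touch clones
already expanding inside the nerve). `nervetcr` implements the
computational side of a paired-compartment TCRβ amplicon study: clonotype
calling from raw reads, expanded-clone and overlap statistics, CDR3
similarity clustering, and a probability model for what a small blood draw
can and cannot detect.

## Clonotype calling from reads

The pipeline mirrors a standard amplicon repertoire workflow:

1. *Paired-end merging* (`assemble_pairs()`): candidate 3′ overlaps of at
   least `min_overlap` (default 10 nt) between read 1 and the reverse
   complement of read 2 are scored as matches − mismatches; the best
   overlap with mismatch rate ≤ 0.1 wins, ties going to the longer overlap
   so that merging is a total order and byte-reproducible. The consensus
   takes the higher-quality base at disagreements (read 1 on a quality
   tie) and the maximum quality at agreements.
2. *Demultiplexing* (`demultiplex()`): reads are assigned to samples by an
   exact match of their first 8 bases against the MID map, whose entries
   are validated to be pairwise Hamming distance ≥ 3; a 1-mismatch mode is
   available and remains unambiguous under that guarantee.
3. *V/J annotation and junction extraction* (`annotate_reads()`): each
   read is scanned against every germline V and J entry with an ungapped
   sliding alignment (+1 match / −1 mismatch over the aligned span,
   identity floor 0.8, minimum span 20 nt). Amplicon reads of this design
   contain no indels, so an exhaustive ungapped scan is exact and fast
   (implemented in C++); externally annotated AIRR rearrangement tables
   are accepted as an alternative entry point (`read_airr()`). The
   junction runs from the first base of the V segment's conserved-cysteine
   codon to the last base of the J segment's conserved F/W codon, and the
   stored `cdr3_aa` is that junction's translation (C…F/W inclusive). One
   convention, applied everywhere, including clustering.
4. *CDR3 quality filter*: a read is discarded if any base inside the
   junction has Phred < 30. Bases outside the junction never affect the
   verdict. The filter applies to post-merge consensus qualities for
   paired data.
5. *Clone calling* (`call_clones()`): reads are grouped on the
   (V gene, J gene, CDR3 amino-acid sequence) key — allele suffixes after
   `*` are trimmed, so grouping is by gene name — and frequencies are
   normalised per sample. Out-of-frame or stop-containing junctions are
   excluded beforehand, since the analysis operates on amino-acid CDR3s.
6. *Contamination screen* (`contamination_check()`): a clone key observed
   at count ≤ 2 in one subject while another subject carries it at ≥ 100×
   that count is treated as cross-sample carry-over and removed; other
   cross-subject keys are flagged `public` and kept. The 100:1 ratio and
   the count ceiling of 2 are exposed parameters: the screen targets trace
   carry-over, which by nature is orders of magnitude below its source,
   while genuinely public clones show balanced abundances.

Every stage preserves read counts in the run report (input = assigned +
unassigned, and so on), which the tests assert.

## Expanded clones, impact, and overlap

A clone is *highly expanded* (HEC) at frequency ≥ 0.5% of its repertoire —
the conventional cut-off for blood. No established cut-off exists for
nerve tissue, where T cells do not normally reside; the package applies
the same threshold there by default but exposes it separately
(`pair_overlap(nerve_hec_threshold = …)`). The *impact* of a clone set is
the sum of its frequencies.

`pair_overlap()` classifies every clone key in the union of a subject's
two compartments as `nerve_restricted` (blood frequency exactly 0),
`blood_restricted`, or `shared`, with per-compartment HEC flags. Because
"absent" is sharp but sequencing is finite, a `near_restricted` flag
additionally marks clones whose blood frequency is below 0.1% — the same
floor the clustering analysis uses for inclusion — capturing "not detected
or detected only at very low frequency". `overlap_summary()` reduces the
records to counts and impacts per category, including the headline
`n_nerve_hecs` / `n_nerve_hecs_restricted` pair.

## CDR3 clustering and the dynamic threshold

Within a sample, relatedness between clones is measured by the Hamming
distance between CDR3 amino-acid sequences. Unequal-length pairs are
*undefined* — never connected, excluded from density estimation — keeping
pure Hamming semantics rather than silently switching to an edit
distance. The distance distribution of a repertoire is typically bimodal:
a low mode of related (convergent or mutationally adjacent) clones and a
high mode of unrelated ones. The clustering threshold is taken at the
valley between the two modes:

* Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
  evaluated on a grid of step 0.05 over `[0, max distance]`;
* the bandwidth is floored at 1 — Hamming distances live on the integer
  lattice, and an unfloored bandwidth on strongly discrete data can drop
  below the lattice spacing, manufacturing one "peak" per integer;
* peaks are strict local maxima of the gridded density; with two or more,
  the valley is the grid argmin between the two highest peaks, rounded
  down; with fewer, the method falls back;
* the threshold is never below 3 amino acids: `max(⌊valley⌋, 3)`.

Clusters are connected components of the `distance ≤ threshold` relation
(`build_clusters()`; a strict `<` flag exists because both conventions
appear in practice). When more than two density maxima exist, the
two-highest-maxima rule is a deliberate disambiguation, and the
integer-histogram valley (used as a brute-force oracle in the tests)
agrees with the KDE valley within ±1 on the validation mixture.

The cross-compartment network (`cross_compartment_network()`) asks a
different question with a fixed rule: are nerve-restricted clones
(frequency ≥ 0.1%) within ≤ 3 mismatches of any blood clone (frequency
≥ 0.1%)? Nodes carry origin, count and frequency; the number of nerve
nodes with at least one blood edge is the "prominent cluster" indicator.
Exports are edge-list TSV and GraphML; layout is left to downstream
viewers.

## The blood-sampling detection model

A 2.5 mL draw from a ~5 L blood volume samples 0.05% of circulating blood,
about 3,750,000 T cells at 1.5×10⁶ T cells/mL. With a per-cell probability
*q* of detecting at least one TCRβ transcript, a clone contributing *k*
cells to the sample is detected with probability `1 − (1 − q)^k` — at
*q* = 2.5%: ~2.5% for one cell, 22% for 10, 92% for 100. The per-cell 2.5%
is treated as a primitive parameter: multiplying the sampled fraction by
the 21 transcripts per cell gives ~1.05%, not 2.5%, so the value is not
derivable from the other stated quantities and is taken as given; the
forward per-transcript model (`per_cell_detection()` and its closed-form
inverse) is provided for sensitivity analysis, and a Monte-Carlo
cross-check (`monte_carlo_detection()`) verifies the closed form.

## What the synthetic generator emulates — and what it does not

Because no repertoire data are publicly deposited for this setting, the
package ships a generator whose defaults encode the study conditions:

* **Blood**: ~5,000 clones with frequencies from a discrete power law
  (`P(w = k) ∝ k^-2`, truncated at k = 2000). The truncation keeps the
  realised regime where most expanded clones sit between 0.5% and a few
  percent with a single dominant clone below 10%; an untruncated exponent-2
  tail routinely throws single clones above 10%, which is not the regime
  being modelled. A lognormal alternative is available.
* **Nerve**: a small repertoire (preset B: 150 clones sequenced to 5,928
  reads) dominated by HECs — exactly `n_nerve_restricted_hecs` clones
  absent from blood and `n_shared_hecs` at HEC level in both compartments.
  Low-frequency nerve clones are drawn from the blood pool at ~0.2% each
  (`low_clone_freq`), and the HECs share the remaining mass in proportion
  to draws from `U[1.2%, 1.8%]`. This allocation keeps every configured
  HEC several binomial standard deviations above the 0.5% cut-off and
  every non-HEC several below it at the preset depths, so the configured
  counts are recovered exactly from finite reads rather than only in
  expectation.
* **Restricted-clone CDR3s** are drawn independently of all blood CDR3s
  and at lengths ≥ 16 amino acids (7–10 random middle positions). With a
  toy germline of 8 V and 4 J genes the CDR3 flanks are shared by many
  clones, so very short random middles would make unrelated clones
  trivially relatable; the longer middles realise the intended
  sequence-independence, with a per-pair probability of a ≤ 3-mismatch
  collision around 10⁻⁵.
* **Reads** are multinomial draws over clone frequencies; each read is
  MID + V segment + middle codons + J segment with per-base substitution
  errors. An error base receives Phred < 30 with probability 0.9 (other
  bases Phred 37), a deliberate coupling that makes the CDR3 quality
  filter consequential and testable. Paired-end mode splits the template
  into two overlapping mates with independent errors.
* **Contamination** copies ≤ 2 reads per key of another subject's dominant
  blood clones into each sample, tagged with the recipient's MID and
  flagged in the ground truth; only donor clones abundant enough for the
  screen's 100:1 rule to be satisfiable are eligible, since trace
  carry-over from a rare clone would be biologically and statistically
  invisible. Genuinely public clones can be added at balanced moderate
  frequencies as specificity controls.

The generator does **not** model V(D)J recombination biology (nucleotide
insertion biases, allele usage), indel sequencing errors, UMI structure,
or real germline diversity. Passing tests therefore demonstrate that the
*analysis machinery* is correct under the stated statistical structure —
multinomial sampling, substitution noise, power-law clonality — not that
the pipeline handles every artefact of real amplicon chemistry.

## Numerical and design choices

* Coordinates are 0-based half-open internally; emitted tables follow the
  AIRR conventions. Qualities are Phred+33 throughout.
* All tie-breaks (V/J assignment, merging, HEC ordering) are total
  orders, so identical inputs give byte-identical outputs;
  `run_full_analysis()` writes a manifest (inputs, parameters, package
  version, seed) sufficient to replay a run exactly.
* The clone key collapses alleles to genes (`TRBV…*01 → TRBV…`), matching
  grouping by gene name; clone counts are abstract abundances (reads or
  UMIs) and no UMI deduplication is performed.
* Degenerate inputs are contracts, not crashes: empty read sets and empty
  repertoires flow through as empty tibbles; single-subject contamination
  checks warn and no-op; fewer than two defined distances is an error for
  the dynamic threshold.
* Test problem sizes: end-to-end recovery uses 25 blood + 15 nerve clones
  at depth 10⁴ (≥ 50× the rarest clone, so exact key recovery is the
  expected outcome and each observed count is checked against the central
  99% binomial interval of its true frequency); preset-B validation runs
  two to three subjects at the full preset depths; clustering correctness
  uses 200 clones against a brute-force transitive-closure oracle and 10⁴
  random pairs against a per-position Hamming oracle. The stochastic
  fixtures are seeded (20250218).

## Known limitations

* The ungapped aligner is intentionally minimal: real data with indels or
  substantial somatic variation should be annotated externally and
  imported via `read_airr()`.
* The contamination rule is a concretisation of "remove trace cross-subject
  carry-over"; site-specific index-hopping rates may warrant different
  parameters, which are exposed.
* The dynamic threshold assumes a coarsely bimodal distance distribution;
  on degenerate inputs it falls back to the 3-amino-acid floor rather than
  guessing.
* Per-patient results from real nerve biopsies cannot be reproduced here —
  no such data ship with the package; the synthetic scenarios exercise the
  identical code paths at matched problem sizes.
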