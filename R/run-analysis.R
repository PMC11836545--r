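#' Run the full paired-repertoire analysis
#'
#' Composes the whole workflow on either a simulated study or user FASTQ
#' input: (optionally) simulate a multi-subject study, write and re-read
#' the FASTQ/MID/germline files, run the read pipeline
#' ([process_reads()]), then per subject: HEC and impact statistics,
#' blood--nerve overlap classification, within-sample dynamic-threshold
#' clustering of the nerve repertoire, the cross-compartment relatedness
#' network, and the detection-probability curve. Every stage's table is
#' written as TSV under `out_dir`, plus GraphML for the networks, a
#' subject-level summary and a JSON run manifest (inputs, parameters,
#' package version, seed) sufficient to reproduce the outputs.
#'
#' @param config A configuration list or path to a YAML file. Recognised
#'   fields: `scenario` (preset name, default `"B"`), `seed`, `n_subjects`,
#'   `out_dir`, `hec_threshold`, `min_q`, `network_min_freq`,
#'   `network_max_mismatch`, plus any [scenario_config()] override under
#'   `scenario_overrides`. Alternatively `reads`/`mates`/`mids`/`germline`
#'   file paths for real input.
#' @param out_dir Output directory (overrides the config field).
#' @return Invisibly, a list with the output directory, the per-subject
#'   `summary` tibble, `clones`, and the run `manifest`.
#' @export
run_full_analysis <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfgv <- function(name, default) config[[name]] %||% default
  out_dir <- out_dir %||% cfgv("out_dir", tempfile("nervetcr_run_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hec_threshold <- cfgv("hec_threshold", 0.005)
  min_q <- cfgv("min_q", 30L)
  net_min_freq <- cfgv("network_min_freq", 0.001)
  net_max_mismatch <- cfgv("network_max_mismatch", 3L)

  simulated <- is.null(config$reads)
  if (simulated) {
    scen <- do.call(load_scenario, c(list(name = cfgv("scenario", "B")),
                                     config$scenario_overrides %||% list()))
    if (!is.null(config$seed)) scen$seed <- as.integer(config$seed)
    study <- simulate_study(scen, n_subjects = cfgv("n_subjects", 3L))
    germline <- study$germline
    mids <- study$mids
    sample_info <- study$sample_info
    # round-trip raw inputs through their file formats
    fq1 <- file.path(out_dir, "reads_R1.fastq")
    fq2 <- if (scen$paired_end) file.path(out_dir, "reads_R2.fastq") else NULL
    write_fastq(study$reads, fq1, mate_path2 = fq2)
    write_mid_map(mids, file.path(out_dir, "mids.tsv"))
    write_germline_fasta(germline, file.path(out_dir, "germline.fasta"))
    write_clone_table(study$truth$repertoires,
                      file.path(out_dir, "truth_clones.tsv"))
    readr::write_tsv(study$truth$provenance,
                     file.path(out_dir, "truth_provenance.tsv"), progress = FALSE)
    reads <- read_fastq(fq1, mate_path = fq2)
    manifest_inputs <- list(scenario = cfgv("scenario", "B"),
                            scenario_config = unclass(scen),
                            n_subjects = cfgv("n_subjects", 3L))
    seed_used <- scen$seed
  } else {
    reads <- read_fastq(config$reads, mate_path = config$mates)
    mids <- read_mid_map(config$mids)
    germline <- read_germline_fasta(config$germline)
    sample_info <- mutate(distinct(mids, .data$sample_id, .data$subject_id),
                          compartment = if_else(grepl("nerve", .data$sample_id),
                                                "nerve", "blood"))
    manifest_inputs <- config[c("reads", "mates", "mids", "germline")]
    seed_used <- cfgv("seed", NA_integer_)
  }

  res <- process_reads(reads, mids, germline, sample_info = sample_info,
                       min_q = min_q)
  write_airr(res$rearrangements, file.path(out_dir, "rearrangements.tsv"))
  write_clone_table(res$clones, file.path(out_dir, "clones.tsv"))
  readr::write_tsv(res$report, file.path(out_dir, "run_report.tsv"),
                   progress = FALSE)
  if (!is.null(res$contamination_report)) {
    readr::write_tsv(res$contamination_report,
                     file.path(out_dir, "contamination_report.tsv"),
                     progress = FALSE)
  }

  summaries <- list()
  for (subj in sort(unique(res$clones$subject_id))) {
    blood <- filter(res$clones, .data$subject_id == subj,
                    .data$compartment == "blood")
    nerve <- filter(res$clones, .data$subject_id == subj,
                    .data$compartment == "nerve")
    if (nrow(blood) == 0 && nrow(nerve) == 0) next
    records <- pair_overlap(blood, nerve, hec_threshold = hec_threshold)
    readr::write_tsv(records,
                     file.path(out_dir, sprintf("overlap_%s.tsv", subj)),
                     progress = FALSE)
    smry <- overlap_summary(records)
    if (nrow(nerve) >= 3) {
      thr <- dynamic_threshold(cpp_hamming_dists(nerve$cdr3_aa))
      clusters <- build_clusters(nerve, threshold = thr)
      readr::write_tsv(glance(thr),
                       file.path(out_dir, sprintf("threshold_%s.tsv", subj)),
                       progress = FALSE)
      write_edge_list(clusters,
                      file.path(out_dir, sprintf("clusters_%s_edges.tsv", subj)))
      smry$nerve_cluster_threshold <- thr$threshold
      smry$n_nerve_clusters <- clusters$n_clusters
    }
    if (nrow(blood) > 0 || nrow(nerve) > 0) {
      net <- cross_compartment_network(blood, nerve, min_freq = net_min_freq,
                                       max_mismatch = net_max_mismatch)
      write_edge_list(net, file.path(out_dir, sprintf("network_%s_edges.tsv", subj)))
      if (nrow(net$nodes) > 0) {
        write_clone_graphml(net, file.path(out_dir, sprintf("network_%s.graphml", subj)))
      }
      smry$n_nerve_linked_to_blood <- net$n_nerve_linked
    }
    summaries[[subj]] <- mutate(smry, subject_id = subj, .before = 1)
  }
  summary_tbl <- bind_rows(summaries)
  readr::write_tsv(summary_tbl, file.path(out_dir, "subject_summary.tsv"),
                   progress = FALSE)

  curve <- detection_curve(c(1L, 10L, 100L, 1000L))
  readr::write_tsv(curve, file.path(out_dir, "detection_curve.tsv"),
                   progress = FALSE)

  manifest <- list(
    package = "nervetcr",
    version = as.character(packageVersion("nervetcr")),
    seed = seed_used,
    inputs = manifest_inputs,
    parameters = list(hec_threshold = hec_threshold, min_q = min_q,
                      network_min_freq = net_min_freq,
                      network_max_mismatch = net_max_mismatch),
    outputs = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, summary = summary_tbl,
                 clones = res$clones, report = res$report,
                 manifest = manifest))
}
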