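#' Read a germline V/J reference FASTA
#'
#' The germline reference is the pluggable stand-in for a full germline
#' database: a FASTA whose headers carry the gene name, segment type and
#' anchor offset as `name|V|offset` (or `|J|`). The anchor offset is 0-based
#' and points at the first base of the codon encoding the conserved cysteine
#' (V segments) or the conserved phenylalanine/tryptophan (J segments); the
#' junction spans from the V anchor codon through the J anchor codon.
#'
#' Validation enforces unique gene names, segment types in `{V, J}`, and
#' that the anchor codon actually translates to `C` (V) or `F`/`W` (J).
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `gene_name`, `segment_type`, `sequence`,
#'   `anchor_offset`, sorted by gene name.
#' @seealso [toy_germline()] for the bundled 8 V / 4 J toy reference.
#' @export
read_germline_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("FASTA file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) format_error(sprintf("no FASTA records in '%s'", path))
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  recs <- purrr::map2(hdr_idx, ends, function(h, e) {
    fields <- strsplit(sub("^>", "", lines[h]), "|", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      format_error(sprintf(
        "germline header '%s' is not of the form 'name|V|offset'", lines[h]))
    }
    tibble(
      gene_name = fields[1],
      segment_type = fields[2],
      sequence = toupper(paste(lines[seq(h + 1L, e)], collapse = "")),
      anchor_offset = as.integer(fields[3])
    )
  })
  ref <- bind_rows(recs)
  validate_germline(ref)
}

#' @rdname read_germline_fasta
#' @param ref A germline tibble to validate.
#' @export
validate_germline <- function(ref) {
  stopifnot(all(c("gene_name", "segment_type", "sequence", "anchor_offset") %in% names(ref)))
  if (anyDuplicated(ref$gene_name)) {
    dup <- ref$gene_name[duplicated(ref$gene_name)][1]
    contract_error(sprintf("duplicate gene_name '%s' in germline reference", dup))
  }
  bad_type <- setdiff(unique(ref$segment_type), c("V", "J"))
  if (length(bad_type)) {
    contract_error(sprintf("segment_type must be V or J, found '%s'", bad_type[1]))
  }
  for (i in seq_len(nrow(ref))) {
    off <- ref$anchor_offset[i]
    seqlen <- nchar(ref$sequence[i])
    if (is.na(off) || off < 0L || off + 3L > seqlen) {
      contract_error(sprintf("gene '%s': anchor_offset %s outside sequence",
                             ref$gene_name[i], off))
    }
    codon <- substr(ref$sequence[i], off + 1L, off + 3L)
    aa <- translate_dna(codon)
    want <- if (ref$segment_type[i] == "V") "C" else c("F", "W")
    if (!aa %in% want) {
      contract_error(sprintf(
        "gene '%s': anchor codon '%s' translates to '%s', expected %s",
        ref$gene_name[i], codon, aa, paste(want, collapse = "/")))
    }
  }
  arrange(as_tibble(ref), .data$gene_name)
}

#' @rdname read_germline_fasta
#' @param germline A validated germline tibble.
#' @export
write_germline_fasta <- function(germline, path) {
  lines <- paste0(">", germline$gene_name, "|", germline$segment_type, "|",
                  germline$anchor_offset, "\n", germline$sequence)
  writeLines(lines, path)
  invisible(path)
}

#' Bundled toy germline reference (8 V, 4 J)
#'
#' A small synthetic germline used by the simulator and the examples. Every
#' V segment ends in four codons translating to a `CASS`-like motif with the
#' conserved cysteine anchored 12 bases before the segment end; every J
#' segment starts with four codons ending at the conserved F/W anchor.
#'
#' @return A validated germline tibble.
#' @export
toy_germline <- function() {
  read_germline_fasta(system.file("extdata", "toy_germline.fasta",
                                  package = "nervetcr", mustWork = TRUE))
}
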