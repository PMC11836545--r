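#' Decode and encode Phred+33 quality strings
#'
#' Sequencing base qualities travel as ASCII strings (Phred score + 33).
#' `phred_scores()` decodes one quality string to an integer vector;
#' `phred_string()` is its inverse.
#'
#' @param qual A single quality string.
#' @param scores An integer vector of Phred scores (0--60).
#' @return `phred_scores()`: integer vector of Phred scores.
#'   `phred_string()`: a single string.
#' @examples
#' phred_scores("II")   # c(40, 40)
#' phred_string(c(40, 40))
#' @export
phred_scores <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1L)
  utf8ToInt(qual) - 33L
}

#' @rdname phred_scores
#' @export
phred_string <- function(scores) {
  stopifnot(is.numeric(scores), all(scores >= 0), all(scores <= 60))
  intToUtf8(as.integer(scores) + 33L)
}


#' Translate DNA to amino acids (standard code)
#'
#' Vectorised translation of in-frame DNA strings. Codons containing `N`
#' translate to `X`; stop codons yield `*`. Sequences whose length is not a
#' multiple of three return `NA`.
#'
#' @param dna Character vector of DNA sequences.
#' @return Character vector of amino-acid sequences.
#' @export
translate_dna <- function(dna) {
  vapply(dna, function(s) {
    if (is.na(s)) return(NA_character_)
    n <- nchar(s)
    if (n %% 3L != 0L) return(NA_character_)
    if (n == 0L) return("")
    codons <- substring(toupper(s), seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(.codon_table[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement DNA strings
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(x)
}

# Hamming distance between two single equal-length strings; NA if unequal.
hamming1 <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) != nchar(b)) return(NA_integer_)
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Contract-error helper: consistent error classes for precondition failures.
contract_error <- function(msg, class = "nervetcr_contract_error") {
  abort(msg, class = c(class, "nervetcr_error"))
}

format_error <- function(msg) {
  abort(msg, class = c("nervetcr_format_error", "nervetcr_error"))
}
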