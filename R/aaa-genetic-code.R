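# Standard genetic code, indexed by codon. Stops are "*".
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIIMTTTTNNKKSSRR",  # ATT..AGG
    "VVVVAAAADDEEGGGG"   # GTT..GGG
  ), "")[[1]]
  # codon enumeration: 3rd base fastest, matching the string above
  codons <- character(64)
  k <- 1L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[k] <- paste0(b1, b2, b3); k <- k + 1L
  }
  setNames(aa, codons)
})
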