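# Standard (bacterial) genetic code machinery shared by the codon metrics.
# The degeneracy structure of the standard code partitions the 61 sense
# codons into 9 two-fold, 1 three-fold (Ile), 5 four-fold and 3 six-fold
# synonymous families, plus the single-codon families Met and Trp.

#' The 64 DNA codons in a fixed order
#' @return character vector of length 64.
#' @keywords internal
#' @noRd
all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Standard genetic code as a codon -> amino-acid map
#'
#' Amino acids are one-letter codes; stop codons map to `"*"`.
#' @return named character vector over the 64 codons.
#' @keywords internal
#' @noRd
std_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  out <- setNames(as.character(gc), names(gc))
  out[all_codons()]
}

#' @noRd
stop_codons <- function() {
  code <- std_genetic_code()
  names(code)[code == "*"]
}

# Synonymous families: list amino acid -> codons (stops excluded).
#' @noRd
synonymous_families <- function() {
  code <- std_genetic_code()
  code <- code[code != "*"]
  split(names(code), code)
}

# Degeneracy class (family size) per amino acid.
#' @noRd
family_degeneracy <- function() {
  vapply(synonymous_families(), length, integer(1L))
}
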