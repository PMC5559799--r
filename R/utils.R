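# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] for the
#' plain-character representation used throughout the package.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Round half away from zero; used wherever a fraction of pairs/contigs must
# become a whole count deterministically.
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

# Random DNA string using the current RNG stream.
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Number of matching characters between two equal-length strings.
n_matching <- function(a, b) {
  sum(charToRaw(a) == charToRaw(b))
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# sample() treats a length-1 numeric vector as 1:n; these never do.
resample <- function(v, k) v[sample.int(length(v), k)]
sample1 <- function(v) v[sample.int(length(v), 1L)]
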