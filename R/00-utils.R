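# Small sequence helpers shared across modules. Sequences are plain upper-case
# character scalars/vectors over {A,C,G,T,N}; "-" marks alignment gaps.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, gaps allowed).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[b])
}

# split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# random DNA of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Translate a codon with the standard (plastid) genetic code
#'
#' @param codon Character vector of 3-letter codons.
#' @return One-letter amino acids; `"*"` for stop, `NA` if the codon contains
#'   an ambiguous base.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa
}

is_stop_codon <- function(codon) {
  codon %in% c("TAA", "TAG", "TGA")
}

# validate alphabet on load (ambiguity codes other than N rejected)
check_alphabet <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGTN-]", toupper(seqs))
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N,-}: %s",
      where, paste(names(seqs)[bad] %||% which(bad), collapse = ", ")
    ))
  }
  invisible(toupper(seqs))
}

# map ungapped residue positions -> alignment columns for one gapped row
aln_column_map <- function(gapped_row) {
  ch <- seq_chars(gapped_row)
  which(ch != "-")
}

# overwrite substring (1-based) in a scalar string
str_assign <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

# deterministic child seed (kept below 2^31)
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
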