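#' Normalize a miRNA identifier for matching
#'
#' Identifier conventions differ between array annotation ("hsa-miR-22")
#' and running text ("miR-22").  Matching is therefore done on a
#' normalized form: lower case, with a leading "hsa-" stripped.
#' Proprietary probe ids (e.g. "miRplus-17952") pass through unchanged
#' apart from case.
#'
#' @param x character vector of miRNA ids.
#' @return character vector of normalized ids.
#' @examples
#' normalize_mirna_id(c("hsa-miR-22", "miR-22")) # both "mir-22"
#' @export
normalize_mirna_id <- function(x) {
  stopifnot(is.character(x))
  x <- tolower(x)
  sub("^hsa-", "", x)
}

# Internal: set equality on normalized miRNA ids.
mirna_setdiff <- function(a, b) {
  a[!(normalize_mirna_id(a) %in% normalize_mirna_id(b))]
}

mirna_intersect <- function(a, b) {
  a[normalize_mirna_id(a) %in% normalize_mirna_id(b)]
}

# Internal: run code with a temporarily seeded RNG, restoring state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Internal: DNA complement / reverse complement on plain character strings.
# Kept as simple chartr-based helpers so low-level scanning code does not
# round-trip through XStringSet objects for every window.
dna_complement <- function(x) chartr("ACGTUacgtu", "TGCAATGCAA", x)

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Internal: normalize a nucleotide string to DNA uppercase (U -> T).
as_dna <- function(x) chartr("u", "t", toupper(chartr("U", "T", x)))

# Internal: normalize to RNA uppercase (T -> U).
as_rna <- function(x) toupper(chartr("Tt", "Uu", x))

# Internal: all (possibly overlapping) start positions of a fixed
# pattern in a string.  gregexpr() only reports non-overlapping hits,
# which would miss self-overlapping seed matches.
find_overlapping <- function(pattern, x) {
  np <- nchar(pattern); L <- nchar(x)
  if (L < np) return(integer())
  starts <- seq_len(L - np + 1L)
  starts[substring(x, starts, starts + np - 1L) == pattern]
}

# Internal: deterministic TSV writer (fixed quoting/eol so identical
# inputs give byte-identical artifacts).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Mature sequence of hsa-miR-199a-5p
#'
#' The mature miRNA used throughout the worked examples
#' (5'-CCCAGUGUUCAGACUACCUGUUC-3').  Its seed (positions 2-7) is CCAGUG,
#' whose DNA seed match is CACTGG; extending the match to position 8
#' gives ACACTGG.
#'
#' @return a length-1 named character vector (RNA alphabet).
#' @export
mir199a5p_sequence <- function() {
  c(`hsa-miR-199a-5p` = "CCCAGUGUUCAGACUACCUGUUC")
}
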