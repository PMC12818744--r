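# Canonical amino-acid alphabet and sequence sanitization shared by all
# modules.  Everything downstream assumes uppercase sequences over the 20
# canonical letters, with "X" as the sentinel for anything else; k-mer
# windows containing the sentinel are excluded from motif counting.

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetical by one-letter code.  Used as the index for every
#' composition table in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sentinel letter standing in for non-canonical residues
#' @export
AA_SENTINEL <- "X"

#' Sanitize a protein sequence to the canonical alphabet
#'
#' Uppercases the input and replaces every letter outside the 20 canonical
#' amino acids (B, J, O, U, X, Z, ambiguity codes, gaps, ...) with the
#' sentinel `"X"`.  Motif counting skips any window containing the
#' sentinel, so non-canonical residues can never create or join a motif.
#'
#' @param x Character vector of sequences.
#' @param warn Emit one warning if any residue was replaced.
#' @return Character vector of sanitized sequences.
#' @export
sanitize_sequence <- function(x, warn = TRUE) {
  x <- toupper(x)
  bad <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  hits <- grepl(bad, x)
  if (any(hits)) {
    if (warn) {
      warning(sum(hits), " sequence(s) contained non-canonical residues; ",
              "replaced with sentinel '", AA_SENTINEL, "'")
    }
    x[hits] <- gsub(bad, AA_SENTINEL, x[hits])
  }
  x
}

#' @keywords internal
assert_nonempty_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  invisible(sequence)
}

# Family labels used for protein metadata; counts in the curated study
# database were 79/42/21/27/17/10 across the six functional families.
FAMILY_LEVELS <- c("RNA-binding", "DNA-binding", "chromatin-binding",
                   "regulation", "hydrolase", "structure", "none")

#' Split a string into its residues
#' @keywords internal
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]
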