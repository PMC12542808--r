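# Shared low-level helpers.

# Characters treated as "not an unambiguous residue". "-" is a gap, "N" and
# "?" are missing; all three count as non-unambiguous for occupancy, identity
# denominators and tip-masking character counts.
MISSING_CHARS <- c("-", "N", "?")

# IUPAC degenerate codes other than N (kept verbatim in baits, but weighted
# into the N-fraction).
DEGENERATE_CHARS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Round half away from zero
#'
#' Commercial-rounding variant used for all reported means and percentages
#' (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1)
  if (length(seqs) == 0) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# Remove gap characters ("-") from sequences; missing codes are retained.
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Count of unambiguous residues per sequence.
n_unambiguous <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(!ch %in% MISSING_CHARS)
  }, integer(1), USE.NAMES = FALSE)
}

# Count of missing characters (gap + N + ?) per sequence.
n_missing_chars <- function(x) nchar(x) - n_unambiguous(x)
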