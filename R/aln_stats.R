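# Column-occupancy trimming and alignment informativeness statistics.

#' Trim alignment columns by occupancy
#'
#' Removes columns where the fraction of sequences carrying an unambiguous
#' residue (not `-`, `N`, `?`) is below `min_col_occupancy`. The sequence
#' set is unchanged; an all-columns-removed result is returned (zero-width)
#' with a warning.
#'
#' @param aln A [dna_alignment()].
#' @param min_col_occupancy Minimum kept-column occupancy (default 0.1).
#' @return The trimmed [dna_alignment()].
#' @export
trim_by_occupancy <- function(aln, min_col_occupancy = 0.1) {
  m <- seq_matrix(unclass(aln))
  occ <- colMeans(!matrix(m %in% MISSING_CHARS, nrow = nrow(m)))
  keep <- occ >= min_col_occupancy
  if (!any(keep)) {
    warn("Occupancy trimming removed every column.")
    return(dna_alignment(setNames(rep("", length(aln)), names(aln)),
                         multicopy = TRUE))
  }
  seqs <- apply(m[, keep, drop = FALSE], 1, paste0, collapse = "")
  dna_alignment(setNames(seqs, names(aln)), multicopy = TRUE)
}

#' Alignment informativeness statistics
#'
#' Percent missing data (gap + ambiguous cells over all cells), variable
#' sites (columns with at least two distinct unambiguous states) and
#' parsimony-informative sites (columns with at least two unambiguous states
#' each carried by at least two sequences). Gaps and ambiguity codes never
#' count as character states. Percentages are reported to 1 decimal, half
#' away from zero.
#'
#' @param aln A [dna_alignment()].
#' @return A one-row tibble: `length`, `pct_missing`, `n_variable`,
#'   `n_parsimony_informative`, `pct_parsimony_informative`.
#' @export
alignment_informativeness <- function(aln) {
  if (!inherits(aln, "dna_alignment") || alignment_length(aln) == 0) {
    abort("Empty alignment.", class = "exonbaits_empty_input_error")
  }
  m <- seq_matrix(unclass(aln))
  missing <- matrix(m %in% MISSING_CHARS, nrow = nrow(m))
  classify <- function(col, miss) {
    states <- table(col[!miss])
    c(variable = length(states) >= 2,
      pi = sum(states >= 2) >= 2)
  }
  cls <- vapply(seq_len(ncol(m)), function(j) classify(m[, j], missing[, j]),
                logical(2))
  n_var <- sum(cls["variable", ])
  n_pi <- sum(cls["pi", ])
  tibble(
    length = ncol(m),
    pct_missing = round_half_away(mean(missing) * 100, 1),
    n_variable = as.integer(n_var),
    n_parsimony_informative = as.integer(n_pi),
    pct_parsimony_informative = round_half_away(n_pi / ncol(m) * 100, 1)
  )
}

#' Informativeness table over a set of alignments
#'
#' @param alignments Named list of [dna_alignment()] objects (names = locus
#'   ids), or a directory of FASTA files.
#' @param min_col_occupancy Optional occupancy trimming applied before the
#'   statistics (`NULL` to skip).
#' @return A tibble with one row per alignment (`locus` + the
#'   [alignment_informativeness()] columns).
#' @export
alignment_stats_table <- function(alignments, min_col_occupancy = NULL) {
  if (is.character(alignments) && length(alignments) == 1 &&
      dir.exists(alignments)) {
    paths <- list.files(alignments, pattern = "\\.fa(sta)?$", full.names = TRUE)
    alignments <- setNames(lapply(paths, read_alignment),
                           sub("\\.fa(sta)?$", "", basename(paths)))
  }
  bind_rows(imap(alignments, function(a, nm) {
    if (!is.null(min_col_occupancy)) a <- trim_by_occupancy(a, min_col_occupancy)
    mutate(alignment_informativeness(a), locus = nm, .before = 1)
  }))
}
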