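#' DNA multiple alignment
#'
#' A light container for an aligned set of DNA sequences: a named character
#' vector of equal-length upper-case strings over `A C G T N - ?` plus IUPAC
#' degenerate codes. Taxon labels must be unique unless `multicopy = TRUE`
#' (gene-family alignments carrying several copies per taxon).
#'
#' @param sequences Named character vector (names = taxon labels).
#' @param multicopy Allow duplicate taxon labels.
#' @return A `dna_alignment` object.
#' @examples
#' aln <- dna_alignment(c(tax1 = "ACGT", tax2 = "AC-T"))
#' alignment_length(aln)
#' @export
dna_alignment <- function(sequences, multicopy = FALSE) {
  if (length(sequences) < 1) {
    abort("An alignment needs at least one record.", class = "exonbaits_format_error")
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("All records must be labelled.", class = "exonbaits_format_error")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    abort(
      sprintf("Ragged alignment: sequence lengths %s.",
              paste(unique(lens), collapse = ", ")),
      class = "exonbaits_shape_error"
    )
  }
  if (!multicopy && anyDuplicated(names(sequences))) {
    abort("Duplicate taxon labels in a single-copy alignment.",
          class = "exonbaits_format_error")
  }
  structure(sequences, class = "dna_alignment")
}

#' @rdname dna_alignment
#' @param x A `dna_alignment`.
#' @export
alignment_length <- function(x) {
  stopifnot(inherits(x, "dna_alignment"))
  nchar(x[[1]])
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d sequence(s) x %d column(s)\n",
              length(x), alignment_length(x)))
  shown <- head(seq_along(x), 6)
  for (i in shown) {
    s <- unclass(x)[[i]]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-20s %s\n", names(x)[i], s))
  }
  if (length(x) > 6) cat(sprintf("  ... %d more\n", length(x) - 6))
  invisible(x)
}

#' @export
`[.dna_alignment` <- function(x, i, ...) {
  dna_alignment(unclass(x)[i], multicopy = TRUE)
}

#' Tidy view of an alignment
#'
#' @param x A [dna_alignment()].
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `sequence`, `ungapped_length`,
#'   `n_missing` (gap + ambiguous characters).
#' @export
as_tibble.dna_alignment <- function(x, ...) {
  tibble(
    taxon = names(x),
    sequence = unname(unclass(x)),
    ungapped_length = nchar(ungap(unclass(x))),
    n_missing = n_missing_chars(unclass(x))
  )
}

# Column slice of an alignment (0-based half-open on alignment columns).
slice_columns <- function(aln, from0, to0) {
  stopifnot(from0 >= 0, to0 <= alignment_length(aln), from0 < to0)
  dna_alignment(substr(unclass(aln), from0 + 1, to0), multicopy = TRUE)
}
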