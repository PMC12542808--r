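# Overlap of the designed panel with external bait sets, by reference-gene
# identity or by exact sequence search.

# Normalize gene ids: case-insensitive, version suffixes (".1", ".2", ...)
# stripped.
normalize_gene_id <- function(ids) {
  toupper(sub("\\.\\d+$", "", ids))
}

#' Locus overlap by reference-gene identity
#'
#' Case-insensitive exact id matching after stripping version suffixes
#' (`AT1G01010.1` matches `at1g01010`).
#'
#' @param panel_gene_ids,other_gene_ids Character vectors of gene ids.
#' @return A list with `count` and the sorted `shared` ids (normalized).
#' @export
overlap_by_gene_id <- function(panel_gene_ids, other_gene_ids) {
  shared <- sort(intersect(
    unique(normalize_gene_id(panel_gene_ids)),
    unique(normalize_gene_id(other_gene_ids))
  ))
  list(count = length(shared), shared = shared)
}

# Does any window of length m of `query` occur exactly in any panel
# sequence? Checked on the given strand only.
has_exact_block <- function(query, panel, m) {
  if (nchar(query) < m) return(FALSE)
  windows <- unique(substring(query, 1:(nchar(query) - m + 1), m:nchar(query)))
  for (w in windows) {
    if (any(stringr::str_detect(panel, stringr::fixed(w)))) return(TRUE)
  }
  FALSE
}

#' Locus overlap by exact sequence search
#'
#' A query sequence matches the panel when it shares an exact substring of
#' at least `min_exact_match` bp with any panel sequence on either strand
#' (reverse-complement matching on by default, since the strand of external
#' target files is not guaranteed). Each query counts at most once.
#'
#' @param panel_sequences,query_sequences Named character vectors
#'   (id -> DNA sequence).
#' @param min_exact_match Minimum exact shared block, bp (default 100).
#' @param both_strands Also search the query's reverse complement.
#' @return A list with `count` and a tibble `pairs` (`query_id`, `panel_id`)
#'   of the first panel hit per matching query.
#' @export
overlap_by_sequence_search <- function(panel_sequences, query_sequences,
                                       min_exact_match = 100,
                                       both_strands = TRUE) {
  panel <- toupper(panel_sequences)
  queries <- toupper(query_sequences)
  hits <- purrr::imap(queries, function(q, qid) {
    forms <- if (both_strands) c(q, revcomp(q)) else q
    for (p in seq_along(panel)) {
      for (f in forms) {
        if (has_exact_block(f, panel[[p]], min_exact_match)) {
          return(tibble(query_id = qid, panel_id = names(panel)[p]))
        }
      }
    }
    NULL
  })
  pairs <- bind_rows(hits)
  if (nrow(pairs) == 0) {
    pairs <- tibble(query_id = character(), panel_id = character())
  }
  list(count = nrow(pairs), pairs = pairs)
}
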