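# Gene- and exon-level filtering cascade: candidate single-copy genes ->
# exon alignments -> final ranked exon panel.

#' Build a gene-candidate table
#'
#' @param gene_id Character vector of gene ids (cross-reference ortholog
#'   names, e.g. Arabidopsis gene names).
#' @param alignments List of [dna_alignment()] objects, one per gene.
#' @param reference_source Reference-genome label(s); recycled.
#' @return A tibble with columns `gene_id`, `reference_source` (list-column),
#'   `alignment` (list-column).
#' @export
gene_candidates <- function(gene_id, alignments, reference_source = "ref") {
  stopifnot(length(gene_id) == length(alignments), all(nzchar(gene_id)))
  tibble(
    gene_id = gene_id,
    reference_source = rep(list(reference_source), length(gene_id)),
    alignment = alignments
  )
}

#' Filter candidate genes on length and taxon coverage
#'
#' Retains genes whose shortest ungapped sequence is at least
#' `config$min_gene_len` and that cover at least `config$min_taxa` distinct
#' taxa (both bounds inclusive). Input order is preserved.
#'
#' @param candidates Tibble from [gene_candidates()].
#' @param config A [design_config()].
#' @return The surviving rows, with `min_ungapped_len` and `n_taxa` columns
#'   added.
#' @export
filter_candidate_genes <- function(candidates, config = design_config()) {
  candidates %>%
    mutate(
      min_ungapped_len = map_int(.data$alignment, function(a) {
        min(nchar(ungap(unclass(a))))
      }),
      n_taxa = map_int(.data$alignment, function(a) {
        length(unique(names(a)))
      })
    ) %>%
    filter(
      .data$min_ungapped_len >= config$min_gene_len,
      .data$n_taxa >= config$min_taxa
    )
}

#' Merge gene-candidate sets found against different reference genomes
#'
#' Takes one candidate table per reference genome and merges them by gene id
#' (the shared ortholog naming). A gene found against k references carries
#' all k labels in `reference_source`; its representative alignment is the
#' one with the most taxa (ties: longer alignment, then the alphabetically
#' first reference).
#'
#' @param per_reference Named list of candidate tibbles (names = reference
#'   labels).
#' @return One merged candidate tibble.
#' @export
merge_across_references <- function(per_reference) {
  stopifnot(is.list(per_reference), !is.null(names(per_reference)))
  stacked <- bind_rows(lapply(names(per_reference), function(ref) {
    per_reference[[ref]] %>%
      select("gene_id", "alignment") %>%
      mutate(.ref = ref)
  }))
  stacked %>%
    mutate(
      .n_taxa = map_int(.data$alignment, ~ length(unique(names(.x)))),
      .len = map_int(.data$alignment, ~ alignment_length(.x))
    ) %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$.n_taxa), desc(.data$.len), .data$.ref,
            .by_group = TRUE) %>%
    summarise(
      reference_source = list(sort(unique(.data$.ref))),
      alignment = .data$alignment[1],
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id) %>%
    select("gene_id", "reference_source", "alignment")
}

# Map an interval on the reference taxon's ungapped sequence to alignment
# columns (both 0-based half-open). Internal gap columns of the reference
# inside the interval are included in the slice.
map_ungapped_interval <- function(ref_seq, start0, end0) {
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-") # alignment columns holding residues, 1-based
  L <- length(residue_cols)
  if (end0 > L) {
    abort(
      sprintf("Exon interval [%d, %d) exceeds ungapped reference length %d.",
              start0, end0, L),
      class = "exonbaits_coordinate_error"
    )
  }
  c(from0 = residue_cols[start0 + 1] - 1L, to0 = residue_cols[end0])
}

#' Split a gene alignment into exon alignments
#'
#' Exon coordinates refer to the reference taxon's ungapped sequence; each
#' exon alignment is the column slice of the gene alignment spanning that
#' interval mapped through the reference's gap pattern. Sequences that are
#' all-gap within an exon are dropped from that exon.
#'
#' @param gene One row of a candidate tibble, or a [dna_alignment()] plus
#'   `gene_id`.
#' @param coords Exon coordinate tibble ([read_exon_coordinates()] schema),
#'   filtered to this gene's rows or carrying its `gene_id`.
#' @param reference_taxon Taxon whose ungapped sequence the coordinates
#'   reference; must be present in the alignment.
#' @param gene_id Gene id (defaults to `gene$gene_id` when `gene` is a row).
#' @return A tibble with columns `gene_id`, `exon_index`, `alignment`
#'   (list-column of exon alignments).
#' @export
split_into_exons <- function(gene, coords, reference_taxon, gene_id = NULL) {
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1)
    gene_id <- gene$gene_id
    aln <- gene$alignment[[1]]
  } else {
    aln <- gene
    stopifnot(!is.null(gene_id))
  }
  if (!reference_taxon %in% names(aln)) {
    abort(sprintf("Reference taxon '%s' absent from alignment.", reference_taxon),
          class = "exonbaits_data_error")
  }
  rows <- coords[coords$gene_id == gene_id, , drop = FALSE]
  ref_seq <- unclass(aln)[[match(reference_taxon, names(aln))]]
  out <- pmap(
    list(rows$exon_index, rows$start, rows$end),
    function(idx, s, e) {
      cols <- map_ungapped_interval(ref_seq, s, e)
      sub <- slice_columns(aln, cols[["from0"]], cols[["to0"]])
      keep <- nchar(ungap(unclass(sub))) > 0
      tibble(gene_id = gene_id, exon_index = as.integer(idx),
             alignment = list(sub[keep]))
    }
  )
  bind_rows(out)
}

#' Mean pairwise identity of an alignment
#'
#' For every unordered pair of sequences, identity is the fraction of
#' matching columns among columns where both members carry an unambiguous
#' residue (gaps, `N` and `?` excluded from that pair's denominator), times
#' 100. The returned value is the mean over pairs; pairs with zero comparable
#' columns are excluded from the mean.
#'
#' @param aln A [dna_alignment()] with at least two sequences.
#' @return Mean pairwise identity in percent.
#' @export
mean_pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (length(aln) < 2) {
    abort("Pairwise identity needs at least two sequences.",
          class = "exonbaits_arity_error")
  }
  m <- seq_matrix(unclass(aln))
  good <- !matrix(m %in% MISSING_CHARS, nrow = nrow(m))
  ids <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      ok <- good[i, ] & good[j, ]
      comparable <- sum(ok)
      if (comparable == 0) next
      ids <- c(ids, sum(m[i, ok] == m[j, ok]) / comparable * 100)
    }
  }
  if (length(ids) == 0) {
    abort("All sequence pairs share no comparable columns; identity undefined.",
          class = "exonbaits_undefined_identity_error")
  }
  mean(ids)
}

#' Annotate exon loci with length and identity
#'
#' @param exons Exon tibble ([split_into_exons()] schema).
#' @return The tibble with `aln_length`, `ungapped_min_len` and
#'   `mean_pairwise_identity` columns added (identity is `NA` for
#'   single-sequence exons).
#' @export
annotate_exons <- function(exons) {
  exons %>%
    mutate(
      aln_length = map_int(.data$alignment, alignment_length),
      ungapped_min_len = map_int(.data$alignment, function(a) {
        min(nchar(ungap(unclass(a))))
      }),
      mean_pairwise_identity = map_dbl(.data$alignment, function(a) {
        if (length(a) < 2) return(NA_real_)
        tryCatch(mean_pairwise_identity(a), exonbaits_undefined_identity_error =
                   function(e) NA_real_)
      })
    )
}

#' Filter exon loci on length and identity
#'
#' Retains exons whose alignment length is at least `config$min_exon_len`
#' and whose mean pairwise identity lies within
#' `[config$identity_lo, config$identity_hi]`, both bounds inclusive.
#'
#' @param exons Exon tibble; annotated via [annotate_exons()] if needed.
#' @param config A [design_config()].
#' @param use_ungapped_length Measure the length criterion on the shortest
#'   ungapped sequence instead of the alignment length.
#' @return The surviving rows.
#' @export
filter_exons <- function(exons, config = design_config(),
                         use_ungapped_length = FALSE) {
  if (nrow(exons) == 0) return(exons)
  if (!"mean_pairwise_identity" %in% names(exons)) exons <- annotate_exons(exons)
  len <- if (use_ungapped_length) exons$ungapped_min_len else exons$aln_length
  keep <- len >= config$min_exon_len &
    !is.na(exons$mean_pairwise_identity) &
    exons$mean_pairwise_identity >= config$identity_lo &
    exons$mean_pairwise_identity <= config$identity_hi
  exons[keep, , drop = FALSE]
}

#' Trim low-occupancy alignment edges
#'
#' Automated stand-in for manual inspection of alignment starts and ends:
#' removes terminal columns while their occupancy (fraction of sequences
#' with an unambiguous residue) is below `min_edge_occupancy`.
#'
#' @param aln A [dna_alignment()].
#' @param min_edge_occupancy Occupancy below which terminal columns are
#'   trimmed (default 0.5).
#' @return The trimmed alignment (may be empty-width; a warning is emitted).
#' @export
trim_alignment_edges <- function(aln, min_edge_occupancy = 0.5) {
  m <- seq_matrix(unclass(aln))
  occ <- colMeans(!matrix(m %in% MISSING_CHARS, nrow = nrow(m)))
  lo <- 1
  hi <- length(occ)
  while (lo <= hi && occ[lo] < min_edge_occupancy) lo <- lo + 1
  while (hi >= lo && occ[hi] < min_edge_occupancy) hi <- hi - 1
  if (hi < lo) {
    warn("Edge trimming removed every column.")
    return(dna_alignment(setNames(rep("", length(aln)), names(aln)),
                         multicopy = TRUE))
  }
  slice_columns(aln, lo - 1, hi)
}

#' Select the final exon panel across reference genomes
#'
#' Exons are keyed by `(gene_id, exon_index)`. Ranking prioritizes exons
#' that passed the filters against the most reference genomes (descending),
#' then orders by gene id and exon index. With `strict_sequence = TRUE`,
#' a reference contributes to an exon's provenance only when its alignment
#' is byte-identical to the representative's.
#'
#' @param per_reference_exons Named list of filtered exon tibbles (names =
#'   reference labels).
#' @param top_n Optionally keep only the first `top_n` ranked exons.
#' @param strict_sequence Require byte-identical alignments across
#'   references.
#' @return A ranked exon tibble with `references` (list-column) and `n_refs`.
#' @export
select_final_exons <- function(per_reference_exons, top_n = NULL,
                               strict_sequence = FALSE) {
  stopifnot(is.list(per_reference_exons), !is.null(names(per_reference_exons)))
  stacked <- bind_rows(lapply(names(per_reference_exons), function(ref) {
    tbl <- per_reference_exons[[ref]]
    if (nrow(tbl) == 0) return(NULL)
    tbl %>% mutate(.ref = ref)
  }))
  if (is.null(stacked) || nrow(stacked) == 0) {
    return(tibble(gene_id = character(), exon_index = integer(),
                  alignment = list(), references = list(),
                  n_refs = integer()))
  }
  ranked <- stacked %>%
    group_by(.data$gene_id, .data$exon_index) %>%
    arrange(.data$.ref, .by_group = TRUE) %>%
    summarise(
      alignment = .data$alignment[1],
      references = list({
        refs <- .data$.ref
        if (strict_sequence) {
          rep_seq <- unclass(.data$alignment[[1]])
          same <- map_lgl(.data$alignment, function(a) {
            identical(unclass(a), rep_seq)
          })
          refs <- refs[same]
        }
        sort(unique(refs))
      }),
      .groups = "drop"
    ) %>%
    mutate(n_refs = lengths(.data$references)) %>%
    arrange(desc(.data$n_refs), .data$gene_id, .data$exon_index)
  if (!is.null(top_n)) ranked <- head(ranked, top_n)
  ranked
}
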