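# Representative selection, fixed-length probe tiling, bait QC and
# capture-space statistics.

# Deterministic ranking of candidate sequences within one side of an exon:
# fewest missing characters, then longest ungapped sequence, then
# alphabetical taxon label.
rank_candidates <- function(taxa, seqs) {
  miss <- n_missing_chars(seqs)
  ulen <- nchar(ungap(seqs))
  order(miss, -ulen, taxa)
}

#' Select per-exon representative sequences
#'
#' Reduces an exon alignment to at most two sequences for bait design: one
#' from the ingroup genus and one from any other genus in the clade. Within
#' each side the representative is the sequence with the fewest missing
#' characters (ties: longest ungapped sequence, then alphabetical taxon
#' label). When only one side is present a single representative is returned
#' with a warning.
#'
#' @param exon A [dna_alignment()] or one exon-tibble row.
#' @param ingroup_taxa Character vector of ingroup taxon labels.
#' @return A tibble with columns `taxon`, `sequence` (ungapped), `role`
#'   (`"ingroup"`/`"outgroup"`).
#' @export
select_representatives <- function(exon, ingroup_taxa) {
  aln <- if (is.data.frame(exon)) exon$alignment[[1]] else exon
  stopifnot(inherits(aln, "dna_alignment"))
  if (length(aln) == 0) {
    abort("Exon has no sequences.", class = "exonbaits_empty_locus_error")
  }
  taxa <- names(aln)
  seqs <- unclass(aln)
  is_in <- taxa %in% ingroup_taxa
  pick_side <- function(side) {
    if (!any(side)) return(NULL)
    ord <- rank_candidates(taxa[side], seqs[side])
    best <- which(side)[ord[1]]
    tibble(taxon = taxa[best], sequence = ungap(seqs[[best]]))
  }
  ing <- pick_side(is_in)
  out <- pick_side(!is_in)
  if (is.null(ing) || is.null(out)) {
    warn("Exon has representatives on only one side (ingroup/outgroup).")
  }
  bind_rows(
    if (!is.null(ing)) mutate(ing, role = "ingroup"),
    if (!is.null(out)) mutate(out, role = "outgroup")
  )
}

#' Build a target set from a final exon panel
#'
#' Applies [select_representatives()] to every exon of a ranked panel and
#' assembles the capture target table. Locus ids are `gene-exon` composites
#' (`<gene_id>_e<exon_index>`).
#'
#' @param final_exons Ranked exon tibble from [select_final_exons()].
#' @param ingroup_taxa Character vector of ingroup taxon labels.
#' @param all_taxa Keep every sequence of each exon (the assembly-reference
#'   layout) instead of the two bait-design representatives.
#' @return A tibble with columns `locus_id`, `taxon`, `sequence`, `role`.
#' @export
build_target_set <- function(final_exons, ingroup_taxa, all_taxa = FALSE) {
  rows <- pmap(
    list(final_exons$gene_id, final_exons$exon_index, final_exons$alignment),
    function(gid, idx, aln) {
      lid <- paste0(gid, "_e", idx)
      if (all_taxa) {
        tibble(
          locus_id = lid,
          taxon = names(aln),
          sequence = ungap(unclass(aln)),
          role = ifelse(names(aln) %in% ingroup_taxa, "ingroup", "outgroup")
        )
      } else {
        select_representatives(aln, ingroup_taxa) %>%
          mutate(locus_id = lid) %>%
          select("locus_id", "taxon", "sequence", "role")
      }
    }
  )
  bind_rows(rows)
}

# GC and ambiguity fractions of bait sequences. Degenerate IUPAC codes other
# than N count toward the N-fraction at half weight by default, full weight
# in strict mode.
bait_composition <- function(seqs, strict_ambiguity = FALSE) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  len <- nchar(seqs)
  gc <- vapply(chars, function(ch) sum(ch %in% c("G", "C")), numeric(1))
  nn <- vapply(chars, function(ch) sum(ch == "N"), numeric(1))
  deg <- vapply(chars, function(ch) sum(ch %in% DEGENERATE_CHARS), numeric(1))
  w <- if (strict_ambiguity) 1 else 0.5
  tibble(gc_fraction = gc / len, n_fraction = (nn + w * deg) / len)
}

#' Tile fixed-length baits along a target sequence
#'
#' Baits of `config$bait_len` nucleotides are laid down every
#' `round(bait_len / tiling_density)` bases starting at position 0 (2x
#' density with 80-nt baits gives a 40-bp step). When the sequence length is
#' not commensurate with the step, one terminal bait anchored at
#' `L - bait_len` is appended so no 3' tail is left uncovered; duplicate
#' start positions collapse. Sequences shorter than one bait yield zero
#' baits with a warning.
#'
#' @param sequence Ungapped DNA string.
#' @param locus_id,taxon Identifiers carried into the bait table.
#' @param config A [design_config()].
#' @param strict_ambiguity Weight degenerate codes fully in `n_fraction`.
#' @return A tibble with columns `locus_id`, `taxon`, `start` (0-based),
#'   `sequence`, `gc_fraction`, `n_fraction`.
#' @export
tile_baits <- function(sequence, locus_id = "locus", taxon = "taxon",
                       config = design_config(), strict_ambiguity = FALSE) {
  stopifnot(length(sequence) == 1, !grepl("-", sequence, fixed = TRUE))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  step <- floor(config$bait_len / config$tiling_density + 0.5)
  if (step < 1) {
    abort("Tiling step rounds to zero; lower the tiling density.",
          class = "exonbaits_config_error")
  }
  empty <- tibble(
    locus_id = character(), taxon = character(), start = integer(),
    sequence = character(), gc_fraction = numeric(), n_fraction = numeric()
  )
  if (L < config$bait_len) {
    warn(sprintf("Sequence '%s' (%d bp) is shorter than one bait (%d nt); no baits.",
                 locus_id, L, config$bait_len))
    return(empty)
  }
  last <- L - config$bait_len
  starts <- seq(0L, last, by = step)
  if (last %% step != 0) starts <- c(starts, last) # terminal 3'-anchored bait
  starts <- unique(as.integer(starts))
  seqs <- substring(sequence, starts + 1, starts + config$bait_len)
  bind_cols(
    tibble(locus_id = locus_id, taxon = taxon, start = starts, sequence = seqs),
    bait_composition(seqs, strict_ambiguity)
  )
}

#' Tile a whole target set
#'
#' @param target_set Tibble with `locus_id`, `taxon`, `sequence`.
#' @param config A [design_config()].
#' @param strict_ambiguity See [tile_baits()].
#' @return One bait tibble over all target sequences.
#' @export
tile_target_set <- function(target_set, config = design_config(),
                            strict_ambiguity = FALSE) {
  bind_rows(pmap(
    list(target_set$sequence, target_set$locus_id, target_set$taxon),
    function(s, lid, tax) {
      tryCatch(
        tile_baits(s, lid, tax, config, strict_ambiguity),
        warning = function(w) {
          tibble(locus_id = character(), taxon = character(),
                 start = integer(), sequence = character(),
                 gc_fraction = numeric(), n_fraction = numeric())
        }
      )
    }
  ))
}

#' Quality-control a bait table
#'
#' Rejects baits whose GC fraction falls outside `[gc_min, gc_max]` or whose
#' ambiguity fraction exceeds `max_n`; exact-duplicate bait sequences
#' collapse to their first occurrence.
#'
#' @param baits Bait tibble from [tile_baits()]/[tile_target_set()].
#' @param gc_min,gc_max Inclusive GC-fraction bounds.
#' @param max_n Maximum tolerated ambiguity fraction.
#' @return A list with `kept` (bait tibble) and `rejected` (bait tibble with
#'   a `reason` column).
#' @export
qc_baits <- function(baits, gc_min = 0.25, gc_max = 0.75, max_n = 0) {
  reason <- rep(NA_character_, nrow(baits))
  reason[baits$gc_fraction < gc_min | baits$gc_fraction > gc_max] <- "gc_out_of_range"
  reason[baits$n_fraction > max_n] <- "too_many_ambiguities"
  dup <- duplicated(baits$sequence)
  reason[is.na(reason) & dup] <- "duplicate_sequence"
  list(
    kept = baits[is.na(reason), , drop = FALSE],
    rejected = mutate(baits[!is.na(reason), , drop = FALSE],
                      reason = reason[!is.na(reason)])
  )
}

#' Capture-space statistics of a target set
#'
#' Per-locus length is the mean ungapped sequence length over that locus's
#' representatives; the capture space is the sum over loci.
#'
#' @param target_set Tibble with `locus_id`, `sequence`.
#' @return A one-row tibble: `capture_space_bp`, `n_loci`, `mean_locus_len`
#'   (2 decimals, half away from zero), `min_locus_len`, `max_locus_len`.
#' @export
capture_space_stats <- function(target_set) {
  if (nrow(target_set) == 0) {
    abort("Empty target set.", class = "exonbaits_empty_input_error")
  }
  per_locus <- target_set %>%
    group_by(.data$locus_id) %>%
    summarise(len = mean(nchar(ungap(.data$sequence))), .groups = "drop")
  tibble(
    capture_space_bp = sum(per_locus$len),
    n_loci = nrow(per_locus),
    mean_locus_len = round_half_away(mean(per_locus$len), 2),
    min_locus_len = min(per_locus$len),
    max_locus_len = max(per_locus$len)
  )
}
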