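#' Read an aligned FASTA file
#'
#' Parses via [Biostrings::readBStringSet()] so that `?` placeholders survive,
#' upper-cases all residues and checks the equal-length invariant.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param multicopy Allow duplicate taxon labels (multi-copy gene families).
#' @return A [dna_alignment()] with records in file order.
#' @export
read_alignment <- function(path, multicopy = FALSE) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Not a readable FASTA file: ", path),
            class = "exonbaits_format_error", parent = e)
    }
  )
  if (length(set) == 0) {
    abort(paste0("Empty FASTA file: ", path), class = "exonbaits_format_error")
  }
  seqs <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  dna_alignment(seqs, multicopy = multicopy)
}

#' Read an unaligned FASTA sequence set
#'
#' For target files and other per-locus sequence collections where records
#' legitimately differ in length (use [read_alignment()] for alignments).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("Empty FASTA file: ", path), class = "exonbaits_format_error")
  }
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

# Plain FASTA writer, fixed 60-column wrap, upper-case as given.
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write an alignment to FASTA
#'
#' @param aln A [dna_alignment()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60) {
  stopifnot(inherits(aln, "dna_alignment"))
  write_fasta(unclass(aln), path, width = width)
}

#' Write a capture target file
#'
#' Writes the reference sequences of a target set as FASTA with headers
#' following the `Taxon-LocusID` convention used by capture-assembly
#' pipelines (single hyphen separator, so taxon labels must be hyphen-free).
#' Sequences are written ungapped; record order is locus id, then taxon.
#'
#' @param target_set A tibble with columns `locus_id`, `taxon`, `sequence`
#'   (such as built by [build_target_set()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(target_set, path) {
  stopifnot(all(c("locus_id", "taxon", "sequence") %in% names(target_set)))
  if (any(grepl("-", target_set$taxon, fixed = TRUE))) {
    bad <- unique(target_set$taxon[grepl("-", target_set$taxon, fixed = TRUE)])
    abort(
      paste0("Taxon label(s) contain the header separator '-': ",
             paste(bad, collapse = ", ")),
      class = "exonbaits_naming_error"
    )
  }
  ord <- order(target_set$locus_id, target_set$taxon)
  seqs <- setNames(
    toupper(ungap(target_set$sequence[ord])),
    paste0(target_set$taxon[ord], "-", target_set$locus_id[ord])
  )
  write_fasta(seqs, path)
}

#' Read exon coordinates from GFF3
#'
#' Consumes rows of feature type `exon`, grouped by the gene attribute
#' (`gene_id`, `gene`, or `Parent`, in that order of preference). GFF
#' 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention at this boundary; exons are numbered in ascending
#' coordinate order within each gene.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `exon_index`, `start`, `end`
#'   (0-based half-open on the gene's ungapped reference sequence).
#' @export
read_exon_coordinates <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) {
    abort("No exon features in GFF3 file.", class = "exonbaits_format_error")
  }
  mc <- S4Vectors::mcols(gr)
  gene <- NULL
  for (cand in c("gene_id", "gene", "Parent")) {
    if (cand %in% names(mc)) {
      gene <- as.character(unlist(mc[[cand]]))
      break
    }
  }
  if (is.null(gene)) {
    abort("GFF3 exon rows carry no gene_id/gene/Parent attribute.",
          class = "exonbaits_format_error")
  }
  tbl <- tibble(
    gene_id = gene,
    start = BiocGenerics::start(gr) - 1L, # GFF 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(gr)
  ) %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(exon_index = row_number()) %>%
    ungroup() %>%
    select("gene_id", "exon_index", "start", "end")
  overlaps <- tbl %>%
    group_by(.data$gene_id) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-n()] & n() > 1)) %>%
    filter(.data$bad)
  if (nrow(overlaps) > 0) {
    abort(
      paste0("Overlapping exons within gene(s): ",
             paste(overlaps$gene_id, collapse = ", ")),
      class = "exonbaits_coordinate_error"
    )
  }
  tbl
}

#' Write exon coordinates as GFF3
#'
#' Inverse of [read_exon_coordinates()]: internal 0-based half-open intervals
#' become GFF3 1-based inclusive `exon` rows with a `gene_id` attribute.
#'
#' @param coords Tibble with `gene_id`, `exon_index`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_coordinates <- function(coords, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\texonbaits\texon\t%d\t%d\t.\t+\t.\tgene_id=%s",
            coords$gene_id, coords$start + 1L, coords$end,
            coords$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}
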