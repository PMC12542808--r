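#' Bait-design configuration
#'
#' Bundles every numeric threshold the design and evaluation workflow uses.
#' Defaults correspond to a clade-specific bait set designed from
#' transcriptome-derived single-copy gene alignments: genes at least 500 bp
#' long covered by at least three taxa; exon alignments at least 500 bp with
#' mean pairwise identity between 75% and 98% (inclusive); 80-nt baits tiled
#' at 2x density; recovery counted at the 50% and 75% of-target-length
#' thresholds; alignment columns kept when at least 10% of sequences carry an
#' unambiguous residue.
#'
#' @param min_gene_len Minimum gene length in bp (shortest ungapped sequence).
#' @param min_taxa Minimum number of distinct taxa per gene.
#' @param min_exon_len Minimum exon alignment length in bp.
#' @param identity_lo,identity_hi Inclusive bounds (percent) on mean pairwise
#'   identity of an exon alignment.
#' @param bait_len Bait length in nucleotides.
#' @param tiling_density Tiling density; 2 means a new bait starts every half
#'   bait-length.
#' @param recovery_thresholds Fractions of the mean target length at which
#'   per-locus recovery is counted (strictly greater-than).
#' @param min_col_occupancy Minimum fraction of sequences with an unambiguous
#'   residue for an alignment column to be kept.
#' @return A `design_config` list.
#' @examples
#' cfg <- design_config()
#' cfg$bait_len / cfg$tiling_density # tiling step in bp
#' @export
design_config <- function(min_gene_len = 500L,
                          min_taxa = 3L,
                          min_exon_len = 500L,
                          identity_lo = 75,
                          identity_hi = 98,
                          bait_len = 80L,
                          tiling_density = 2.0,
                          recovery_thresholds = c(0.50, 0.75),
                          min_col_occupancy = 0.1) {
  stopifnot(
    min_gene_len >= 1, min_taxa >= 1, min_exon_len >= 1,
    identity_lo > 0, identity_lo <= identity_hi, identity_hi <= 100,
    bait_len >= 1, tiling_density > 0,
    all(recovery_thresholds > 0), all(recovery_thresholds <= 1),
    min_col_occupancy > 0, min_col_occupancy <= 1
  )
  structure(
    list(
      min_gene_len = as.integer(min_gene_len),
      min_taxa = as.integer(min_taxa),
      min_exon_len = as.integer(min_exon_len),
      identity_lo = identity_lo,
      identity_hi = identity_hi,
      bait_len = as.integer(bait_len),
      tiling_density = tiling_density,
      recovery_thresholds = sort(recovery_thresholds),
      min_col_occupancy = min_col_occupancy
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  gene filter : >= %d bp, >= %d taxa\n", x$min_gene_len, x$min_taxa))
  cat(sprintf("  exon filter : >= %d bp, identity in [%g, %g]%%\n",
              x$min_exon_len, x$identity_lo, x$identity_hi))
  cat(sprintf("  tiling      : %d-nt baits at %gx density\n",
              x$bait_len, x$tiling_density))
  cat(sprintf("  recovery    : > %s of target length\n",
              paste0(x$recovery_thresholds * 100, "%", collapse = ", > ")))
  cat(sprintf("  occupancy   : >= %g per column\n", x$min_col_occupancy))
  invisible(x)
}

#' Read a design configuration from a YAML-ish key: value file
#'
#' Plain `key: value` lines; unknown keys error. Lists (recovery thresholds)
#' are comma-separated.
#'
#' @param path Path to the config file.
#' @return A [design_config()].
#' @export
read_design_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), character(1))
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = ":"))
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  args <- setNames(vals, keys)
  allowed <- names(formals(design_config))
  bad <- setdiff(names(args), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(design_config, args)
}
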