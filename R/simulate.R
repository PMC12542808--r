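# Seeded simulators for every input class the toolkit consumes: ortholog
# alignments with exon structure, capture recovery tables, and gene trees
# with controlled discordance. All generators are pure functions of their
# arguments plus the seed.

# Evolve sequences down a tree by per-site substitution (no indels): each
# site mutates along each edge with probability subst_prob, to a uniformly
# chosen different base.
evolve_on_tree <- function(tree, len, subst_prob) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(bases, len, replace = TRUE)
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) { # phylo edges are in preorder
    par <- edge[i, 1]
    child <- edge[i, 2]
    s <- seqs[[par]]
    mut <- runif(len) < subst_prob
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    seqs[[child]] <- s
  }
  setNames(
    vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""),
           character(1)),
    tree$tip.label
  )
}

# Independent straight-loop identity computation used only for truth tables
# (kept separate from mean_pairwise_identity on purpose).
truth_identity <- function(seqs) {
  if (length(seqs) < 2) return(NA_real_)
  mat <- do.call(rbind, strsplit(unname(toupper(seqs)), ""))
  vals <- c()
  for (i in 1:(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      ok <- !(mat[i, ] %in% MISSING_CHARS) & !(mat[j, ] %in% MISSING_CHARS)
      if (sum(ok) == 0) next
      vals <- c(vals, 100 * sum(mat[i, ok] == mat[j, ok]) / sum(ok))
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Simulate ortholog gene alignments with exon structure
#'
#' Genes evolve along a random labelled topology by per-site substitution;
#' exon boundaries are recorded on the first taxon (the gapless reference).
#' Optional taxon dropout and terminal missingness exercise the coverage and
#' occupancy filters. A truth table records each gene/exon's length, taxon
#' coverage and realized mean pairwise identity so that filter outcomes are
#' predictable.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (length-2) of exons per gene.
#' @param exon_len Integer range of exon lengths, bp.
#' @param n_taxa Number of taxa; the first `ingroup_size` are the ingroup.
#' @param ingroup_size Ingroup taxon count.
#' @param subst_prob Per-site per-edge substitution probability.
#' @param taxon_dropout Probability a non-reference taxon is absent from a
#'   gene.
#' @param missing_frac Probability a sequence gets a masked terminal chunk.
#' @param seed Integer seed fixing all randomness.
#' @return A list: `alignments` (named list of [dna_alignment()]), `coords`
#'   (exon coordinate tibble), `truth` (list of `genes` and `exons` tibbles),
#'   `ingroup_taxa`, `reference_taxon`.
#' @export
simulate_ortholog_alignments <- function(n_genes = 20,
                                         exons_per_gene = c(1, 3),
                                         exon_len = c(400, 900),
                                         n_taxa = 8,
                                         ingroup_size = 5,
                                         subst_prob = 0.02,
                                         taxon_dropout = 0,
                                         missing_frac = 0,
                                         seed = 1) {
  stopifnot(ingroup_size < n_taxa, ingroup_size >= 1)
  set.seed(seed)
  taxa <- c(sprintf("Ingroup_sp%02d", seq_len(ingroup_size)),
            sprintf("Outgroup_sp%02d", seq_len(n_taxa - ingroup_size)))
  reference_taxon <- taxa[1]
  alignments <- list()
  coords <- list()
  truth_genes <- list()
  truth_exons <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%04d", g)
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
    lens <- sample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
    total <- sum(lens)
    topo <- ape::rtree(n_taxa, tip.label = sample(taxa))
    seqs <- evolve_on_tree(topo, total, subst_prob)[taxa]
    keep <- c(TRUE, runif(n_taxa - 1) >= taxon_dropout)
    seqs <- seqs[keep]
    if (missing_frac > 0) {
      for (t in seq_along(seqs)[-1]) {
        if (runif(1) < missing_frac) {
          cut <- sample.int(floor(total * 0.3), 1)
          substr(seqs[t], total - cut + 1, total) <- strrep("-", cut)
        }
      }
    }
    aln <- dna_alignment(seqs)
    alignments[[gid]] <- aln
    ends <- cumsum(lens)
    starts <- c(0L, head(ends, -1))
    coords[[gid]] <- tibble(gene_id = gid, exon_index = seq_len(n_ex),
                            start = as.integer(starts), end = as.integer(ends))
    truth_genes[[gid]] <- tibble(
      gene_id = gid, n_taxa = length(seqs),
      min_ungapped_len = min(nchar(ungap(seqs))), total_len = total
    )
    truth_exons[[gid]] <- tibble(
      gene_id = gid, exon_index = seq_len(n_ex), length = as.integer(lens),
      n_taxa = length(seqs),
      mean_pairwise_identity = vapply(seq_len(n_ex), function(e) {
        sub <- substr(seqs, starts[e] + 1, ends[e])
        keep_seq <- nchar(gsub("-", "", sub, fixed = TRUE)) > 0
        truth_identity(sub[keep_seq])
      }, numeric(1))
    )
  }
  list(
    alignments = alignments,
    coords = bind_rows(coords),
    truth = list(genes = bind_rows(truth_genes), exons = bind_rows(truth_exons)),
    ingroup_taxa = taxa[seq_len(ingroup_size)],
    reference_taxon = reference_taxon
  )
}

#' Simulate a capture recovery table
#'
#' Emulates the long-format per-sample, per-locus output of a capture
#' assembly: recovered lengths drawn as fractions of the target length with
#' a sample-specific mean, an optional linear specimen-age effect on that
#' mean, locus dropout, and paralog flags injected at a fixed rate. Read
#' counts and on-target fractions are drawn from ranges matching published
#' herbarium capture experiments (millions of reads, 13-39% on target).
#'
#' @param target_lengths Named numeric vector: locus id -> mean target
#'   length (bp).
#' @param n_samples Number of samples.
#' @param age_range Specimen-age range, years.
#' @param base_recovery Range of per-sample mean recovery fraction.
#' @param age_slope Change in mean recovery fraction per year of age.
#' @param dropout Probability a locus yields no sequence in a sample.
#' @param paralog_rate Per-locus probability of a depth-based paralog flag.
#' @param reads_range,on_target_range Ranges for total reads and mapped
#'   fraction.
#' @param seed Integer seed.
#' @return A list: `records` (long tibble for [build_sample_stats()]) and
#'   `samples` (per-sample tibble with `sample`, `age`, `mean_recovery`).
#' @export
simulate_recovery_table <- function(target_lengths,
                                    n_samples = 23,
                                    age_range = c(5, 95),
                                    base_recovery = c(0.75, 0.95),
                                    age_slope = 0,
                                    dropout = 0.03,
                                    paralog_rate = 0.05,
                                    reads_range = c(2.8e6, 1.4e7),
                                    on_target_range = c(0.13, 0.39),
                                    seed = 1) {
  set.seed(seed)
  loci <- names(target_lengths)
  stopifnot(!is.null(loci), all(target_lengths > 0))
  samples <- sprintf("sample%03d", seq_len(n_samples))
  ages <- round(runif(n_samples, age_range[1], age_range[2]))
  base <- runif(n_samples, base_recovery[1], base_recovery[2])
  mean_rec <- pmin(pmax(base + age_slope * (ages - mean(age_range)), 0), 1)
  recs <- lapply(seq_len(n_samples), function(s) {
    reads <- round(runif(1, reads_range[1], reads_range[2]))
    mapped <- round(reads * runif(1, on_target_range[1], on_target_range[2]))
    frac <- pmin(pmax(rnorm(length(loci), mean_rec[s], 0.08), 0), 1)
    frac[runif(length(loci)) < dropout] <- 0
    depth_flag <- rbinom(length(loci), 1, paralog_rate)
    tibble(
      sample = samples[s], locus = loci,
      recovered_len = round(frac * target_lengths),
      target_len = unname(target_lengths),
      reads = reads, mapped = mapped,
      paralog_len = depth_flag * rbinom(length(loci), 1, 0.8),
      paralog_depth = depth_flag
    )
  })
  list(
    records = bind_rows(recs),
    samples = tibble(sample = samples, age = ages, mean_recovery = mean_rec)
  )
}

# One nearest-neighbour interchange at the given internal edge row of
# tree$edge (child must be an internal node). alt = 1 or 2 picks which child
# subtree of the edge's lower node is swapped with its "uncle" subtree.
apply_nni <- function(tree, edge_row, alt = 1) {
  edge <- tree$edge
  u <- edge[edge_row, 1]
  v <- edge[edge_row, 2]
  ntip <- length(tree$tip.label)
  stopifnot(v > ntip)
  v_child_rows <- which(edge[, 1] == v)
  u_other_rows <- setdiff(which(edge[, 1] == u), edge_row)
  stopifnot(length(v_child_rows) >= 2, length(u_other_rows) >= 1)
  r1 <- v_child_rows[alt]
  r2 <- u_other_rows[1]
  tmp <- edge[r1, 2]
  edge[r1, 2] <- edge[r2, 2]
  edge[r2, 2] <- tmp
  tree$edge <- edge
  tree <- ape::reorder.phylo(tree, "cladewise")
  # canonicalize node numbering
  ape::read.tree(text = ape::write.tree(tree))
}

#' Simulate gene trees around a species tree
#'
#' Each gene tree equals the species tree with probability
#' `1 - discordance_prob`; otherwise one random nearest-neighbour
#' interchange is applied at a random internal branch (or at `nni_edge`
#' when pinned). Optional duplicate-tip injection (labels `taxon@1`,
#' `taxon@2`) supports tip-masking tests.
#'
#' @param species_tree An ape `phylo` (branch lengths optional).
#' @param n_trees Number of gene trees.
#' @param discordance_prob Probability a gene tree is one NNI away.
#' @param nni_edge Optional row index into `species_tree$edge` pinning the
#'   rearranged branch (must point at an internal child node).
#' @param dup_rate Per-tip probability of injecting a duplicate copy.
#' @param seed Integer seed.
#' @return A list of `phylo` gene trees.
#' @export
simulate_gene_trees <- function(species_tree, n_trees,
                                discordance_prob = 0,
                                nni_edge = NULL,
                                dup_rate = 0,
                                seed = 1) {
  set.seed(seed)
  if (is.null(species_tree$edge.length)) {
    species_tree <- ape::compute.brlen(species_tree, 1)
  }
  ntip <- length(species_tree$tip.label)
  internal_rows <- which(species_tree$edge[, 2] > ntip)
  lapply(seq_len(n_trees), function(i) {
    gt <- species_tree
    if (length(internal_rows) > 0 && runif(1) < discordance_prob) {
      row <- if (is.null(nni_edge)) {
        internal_rows[sample.int(length(internal_rows), 1)]
      } else {
        nni_edge
      }
      gt <- apply_nni(gt, row, alt = sample(1:2, 1))
    }
    if (dup_rate > 0) {
      for (tip in species_tree$tip.label) {
        if (runif(1) < dup_rate && tip %in% gt$tip.label) {
          idx <- match(tip, gt$tip.label)
          gt$tip.label[idx] <- paste0(tip, "@1")
          single <- structure(
            list(edge = matrix(c(2L, 1L), 1, 2),
                 tip.label = paste0(tip, "@2"),
                 edge.length = 0.1, Nnode = 1L),
            class = "phylo"
          )
          gt <- ape::bind.tree(gt, single, where = idx, position = 0.05)
        }
      }
    }
    gt
  })
}
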