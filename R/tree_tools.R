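# Same-taxon tip masking on gene trees and per-branch quartet concordance
# between a species tree and a set of gene trees. Trees are ape "phylo"
# objects; unrooted semantics throughout (branches are identified by their
# leaf bipartition, so input rooting is irrelevant).

# Taxon of a leaf label: the part before the reserved "@" copy separator.
taxon_of <- function(labels) sub("@.*$", "", labels)

#' Unambiguous character counts from an alignment
#'
#' Convenience for feeding [mask_monophyletic_tips()]: counts residues that
#' are not `-`, `N` or `?` per sequence.
#'
#' @param aln A [dna_alignment()] (typically occupancy-trimmed).
#' @return Named integer vector (leaf label -> count).
#' @export
char_counts_from_alignment <- function(aln) {
  setNames(n_unambiguous(unclass(aln)), names(aln))
}

# Pick the index to KEEP among competing same-taxon leaves: most unambiguous
# characters; ties broken by lexicographically smallest label.
best_leaf <- function(labels, counts) {
  ord <- order(-counts, labels)
  ord[1]
}

#' Mask duplicate same-taxon tips on a gene tree
#'
#' For every monophyletic clade of same-taxon leaves, and for paraphyletic
#' grades interrupted only by same-taxon leaves, all but the leaf with the
#' most unambiguous characters are pruned (ties: lexicographically smallest
#' label). Degree-2 nodes left by pruning are suppressed. Singleton taxa are
#' never touched.
#'
#' @param tree An ape `phylo` with leaf labels `taxon` or `taxon@copy`.
#' @param char_counts Named vector of unambiguous character counts covering
#'   every leaf (see [char_counts_from_alignment()]).
#' @return The masked `phylo`.
#' @export
mask_monophyletic_tips <- function(tree, char_counts) {
  missing_leaves <- setdiff(tree$tip.label, names(char_counts))
  if (length(missing_leaves) > 0) {
    abort(paste0("No character count for leaf/leaves: ",
                 paste(missing_leaves, collapse = ", ")),
          class = "exonbaits_data_error")
  }
  repeat {
    tips <- tree$tip.label
    ntip <- length(tips)
    if (ntip <= 2 || !anyDuplicated(taxon_of(tips))) break
    edge <- tree$edge
    parent_of <- function(node) {
      p <- edge[edge[, 2] == node, 1]
      if (length(p) == 0) NA_integer_ else p
    }
    children_of <- function(node) edge[edge[, 1] == node, 2]
    taxa <- taxon_of(tips)
    to_drop <- NULL
    for (i in seq_len(ntip)) {
      p <- parent_of(i)
      if (is.na(p)) next
      sibs <- setdiff(children_of(p), i)
      tip_sibs <- sibs[sibs <= ntip]
      rivals <- tip_sibs[taxa[tip_sibs] == taxa[i]]
      # paraphyletic rule: a tip whose parent's sibling is a same-taxon tip
      g <- parent_of(p)
      if (!is.na(g)) {
        uncles <- setdiff(children_of(g), p)
        uncle_tips <- uncles[uncles <= ntip]
        rivals <- c(rivals, uncle_tips[taxa[uncle_tips] == taxa[i]])
      }
      if (length(rivals) > 0) {
        grp <- unique(c(i, rivals))
        keep <- grp[best_leaf(tips[grp], char_counts[tips[grp]])]
        to_drop <- setdiff(grp, keep)
        break
      }
    }
    if (is.null(to_drop)) break
    tree <- ape::drop.tip(tree, tips[to_drop], collapse.singles = TRUE)
  }
  tree
}

# Leaf-label sets under every node of a phylo (rooted representation).
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  function(node) {
    if (node <= ntip) tree$tip.label[node] else tree$tip.label[pp[[node - ntip]]]
  }
}

# Classify the unrooted quartet topology induced by a gene tree for taxa
# q = c(a, b, c, d): returns the 2-element set paired with q[1], or NULL when
# the quartet is unresolved (polytomy).
induced_pairing <- function(split_sets, q) {
  for (s in split_sets) {
    inter <- intersect(s, q)
    if (length(inter) == 2) {
      if (q[1] %in% inter) return(setdiff(inter, q[1]))
      return(setdiff(setdiff(q, inter), q[1]))
    }
  }
  NULL
}

#' Per-branch quartet concordance of gene trees with a species tree
#'
#' For every internal branch of the (unrooted) species tree, the four taxon
#' clusters around the branch are formed; for each quartet (one taxon per
#' cluster) and each gene tree containing all four taxa, the induced
#' unrooted quartet topology is classified as the main topology (the
#' species-tree pairing), the first alternative (cluster 1 paired with
#' cluster 3) or the second alternative (cluster 1 paired with cluster 4).
#' Within each side of a branch, clusters are ordered by their smallest leaf
#' label — a fixed, arbitrary labelling convention for the two alternatives.
#' Frequencies are totals over gene trees and quartets, normalized.
#'
#' Branches whose endpoints are multifurcating (more than four clusters) and
#' branches with no resolvable quartet are reported with
#' `n_quartets_sampled` / zero counts rather than silently dropped.
#'
#' @param species_tree An ape `phylo`; rooting is ignored.
#' @param gene_trees List (or `multiPhylo`) of single-copy gene trees whose
#'   taxa are a subset of the species tree's.
#' @param max_quartets_per_branch Cap on sampled quartets per branch
#'   (`Inf` = exhaustive enumeration).
#' @param seed Optional integer seeding the quartet subsampling.
#' @return A tibble of class `quartet_support`: `branch` (sorted leaf set of
#'   the smaller bipartition side), `n_quartets_sampled`, `n_trees_used`,
#'   `f_main`, `f_alt1`, `f_alt2` (NA when nothing was resolvable).
#' @export
quartet_frequencies <- function(species_tree, gene_trees,
                                max_quartets_per_branch = Inf,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  for (gt in gene_trees) {
    if (anyDuplicated(taxon_of(gt$tip.label))) {
      abort("Gene trees must be single-copy (mask duplicate tips first).",
            class = "exonbaits_data_error")
    }
  }
  st <- ape::unroot(species_tree)
  ntip <- length(st$tip.label)
  tipset <- node_tip_sets(st)
  root <- ntip + 1L
  edge <- st$edge
  children_of <- function(node) edge[edge[, 1] == node, 2]

  # Precompute gene-tree split sets (clades of the rooted representation;
  # each clade is one side of an unrooted split) and leaf sets.
  gt_splits <- lapply(gene_trees, function(gt) {
    pp <- ape::prop.part(gt)
    lapply(pp, function(ix) gt$tip.label[ix])
  })
  gt_leaves <- lapply(gene_trees, function(gt) gt$tip.label)

  internal_edges <- which(edge[, 2] > ntip)
  records <- lapply(internal_edges, function(ei) {
    u <- edge[ei, 1]
    v <- edge[ei, 2]
    v_side <- tipset(v)
    other_side <- setdiff(st$tip.label, v_side)
    small <- if (length(v_side) <= length(other_side)) v_side else other_side
    branch_id <- paste(sort(small), collapse = ",")
    rec0 <- tibble(branch = branch_id, n_quartets_sampled = 0L,
                   n_trees_used = 0L, f_main = NA_real_,
                   f_alt1 = NA_real_, f_alt2 = NA_real_)
    # Clusters on v's side: v's children subtrees.
    v_kids <- children_of(v)
    # Clusters on u's side.
    u_kids <- setdiff(children_of(u), v)
    if (u == root) {
      u_clusters <- lapply(u_kids, tipset)
    } else {
      up_side <- setdiff(st$tip.label, tipset(u))
      u_clusters <- c(lapply(u_kids, tipset), list(up_side))
    }
    v_clusters <- lapply(v_kids, tipset)
    if (length(u_clusters) != 2 || length(v_clusters) != 2 ||
        any(lengths(c(u_clusters, v_clusters)) == 0)) {
      return(rec0) # multifurcation or degenerate branch: reported, not scored
    }
    # Fixed labelling: within each side, order clusters by smallest label.
    ord_u <- order(vapply(u_clusters, min, character(1)))
    ord_v <- order(vapply(v_clusters, min, character(1)))
    cl <- c(u_clusters[ord_u], v_clusters[ord_v]) # C1, C2 | C3, C4

    sizes <- lengths(cl)
    n_total <- prod(sizes)
    if (is.finite(max_quartets_per_branch) && n_total > max_quartets_per_branch) {
      quartets <- replicate(max_quartets_per_branch,
                            vapply(cl, sample, character(1), size = 1),
                            simplify = FALSE)
    } else {
      grid <- expand.grid(cl, stringsAsFactors = FALSE)
      quartets <- lapply(seq_len(nrow(grid)), function(r) unlist(grid[r, ]))
    }
    counts <- c(main = 0, alt1 = 0, alt2 = 0)
    trees_used <- logical(length(gene_trees))
    for (q in quartets) {
      for (g in seq_along(gene_trees)) {
        if (!all(q %in% gt_leaves[[g]])) next
        mate <- induced_pairing(gt_splits[[g]], q)
        if (is.null(mate)) next
        trees_used[g] <- TRUE
        # q = (c1, c2, c3, c4); pairing of c1 decides the class
        cls <- if (q[2] %in% mate) "main" else if (q[3] %in% mate) "alt1" else "alt2"
        counts[cls] <- counts[cls] + 1
      }
    }
    total <- sum(counts)
    rec0$n_quartets_sampled <- length(quartets)
    rec0$n_trees_used <- sum(trees_used)
    if (total > 0) {
      rec0$f_main <- counts[["main"]] / total
      rec0$f_alt1 <- counts[["alt1"]] / total
      rec0$f_alt2 <- counts[["alt2"]] / total
    }
    rec0
  })
  out <- bind_rows(records)
  class(out) <- c("quartet_support", class(out))
  out
}
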