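# Fixture builders and independent brute-force oracles. The oracles
# deliberately re-derive every quantity with straightforward loops, staying
# independent of the package's implementation paths.

aln <- function(...) dna_alignment(c(...))

random_aln <- function(n_seq, len, alphabet = c("A", "C", "G", "T"),
                       missing_prob = 0) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    if (missing_prob > 0) {
      miss <- runif(len) < missing_prob
      ch[miss] <- sample(c("-", "N", "?"), sum(miss), replace = TRUE)
    }
    paste0(ch, collapse = "")
  }, character(1))
  dna_alignment(setNames(seqs, sprintf("t%02d", seq_len(n_seq))))
}

# --- pairwise identity oracle: explicit double loop over pairs/columns ----
oracle_pairwise_identity <- function(a) {
  seqs <- unclass(a)
  miss <- c("-", "N", "?")
  ids <- c()
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (j <= i) next
      x <- strsplit(seqs[[i]], "")[[1]]
      y <- strsplit(seqs[[j]], "")[[1]]
      matches <- 0
      comparable <- 0
      for (k in seq_along(x)) {
        if (x[k] %in% miss || y[k] %in% miss) next
        comparable <- comparable + 1
        if (x[k] == y[k]) matches <- matches + 1
      }
      if (comparable > 0) ids <- c(ids, 100 * matches / comparable)
    }
  }
  mean(ids)
}

# --- site-class oracle: per-column tabulation ----------------------------
oracle_site_classes <- function(a) {
  seqs <- unclass(a)
  miss <- c("-", "N", "?")
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  n_var <- 0
  n_pi <- 0
  n_missing_cells <- 0
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    n_missing_cells <- n_missing_cells + sum(col %in% miss)
    states <- table(col[!col %in% miss])
    if (length(states) >= 2) n_var <- n_var + 1
    if (sum(states >= 2) >= 2) n_pi <- n_pi + 1
  }
  list(
    n_variable = n_var, n_pi = n_pi,
    pct_missing = 100 * n_missing_cells / length(mat)
  )
}

# --- tiling oracle: exhaustive enumeration of start positions ------------
oracle_tile_starts <- function(L, bait_len = 80, step = 40) {
  if (L < bait_len) return(integer(0))
  starts <- c()
  s <- 0
  while (s <= L - bait_len) {
    starts <- c(starts, s)
    s <- s + step
  }
  if (!((L - bait_len) %in% starts)) starts <- c(starts, L - bait_len)
  sort(unique(starts))
}

# --- quartet oracle ------------------------------------------------------
# Pairing of the first taxon in a 4-leaf induced subtree, via keep.tip and
# cherry detection; NULL when unresolved.
oracle_quartet_pairing <- function(tree, q) {
  sub <- ape::unroot(ape::keep.tip(tree, q))
  edge <- sub$edge
  ntip <- length(sub$tip.label)
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    tipkids <- kids[kids <= ntip]
    if (length(tipkids) == 2) {
      pair <- sub$tip.label[tipkids]
      if (q[1] %in% pair) return(setdiff(pair, q[1]))
      return(setdiff(setdiff(q, pair), q[1]))
    }
  }
  NULL
}

# Per-branch quartet frequencies re-derived from scratch: the tree is
# treated as an undirected graph and the four clusters around an internal
# edge are found by breadth-first reachability with the edge's endpoints
# blocked.
oracle_quartet_freqs <- function(species_tree, gene_trees) {
  st <- ape::unroot(species_tree)
  ntip <- length(st$tip.label)
  edge <- st$edge
  nodes <- max(edge)
  adj <- lapply(seq_len(nodes), function(i) {
    c(edge[edge[, 1] == i, 2], edge[edge[, 2] == i, 1])
  })
  reach_tips <- function(from, blocked) {
    seen <- c(from)
    queue <- from
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (nb %in% seen || nb == blocked) next
        seen <- c(seen, nb)
        queue <- c(queue, nb)
      }
    }
    st$tip.label[seen[seen <= ntip]]
  }
  res <- list()
  for (i in which(edge[, 2] > ntip)) {
    u <- edge[i, 1]
    v <- edge[i, 2]
    v_side <- reach_tips(v, blocked = u)
    o_side <- setdiff(st$tip.label, v_side)
    small <- if (length(v_side) <= length(o_side)) v_side else o_side
    branch <- paste(sort(small), collapse = ",")
    cu <- lapply(setdiff(adj[[u]], v), function(w) reach_tips(w, blocked = u))
    cv <- lapply(setdiff(adj[[v]], u), function(w) reach_tips(w, blocked = v))
    if (length(cu) != 2 || length(cv) != 2) next
    cu <- cu[order(vapply(cu, min, character(1)))]
    cv <- cv[order(vapply(cv, min, character(1)))]
    counts <- c(main = 0, alt1 = 0, alt2 = 0)
    for (a in cu[[1]]) for (b in cu[[2]]) for (d in cv[[1]]) for (e in cv[[2]]) {
      q <- c(a, b, d, e)
      for (gt in gene_trees) {
        if (!all(q %in% gt$tip.label)) next
        mate <- oracle_quartet_pairing(gt, q)
        if (is.null(mate)) next
        cls <- if (b %in% mate) "main" else if (d %in% mate) "alt1" else "alt2"
        counts[cls] <- counts[cls] + 1
      }
    }
    tot <- sum(counts)
    res[[branch]] <- if (tot == 0) c(NA, NA, NA) else counts / tot
  }
  res
}
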