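test_that("gene filtering applies inclusive length and taxon-coverage bounds", {
  cfg <- design_config()
  g_short <- dna_alignment(setNames(
    c(strrep("A", 499), rep(strrep("C", 499), 4)), paste0("t", 1:5)
  ))
  g_edge <- dna_alignment(setNames(rep(strrep("A", 500), 3), paste0("t", 1:3)))
  cands <- gene_candidates(c("short", "edge"), list(g_short, g_edge))
  kept <- filter_candidate_genes(cands, cfg)
  expect_equal(kept$gene_id, "edge") # 499 bp rejected, 500 bp / 3 taxa kept
})

test_that("gene filtering matches a per-gene hand check on simulated genes", {
  set.seed(7)
  cfg <- design_config()
  genes <- lapply(1:10, function(i) {
    n <- sample(2:6, 1)
    len <- sample(450:600, 1)
    dna_alignment(setNames(
      replicate(n, paste0(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")),
      paste0("t", 1:n)
    ))
  })
  cands <- gene_candidates(sprintf("g%02d", 1:10), genes)
  kept <- filter_candidate_genes(cands, cfg)
  manual <- vapply(genes, function(a) {
    min(nchar(gsub("-", "", unclass(a)))) >= 500 && length(a) >= 3
  }, logical(1))
  expect_equal(kept$gene_id, sprintf("g%02d", 1:10)[manual])
  # monotonicity: tightening a threshold never adds survivors
  tighter <- filter_candidate_genes(cands, design_config(min_gene_len = 550))
  expect_true(all(tighter$gene_id %in% kept$gene_id))
})

test_that("merging across references unions gene ids and records provenance", {
  a <- dna_alignment(c(t1 = "ACGT", t2 = "ACGT"))
  b <- dna_alignment(c(t1 = "ACGT", t2 = "ACGT", t3 = "ACGT"))
  merged <- merge_across_references(list(
    R1 = gene_candidates(c("g1", "g2"), list(a, a)),
    R2 = gene_candidates(c("g2", "g3"), list(b, a))
  ))
  expect_setequal(merged$gene_id, c("g1", "g2", "g3"))
  expect_equal(merged$reference_source[[match("g2", merged$gene_id)]],
               c("R1", "R2"))
  # representative for g2 is R2's alignment (more taxa)
  expect_equal(length(merged$alignment[[match("g2", merged$gene_id)]]), 3L)

  # disjoint inputs: sizes add, all single-sourced
  dis <- merge_across_references(list(
    R1 = gene_candidates(paste0("a", 1:3), replicate(3, a, simplify = FALSE)),
    R2 = gene_candidates(paste0("b", 1:4), replicate(4, a, simplify = FALSE))
  ))
  expect_equal(nrow(dis), 7L)
  expect_true(all(lengths(dis$reference_source) == 1))
})

test_that("union size over three references matches inclusion-exclusion", {
  a <- dna_alignment(c(t1 = "ACGT", t2 = "ACGT"))
  ids <- list(
    R1 = c("g1", "g2", "g3", "g4"),
    R2 = c("g3", "g4", "g5"),
    R3 = c("g1", "g4", "g6", "g7")
  )
  sets <- lapply(ids, function(v) {
    gene_candidates(v, replicate(length(v), a, simplify = FALSE))
  })
  merged <- merge_across_references(sets)
  expect_equal(nrow(merged), length(Reduce(union, ids)))
})

test_that("exon splitting maps ungapped coordinates through the gap pattern", {
  cfg_coords <- tibble::tibble(gene_id = "g", exon_index = 1L,
                               start = 0L, end = 2L)
  # gapless reference: plain column slice
  a <- dna_alignment(c(ref = "ACGT", o1 = "AGGT"))
  ex <- split_into_exons(a, cfg_coords, "ref", gene_id = "g")
  expect_equal(unclass(ex$alignment[[1]])[["ref"]], "AC")

  # gapped reference: internal gap column included
  b <- dna_alignment(c(ref = "A-CGT", o1 = "AGCGT"))
  ex2 <- split_into_exons(b, cfg_coords, "ref", gene_id = "g")
  expect_equal(unclass(ex2$alignment[[1]])[["ref"]], "A-C")
  expect_equal(unclass(ex2$alignment[[1]])[["o1"]], "AGC")

  # coordinates beyond the ungapped length error
  bad <- tibble::tibble(gene_id = "g", exon_index = 1L, start = 0L, end = 5L)
  expect_error(split_into_exons(a, bad, "ref", gene_id = "g"),
               class = "exonbaits_coordinate_error")

  # all-gap sequences are dropped per exon
  c3 <- dna_alignment(c(ref = "ACGT", o1 = "--GT"))
  ex3 <- split_into_exons(c3, cfg_coords, "ref", gene_id = "g")
  expect_equal(names(ex3$alignment[[1]]), "ref")
})

test_that("exon slices concatenate to the reference subsequence in order", {
  set.seed(11)
  sim <- simulate_ortholog_alignments(n_genes = 3, exons_per_gene = c(2, 4),
                                      exon_len = c(50, 120), seed = 11)
  for (gid in names(sim$alignments)) {
    exons <- split_into_exons(sim$alignments[[gid]], sim$coords,
                              sim$reference_taxon, gene_id = gid)
    ref_parts <- vapply(exons$alignment, function(a) {
      gsub("-", "", unclass(a)[[sim$reference_taxon]])
    }, character(1))
    full_ref <- gsub("-", "", unclass(sim$alignments[[gid]])[[sim$reference_taxon]])
    expect_equal(paste0(ref_parts, collapse = ""), full_ref)
  }
})

test_that("mean pairwise identity matches textbook cases and is order-invariant", {
  expect_equal(mean_pairwise_identity(aln(a = "ACGT", b = "ACGT")), 100)
  expect_equal(mean_pairwise_identity(aln(a = "ACGT", b = "ACGA")), 75)
  expect_error(mean_pairwise_identity(aln(a = "ACGT")),
               class = "exonbaits_arity_error")
  expect_error(
    mean_pairwise_identity(aln(a = "AC--", b = "--GT")),
    class = "exonbaits_undefined_identity_error"
  )

  set.seed(3)
  a <- random_aln(5, 40, missing_prob = 0.1)
  shuffled <- a[sample(length(a))]
  expect_equal(mean_pairwise_identity(shuffled), mean_pairwise_identity(a))
  # appending a shared all-gap column changes nothing
  gapped <- dna_alignment(setNames(paste0(unclass(a), "-"), names(a)),
                          multicopy = TRUE)
  expect_equal(mean_pairwise_identity(gapped), mean_pairwise_identity(a))
})

test_that("exon filtering uses inclusive bounds and is idempotent and monotone", {
  cfg <- design_config()
  mk <- function(len, div) {
    # two sequences differing in a prefix, identity = 100 * (1 - div/len)
    s1 <- strrep("A", len)
    s2 <- paste0(strrep("C", div), strrep("A", len - div))
    tibble::tibble(gene_id = "g", exon_index = 1L,
                   alignment = list(aln(a = s1, b = s2)))
  }
  at_lo <- annotate_exons(mk(500, 125)) # identity exactly 75.0
  expect_equal(at_lo$mean_pairwise_identity, 75)
  expect_equal(nrow(filter_exons(at_lo, cfg)), 1L)

  identical_seqs <- annotate_exons(mk(500, 0)) # 100% exceeds the 98 cap
  expect_equal(nrow(filter_exons(identical_seqs, cfg)), 0L)

  short <- annotate_exons(mk(499, 60))
  expect_equal(nrow(filter_exons(short, cfg)), 0L)

  batch <- dplyr::bind_rows(mk(500, 125), mk(520, 10), mk(600, 60), mk(450, 60))
  batch <- annotate_exons(batch)
  kept <- filter_exons(batch, cfg)
  manual <- with(batch, aln_length >= 500 &
                   mean_pairwise_identity >= 75 & mean_pairwise_identity <= 98)
  expect_equal(nrow(kept), sum(manual))
  expect_equal(filter_exons(kept, cfg), kept) # idempotent
  tight <- filter_exons(batch, design_config(identity_hi = 90))
  expect_true(all(tight$mean_pairwise_identity %in% kept$mean_pairwise_identity))
})

test_that("final exon selection ranks by cross-reference sharing", {
  mk_exon <- function(gid, idx) {
    tibble::tibble(gene_id = gid, exon_index = as.integer(idx),
                   alignment = list(aln(a = "ACGT", b = "ACGA")))
  }
  per_ref <- list(
    R1 = dplyr::bind_rows(mk_exon("g1", 1), mk_exon("g2", 1), mk_exon("g3", 2)),
    R2 = dplyr::bind_rows(mk_exon("g1", 1), mk_exon("g3", 2)),
    R3 = dplyr::bind_rows(mk_exon("g1", 1), mk_exon("g9", 1))
  )
  sel <- select_final_exons(per_ref)
  expect_equal(sel$n_refs, c(3L, 2L, 1L, 1L))
  expect_equal(sel$gene_id[1], "g1")
  # no duplicate keys
  expect_equal(anyDuplicated(paste(sel$gene_id, sel$exon_index)), 0L)
  # order equals an independently sorted list
  manual <- sel[order(-sel$n_refs, sel$gene_id, sel$exon_index), ]
  expect_equal(sel, manual)
  # empty input -> empty output
  expect_equal(nrow(select_final_exons(list(R1 = mk_exon("g", 1)[0, ]))), 0L)
  # top-n cut
  expect_equal(nrow(select_final_exons(per_ref, top_n = 2)), 2L)
})

test_that("edge trimming removes low-occupancy flanks only", {
  a <- dna_alignment(c(
    t1 = "--ACGT--",
    t2 = "--ACGA-N",
    t3 = "NNACGTA-",
    t4 = "--ACGTAC"
  ))
  trimmed <- trim_alignment_edges(a, 0.5)
  expect_equal(alignment_length(trimmed), 5L) # cols 3..7 survive
  expect_equal(unclass(trimmed)[["t1"]], "ACGT-")
})
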