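test_that("representative selection keeps one ingroup and one outgroup sequence", {
  a <- aln(Ast1 = "ACGTACGT", Ast2 = "ACGTACG-", Oxy1 = "ACCTACGT")
  reps <- select_representatives(a, ingroup_taxa = c("Ast1", "Ast2"))
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$taxon[reps$role == "ingroup"], "Ast1") # fewest missing
  expect_equal(reps$taxon[reps$role == "outgroup"], "Oxy1")

  # one-sided exon: single representative plus warning
  only_in <- aln(Ast1 = "ACGT", Ast2 = "ACGA")
  expect_warning(reps1 <- select_representatives(only_in, c("Ast1", "Ast2")),
                 "only one side")
  expect_equal(nrow(reps1), 1L)
})

test_that("representative ties break by ungapped length then taxon name", {
  # equal missing counts; Bst is longer ungapped; Ast/Zst tie -> alphabetical
  a <- aln(Ast = "ACG-", Bst = "ACNT", Zst = "ACG-", Out = "ACGT")
  reps <- select_representatives(a, ingroup_taxa = c("Ast", "Bst", "Zst"))
  expect_equal(reps$taxon[reps$role == "ingroup"], "Bst")
  b <- aln(Zst = "ACG-", Ast = "ACG-", Out = "ACGT")
  reps2 <- select_representatives(b, ingroup_taxa = c("Ast", "Zst"))
  expect_equal(reps2$taxon[reps2$role == "ingroup"], "Ast")
})

test_that("bait tiling enumerates the documented start positions", {
  cfg <- design_config()
  seq80 <- strrep("AC", 40)
  expect_equal(tile_baits(seq80, config = cfg)$start, 0L) # single window
  seq120 <- strrep("AC", 60)
  expect_equal(tile_baits(seq120, config = cfg)$start, c(0L, 40L))
  seq100 <- strrep("AC", 50)
  expect_equal(tile_baits(seq100, config = cfg)$start, c(0L, 20L)) # terminal anchor
  expect_warning(none <- tile_baits(strrep("A", 79), config = cfg), "shorter")
  expect_equal(nrow(none), 0L)
  expect_error(tile_baits(seq80, config = design_config(tiling_density = 200)),
               class = "exonbaits_config_error")
  # every bait has the configured length and maps back to its source
  baits <- tile_baits(paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
                      config = cfg)
  expect_true(all(nchar(baits$sequence) == 80))
})

test_that("tiling covers every base, twice away from the ends at 2x density", {
  cfg <- design_config()
  for (L in c(80, 95, 120, 161, 200, 317)) {
    s <- strrep("A", L)
    baits <- tile_baits(s, config = cfg)
    cover <- integer(L)
    for (i in seq_len(nrow(baits))) {
      idx <- (baits$start[i] + 1):(baits$start[i] + 80)
      cover[idx] <- cover[idx] + 1
    }
    expect_true(all(cover >= 1))
    interior <- setdiff(seq_len(L), c(1:40, (L - 39):L))
    if (length(interior) > 0) expect_true(all(cover[interior] >= 2))
  }
})

test_that("bait QC rejects on GC and ambiguity and collapses duplicates", {
  cfg <- design_config()
  polyA <- tile_baits(strrep("A", 80), "l1", config = cfg)
  qc <- qc_baits(polyA)
  expect_equal(nrow(qc$kept), 0L)
  expect_equal(qc$rejected$reason, "gc_out_of_range")

  balanced <- tile_baits(strrep("ACGT", 20), "l1", config = cfg)
  dup <- dplyr::bind_rows(balanced, dplyr::mutate(balanced, locus_id = "l2"))
  qc2 <- qc_baits(dup)
  expect_equal(nrow(qc2$kept), 1L)
  expect_equal(qc2$rejected$reason, "duplicate_sequence")

  # batch with known GC values matches a per-bait hand check
  set.seed(5)
  seqs <- replicate(30, paste0(sample(c("A", "C", "G", "T"), 80, TRUE),
                               collapse = ""))
  baits <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    tile_baits(seqs[i], paste0("l", i), config = cfg)
  }))
  qc3 <- qc_baits(baits)
  gc <- vapply(strsplit(seqs, ""), function(ch) mean(ch %in% c("G", "C")),
               numeric(1))
  expect_equal(sort(qc3$kept$locus_id),
               sort(paste0("l", which(gc >= 0.25 & gc <= 0.75 &
                                        !duplicated(seqs)))))
  # permissive bounds are the identity up to deduplication
  qc4 <- qc_baits(baits, gc_min = 0, gc_max = 1, max_n = 1)
  expect_equal(nrow(qc4$kept), sum(!duplicated(baits$sequence)))
})

test_that("ambiguity fractions weight degenerate codes at half by default", {
  b <- tile_baits(paste0(strrep("AC", 38), "NRWY"), "l", config = design_config())
  expect_equal(b$n_fraction[1], (1 + 0.5 * 3) / 80)
  b2 <- tile_baits(paste0(strrep("AC", 38), "NRWY"), "l",
                   config = design_config(), strict_ambiguity = TRUE)
  expect_equal(b2$n_fraction[1], 4 / 80)
})

test_that("capture-space statistics summarize per-locus lengths", {
  ts <- tibble::tibble(
    locus_id = c("l1", "l2"),
    taxon = c("A", "A"),
    sequence = c(strrep("A", 500), strrep("C", 1500))
  )
  st <- capture_space_stats(ts)
  expect_equal(st$capture_space_bp, 2000)
  expect_equal(st$mean_locus_len, 1000.00)
  expect_equal(st$min_locus_len, 500)
  expect_equal(st$max_locus_len, 1500)

  single <- capture_space_stats(ts[1, ])
  expect_equal(single$mean_locus_len, single$min_locus_len)
  expect_equal(single$mean_locus_len, single$max_locus_len)

  expect_error(capture_space_stats(ts[0, ]), class = "exonbaits_empty_input_error")

  # 50 simulated loci: stats equal an independent recomputation
  set.seed(9)
  lens <- sample(400:3800, 50)
  ts2 <- tibble::tibble(locus_id = sprintf("L%02d", 1:50), taxon = "A",
                        sequence = vapply(lens, strrep, character(1), x = "G"))
  st2 <- capture_space_stats(ts2)
  expect_equal(st2$capture_space_bp, sum(lens))
  expect_equal(st2$mean_locus_len, round(mean(lens), 2))
  expect_equal(c(st2$min_locus_len, st2$max_locus_len), range(lens))
})

test_that("a built target set tiles deterministically end to end", {
  sim <- simulate_ortholog_alignments(n_genes = 4, exons_per_gene = c(1, 2),
                                      exon_len = c(90, 200), seed = 21)
  panel <- list()
  for (gid in names(sim$alignments)) {
    panel[[gid]] <- split_into_exons(sim$alignments[[gid]], sim$coords,
                                     sim$reference_taxon, gene_id = gid)
  }
  exons <- annotate_exons(dplyr::bind_rows(panel))
  sel <- select_final_exons(list(ref = exons))
  ts <- build_target_set(sel, sim$ingroup_taxa)
  expect_true(all(ts$role %in% c("ingroup", "outgroup")))
  expect_true(all(table(ts$locus_id) <= 2))
  baits1 <- tile_target_set(ts)
  baits2 <- tile_target_set(ts)
  expect_identical(baits1, baits2) # byte-identical on fixed input
  expect_true(all(nchar(baits1$sequence) == 80))
})
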