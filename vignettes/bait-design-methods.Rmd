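---
title: "Designing and evaluating a clade-specific exon bait set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a clade-specific exon bait set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonbaits)
library(dplyr)
```

## The problem

Target enrichment (hybrid capture) concentrates sequencing effort on a few
hundred putative single-copy nuclear loci, which makes it the method of
choice for phylogenomics from degraded herbarium DNA. Designing a
clade-specific bait set from transcriptome-derived ortholog alignments
involves a cascade of filters — gene length, taxon coverage, per-exon
length and divergence — followed by probe tiling; evaluating a capture
experiment involves per-sample recovery statistics, alignment
informativeness, and concordance between gene trees and the species tree.
`exonbaits` implements that whole workflow as composable, tibble-first
functions, together with seeded simulators for every input class so the
pipeline is testable without any sequencing data.

## The filtering cascade

Candidate genes are multi-species alignments keyed by a cross-reference
ortholog name (an *Arabidopsis* gene id when legume references are used).
`filter_candidate_genes()` keeps genes whose **shortest ungapped sequence**
is at least `min_gene_len` (default 500 bp) and that cover at least
`min_taxa` (default 3) distinct taxa. Both bounds are inclusive — the
thresholds are phrased as minima, so a 500-bp gene with exactly three taxa
survives.

Because assembling multi-exon genes across divergent taxa risks chimeric
sequences from paralogous copies, each exon is treated as its own
evolutionary unit from here on: `split_into_exons()` slices the gene
alignment at exon boundaries given on the ungapped reference sequence
(0-based, half-open), mapping the interval through the reference's gap
pattern, and exons are never re-stitched downstream.

Exon alignments then pass `filter_exons()`: alignment length at least
`min_exon_len` (500 bp) and mean pairwise identity within
`[identity_lo, identity_hi]` = [75, 98] per cent, both ends inclusive. The
lower bound discards alignments too divergent for reliable hybridization
(bait-target similarity governs capture efficiency); the upper bound
discards near-invariant exons that would carry little phylogenetic signal.

Two readings of that identity criterion were possible; the package uses the
**mean over all unordered sequence pairs**, where each pair's identity is
computed over the columns in which both members carry an unambiguous
residue (gaps, `N` and `?` are excluded from that pair's denominator, and
pairs with no comparable column are excluded from the mean). This matches
common alignment-viewer semantics and is stable under missing data, unlike
a min/max reading. Similarly, "length" for the exon filter is read as
alignment length (columns); a flag (`use_ungapped_length`) switches to the
shortest ungapped sequence for sensitivity analysis.

Where the exon panel is assembled against several reference genomes,
`select_final_exons()` ranks exons by how many references they survived
(descending), then by gene id and exon index. Cross-reference identity is
decided by the `(gene_id, exon_index)` key — the merge is by ortholog
name, as sequence-level equality across independently assembled references
is too strict in practice; a `strict_sequence` mode requiring byte-identical
alignments is available. Manual inspection of alignment ends is replaced by
an optional automated trim (`trim_alignment_edges()`, off by default) that
removes terminal columns with under 50% occupancy.

## Probe tiling

`select_representatives()` reduces each exon to at most two sequences —
one ingroup, one outgroup — choosing per side the sequence with the fewest
missing characters (ties: longest ungapped, then alphabetical taxon), so a
fixed input always yields a byte-identical bait file. `tile_baits()` lays
down `bait_len` = 80-nt windows every `round(bait_len / tiling_density)`
bases; 2x density gives a 40-bp step, the standard vendor meaning of
"tiling density". When the sequence length is not commensurate with the
step, one extra bait is anchored at the 3' end so no exon tail is left
uncovered — this maximizes coverage of the declared capture space at the
cost of a locally higher overlap. Sequences shorter than one bait yield no
baits (with a warning) rather than padded probes.

`qc_baits()` applies the generic manufacturability screens a vendor would:
GC fraction within [0.25, 0.75], no ambiguous bases (`max_n = 0`), and
exact-duplicate collapse. Degenerate IUPAC codes other than `N` are kept
verbatim in the bait sequence but count toward the ambiguity fraction at
half weight by default (full weight in strict mode) — they hybridize
partially, so neither ignoring them nor treating them as hard failures is
right. Vendors apply additional undisclosed filters, so a manufactured kit
is generally smaller than the naive tiling count; the package makes no
attempt to reproduce proprietary QC.

## Capture evaluation

`build_sample_stats()` turns a long-format recovery table (one row per
sample x locus, as produced by capture-assembly pipelines) into the
standard per-sample summary: reads, on-target percentage, locus counts at
the recovery thresholds, paralog-warning counts, total bases. The
`recovery_thresholds` (0.50, 0.75 of the mean target length) use a strict
`>` comparison, matching the ">50%"/">75%" phrasing of published summary
tables; an `inclusive` flag flips to `>=`. Paralog flags are consumed as
input, not recomputed — assembly-level paralog detection belongs to the
assembler. Per-locus "mean target length" is the mean over the reference
sequences for that locus in the target file.

`summarize_stats()` reports per-column means to 1 decimal, rounded half
away from zero (commercial rounding, as in published tables; base R rounds
half to even), exact sums, and min/max with the attaining samples. The
summary on-target percentage is the pooled ratio `sum(mapped)/sum(reads)`,
not the mean of per-sample percentages — the two differ and published
tables use the pooled form. The package ships the full 23-sample
Astragalean capture summary as a plain-text fixture
(`astragalean_capture_stats()`); `summarize_stats()` reproduces every
average, sum and range of that experiment, which the acceptance script
recomputes at run time. Note the table's own data place the maximum
75%-threshold count (805) on *A. sungpanensis*; the package reports the
arg-max from the data and does not arbitrate conflicting prose.

`linear_r2()` is ordinary least squares with `R^2` reported to 3 decimals;
a constant response returns 0 by convention (there is no variance to
explain) and a constant predictor errors. `fit_recovery_trend()` wraps the
same fit as an object with `tidy()`/`glance()` methods.

## Alignment statistics

`trim_by_occupancy()` removes columns where fewer than `min_col_occupancy`
(default 0.1) of sequences carry an unambiguous residue. Throughout the
package `-` is a gap and `N`/`?` are missing, and all three count as
non-unambiguous — for occupancy, for identity denominators, and for tip
masking. `alignment_informativeness()` uses the textbook definitions: a
column is variable with at least two distinct unambiguous states, and
parsimony-informative with at least two states each in at least two
sequences; gaps and ambiguity codes never act as character states (the
behavior of standard alignment summarizers). "Missing data" counts both
gaps and ambiguous cells, since published percentages rarely distinguish
them; this is documented rather than configurable.

## Tree tools

`mask_monophyletic_tips()` prunes duplicate same-taxon leaves
(`taxon@copy` labels) when they form a monophyletic clade or a
paraphyletic grade, keeping the leaf with the most unambiguous characters
in the trimmed alignment (ties: lexicographically smallest label). The
implementation iterates two local rules to a fixed point — same-taxon
sibling tips, and a tip whose parent's sibling is a same-taxon tip — which
collapses both clades and ladders; degree-2 nodes are suppressed after
each prune. Singleton taxa are never touched.

`quartet_frequencies()` computes, for every internal branch of the
(unrooted) species tree, the fraction of gene-tree quartets agreeing with
the species-tree topology versus its two alternatives — the quantities
shown as pie charts on coalescent species trees. Around each branch the
four taxon clusters are formed; each quartet drawn one-per-cluster is
classified in each gene tree containing all four taxa by scanning the gene
tree's splits for one separating the quartet two-against-two. Which
discordant topology is "first" versus "second" is not standardized
anywhere, so the package fixes an arbitrary but documented convention:
clusters are ordered within each side of the branch by smallest leaf
label, and alternative 1 pairs cluster 1 with cluster 3. Local posterior
probabilities are deliberately out of scope — they belong to coalescent
species-tree tools; only quartet frequencies are computed here. Branches
adjacent to multifurcations, and branches where no gene tree resolves any
quartet, are reported with zero counts rather than dropped. Exhaustive
enumeration is the default; `max_quartets_per_branch` switches to seeded
uniform subsampling, which agrees with exhaustive mode within binomial
error.

## The simulators

The generators exist so that every module can be exercised, and every
truth recovered, without downloads:

* `simulate_ortholog_alignments()` evolves each gene along a random
  labelled topology by per-site substitution (default 8 taxa, 5 ingroup,
  substitution probability 0.02 per edge — which lands exon identities in
  the high-80s/low-90s per cent, the band a clade-specific design targets).
  Exon boundaries (1–3 exons of 400–1000 bp by default) are recorded on
  the gapless first taxon. There are no indels beyond optional terminal
  missingness: indel realism is irrelevant to the filters under test, and
  the truth table (length, coverage, realized identity per exon) stays
  exactly computable.
* `simulate_recovery_table()` draws per-locus recovered lengths as
  fractions of target with a per-sample mean (base 0.75–0.95), optional
  linear specimen-age effect, dropout, and Bernoulli paralog flags. Read
  counts (2.8–14 million) and on-target fractions (13–39%) are drawn from
  the ranges observed in the packaged capture experiment so simulated and
  fixture regimes are comparable.
* `simulate_gene_trees()` emits the species tree or a one-NNI
  rearrangement with a given probability, optionally pinned to one branch,
  with optional duplicate-tip injection for masking tests.

What passing tests on these simulators does **not** show: robustness to
alignment error, indels, chimeric assemblies, or realistic coalescent
branch lengths. The simulators validate the arithmetic and the contracts,
not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* All reported means/percentages round half away from zero (1 decimal for
  table statistics, 2 for locus lengths); `R^2` uses 3 decimals.
* Interval arithmetic is 0-based half-open internally; GFF3 1-based
  inclusive coordinates convert at the I/O boundary (and back, an exact
  involution).
* Ragged FASTA errors immediately; empty alignments, empty target sets and
  sub-bait-length sequences raise typed errors or warnings rather than
  returning silently empty results.
* The tiling step rounds half away from zero and a step of zero is a
  configuration error.
* An alignment whose pairs share no comparable columns has undefined
  identity and errors rather than returning an arbitrary number.

## Problem sizes used in the test-suite and acceptance runs

The packaged checks run the pipeline at deliberately small scales — up to
40 genes x 8 taxa for design, 200 samples x 800 loci for parameter
recovery, 6–10-taxon trees with up to 50 gene trees for quartet work —
sizes at which the brute-force oracles (pair enumeration, per-column
classification, exhaustive window and quartet enumeration) remain exact
and fast. The implementation itself has no such limits; the same calls
scale to panel sizes in the hundreds of loci used in real designs.

## Known limitations

* Ortholog inference, alignment, read processing, assembly and
  species-tree estimation are out of scope; the package starts from
  alignments, recovery tables and trees.
* Manufacturer-specific probe QC is not reproducible; `qc_baits()` covers
  only the generic screens above.
* Sequence-overlap search is exact-substring (either strand), not
  approximate homology search.
* Quartet concordance requires single-copy gene trees; mask first
  (`mask_monophyletic_tips()`), multi-copy quartet scoring is not
  implemented.
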