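---
title: "Methods: screening for independently eroded conserved TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for independently eroded conserved TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

When a complex trait is lost independently in two clades of a phylogeny,
every regulatory element dedicated to that trait switches to neutral
evolution in both clades, while remaining under purifying selection in
species that keep the trait. Given enough time, the trait-dedicated
transcription factor binding sites erode detectably in both target
lineages but stay intact in their sister ("outgroup") species and across
the rest of the phylogeny. `erosionscan` implements the full screen built
on this signature: predict deeply conserved binding sites from a
reference-anchored multiple alignment, call sites eroded per target
lineage against its outgroups, intersect the lineages, and ask whether
the most significant independently eroded sites congregate near genes of
a shared function.

## Conserved-site prediction

**Conservation windows.** Every reference base receives a weighted
percent identity (PID): the branch length of the minimal subtree
connecting the reference and all species whose aligned base matches it
(case-insensitively; gaps and `N` count as non-matching), divided by the
total branch length of the tree, so PID is in [0, 1]. The profile is
smoothed with a 100-bp centred mean (truncated, not mirrored, at block
edges — the simplest unbiased choice) and discretised into 1% bins. The
paper-gap here is the exact meaning of "branch length over which a base
is conserved"; we operationalise it as the induced (Steiner) subtree of
the reference plus matching leaves, which is what makes the
total-branch-length normalisation yield a number in [0, 1].

**Motif matching.** Motifs are position frequency matrices
(pseudocount 0.001 per cell, configurable, so no frequency is ever
zero). A window is scored with the information-weighted MATCH similarity
`S = sum_i I(i) f(i, b_i)` with `I(i) = sum_b f log2(4 f)`, min-max
normalised so the consensus scores 1 and the anti-consensus 0; windows
at or above 0.8 are matches, on either strand. `N` in a window means no
match. The MATCH definition is adopted with log base 2; the base choice
cancels in the normalised score. The core-similarity pre-filter of the
original MATCH tool is not used — the screen operates with a single 0.8
full-matrix cutoff.

**Branch-length (BBL) score.** Each reference-matching window's
conservation statistic is the induced-subtree branch length of the
species whose aligned, gapless sequence at those columns also scores at
least 0.8 (the reference itself counts toward the species tally). This
deterministic branch-length surrogate is monotone in the same quantity
as Bayesian branch-length scoring; the full Bayesian weighting is not
restated in the source literature, so we record this as a deliberate
simplification.

**Shuffled-motif null and empirical p.** For each motif we build null
motifs by shuffling columns, keeping annotated CpG column pairs glued in
C→G order (CpG pairs are auto-annotated from consensus letters and can
be overridden). One guard matters in practice: a shuffle of a motif with
repeated consensus letters can reproduce the motif itself, and such a
"null" would rediscover every real instance; shuffles whose MATCH score
against the real consensus reaches the detection threshold are therefore
redrawn (`null_shuffle()`). Null BBL scores are recorded per 1%
conservation bin of each matching window's central base, pooled across
10 shuffles per motif (configurable). The empirical p-value of a real
prediction is `(#{null >= score} + 1) / (N + 1)` over its bin. Because
the retention gate is p <= 1e-3, a bin must hold at least 999 null
observations to be decidable; sparse bins borrow symmetrically from
their nearest populated neighbours until at least `min_null`
observations (default 3000) are pooled. The default is deliberately
above the 999 floor: with ~1000 pooled scores a single stray
high-conservation null observation forces p to 2/1001 and silently
vetoes an entire bin, whereas pooling 3000 tolerates a couple of such
observations while still resolving the 1e-3 gate.

**Retention gates.** A prediction is kept iff empirical p <= 1e-3, it
is preserved in at least 5 species, and those species span at least 3.0
substitutions/site. Prediction is restricted to the allowed space — the
complement of the exon and repeat masks; overlapping same-motif hits on
both strands are both kept at this stage (deduplication happens after
the independent intersection).

## Erosion calling

A conserved site is *eroded* in a target species when the target is
absent from the matching-species set while at least one declared
outgroup is present (evidence the ancestor had the site). Calls whose
target sequence overlaps an assembly gap — an `N` run in the target row
or an interval of a supplied gap BED — are discarded rather than
mistaken for loss. "Absent in target" deliberately covers both motif
mismatch and missing alignment; the mechanism is classified post hoc:
*mismatch* when any target base aligns over the site's columns,
*deletion* when none does. Sites eroded in every target lineage (two or
three are supported) form the independent set; they are ranked by
empirical p (ties broken by higher BBL, then coordinate), the top 5000
are kept *plus all ties at the cutoff p* to avoid arbitrary
tie-breaking, and overlapping entries are removed greedily
best-first — the cluster-resolution order is not dictated by the source
method, and greedy highest-significance-first is the canonical choice.

## Enrichment

Regulatory domains follow the basal-plus-extension rule: a strand-aware
basal domain 5 kb upstream / 1 kb downstream of the TSS, extended up to
1 Mb in each direction but stopping at the nearest neighbouring basal
domain and never shrinking below its own basal. A region hits a gene
when its midpoint lies in the gene's extended domain — the midpoint
convention makes hits unambiguous and matches the fraction-of-genome
success probability of the region test. Per ontology term (tested when
its gene set intersected with the universe of genes has 10–500
members): a binomial region test against the term's annotated genome
fraction, and a hypergeometric gene test over the gene universe (the
gene-based test variant is not restated in the source; hypergeometric
is the standard choice). Benjamini–Hochberg correction runs across
exactly the tested terms. A term is reported when region fold >= 2 and
both FDRs are <= 0.05; survivors are sorted by region FDR.

The permutation overlap test places the top regions
(lengths preserved, mutually non-overlapping, each inside a single
allowed interval) uniformly in the allowed space, 10,000 times by
default, by rejection sampling with a bounded retry budget; the
statistic is the number of regions overlapping any feature, and
`p = (b + 1) / (m + 1)`, which can never be exactly zero — with 10,000
permutations the floor is 9.99e-5.

## The synthetic world

`generate_world()` builds, deterministically from one seed, a miniature
world exercising every code path: 10 species on a fixed tree (total
branch length 8.2 substitutions/site) with two independent target
clades, each target paired with one outgroup; a 480 kb single-chromosome
genome tiled by 10 kb alignment blocks; 80 genes every ~6 kb with
300 bp exons and 30 repeat intervals; a 25-term ontology whose 12-gene
trait term attracts 80% of the independently eroded sites; 3 motifs of
width 9 (seven 0.85-sharp columns, two soft columns); and 190 planted
consensus instances — 60 conserved everywhere, 25 eroded in each single
target, 80 independently eroded with a (0.6, 0.3, 0.1) mixture of
both-mismatch, mixed and both-deletion mechanisms. Background sequence
evolves by i.i.d. Jukes–Cantor substitutions per branch with no
background indels — the simplest model that still exercises every
stage. Planted mismatches are substitutions at informative columns,
re-verified to score below 0.8; deletions blank the whole target row.

Several world-design choices deserve a word:

* **Scale.** The sizes above keep a full screen around 15–20 s on one
  CPU while leaving >10,000 null observations per motif, enough to
  resolve the 1e-3 empirical-p gate with room to spare.
* **Motif library realism.** Consensus sequences are drawn with at
  least 3 distinct bases, no base more than 4 times, and pairwise
  letter-multiset distance of at least 3 on both strands. Curated motif
  libraries are non-redundant and exclude low-complexity patterns; with
  repetitive or mutually similar consensi, a shuffle of one motif can
  match another motif's instances, which confounds the per-motif null.
* **Gene spacing.** Trait-directed sites are planted within ~800 bp of
  their gene's TSS while genes sit ~6 kb apart, so a site's midpoint
  falls in the basal domain of its own gene only; this keeps the
  gene-level hypergeometric test interpretable in a small universe.
* **What the world does not emulate.** Rate heterogeneity,
  context-dependent mutation, background indels, alignment error, motif
  turnover and dimer spacing variation. Passing tests demonstrate that
  the implementation recovers what it plants under its stated model —
  not that the screen is robust to real-data artefacts.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open in every table (BED convention);
conversions to the 1-based representation used by interval algebra
happen only inside helpers. Minus-strand reference MAF blocks are
normalised to the forward strand on input. Ties in ranking are broken
by higher BBL, then leftmost coordinate. A degenerate motif column set
with equal min and max score yields MATCH 0. Empty null bins are an
error at the lookup level; the screen instead borrows from neighbouring
bins as described. The permutation test refuses region sets longer than
the allowed space, and reports an error when non-overlapping placement
fails for 1000 consecutive rounds.

## Problem sizes used by the shipped validation

The bundled tests run the full screen on the default world (one seed),
check trait-term top-rank across 20 replicate worlds, verify the
mechanism mixture against its planted (0.6, 0.3, 0.1) composition, and
check binomial calibration of the region test over 50 seeds of 400
uniformly placed regions against the default world's domains. Oracle
tests enumerate all 4^w windows for widths up to 6, all binomial and
hypergeometric tails up to n, N = 12, and exhaustive greedy simulations
of overlap deduplication on random clusters of up to 20 sites.

## Limitations

The BBL score is a deterministic branch-length surrogate, not the full
Bayesian treatment; empirical p-values are bounded below by the null
count and are pooled across neighbouring conservation bins when sparse;
the synthetic world's erosion is planted at full strength rather than
accumulated along branches; and genome-scale quantities from real
58-mammal alignments (millions of sites, hundreds of thousands of
eroded calls) are far outside the desk-scale problem sizes used here.
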