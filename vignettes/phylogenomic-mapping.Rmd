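---
title: "Phylogenomic profile maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenomic profile maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomapr)
```

# The model

A phylogenetic profile describes a protein by *where its homologs are*:
a vector of best-homology-search bit scores across a panel of sequenced
genomes. Proteins that were inherited, lost and transferred together —
members of one functional module — tend to share a profile, so
clustering proteins by profile similarity recovers putative modules
without using sequence similarity between the proteins themselves.

`phylomapr` implements this as a pipeline of small, separately testable
stages:

1. **Profile construction** (`buildProfileMatrix`). From 12-column
   tabular all-vs-all search output, the best hit per (protein, genome)
   is kept (ties broken by lower e-value, then lexicographic subject
   id), cells are retained only when bit score > 50 **and** e-value <
   1e-5 (both inequalities strict, following the retention rule the
   profile method is defined with), and proteins qualifying in fewer
   than 5 genomes are dropped. Absent hits are stored as 0 bits, not
   `NA`, so rank correlations are well defined downstream. The query's
   own genome is excluded: a self-match would dominate every row while
   carrying no comparative signal.
2. **Profile similarity** (`spearmanMatrix`). Spearman rank correlation
   between profile rows, with average ranks for ties. The 0-cells make
   ties heavy, so the tie convention materially changes rho and must be
   pinned; average ranks is the standard definition. A constant row has
   undefined correlation and is recorded as 0 with a warning rather
   than propagating `NA`.
3. **Graph sparsification** (`topCorrelates`). Each protein keeps its
   50 most positively correlated partners (fewer if fewer exist;
   nothing with rho <= 0 is ever kept). The directed lists are
   symmetrized by union — an edge survives if either endpoint ranked it
   — which preserves mutual-neighbor structure; intersection
   symmetrization is available as an option. Whether the historical
   top-50 lists were directed or symmetric is not recorded anywhere we
   could verify, so both behaviors are exposed and union is the
   default. Correlations are computed on raw bit scores (not
   presence/absence), again with the alternative available by
   pre-binarizing the matrix.
4. **Embedding** (`embedMap`). A deterministic combination of
   multi-dimensional scaling and force-directed placement: classical
   MDS on graph shortest-path distances (edge length `1 - rho`)
   initializes coordinates; 200 Fruchterman–Reingold-style iterations
   refine them, with edge springs pulling neighbors toward distance
   `1 - rho` at stiffness rho, all-pairs repulsion, and a linearly
   cooling step cap. No random numbers are used, so a layout is
   reproducible bit-for-bit and structurally identical proteins (same
   neighbors, same correlations) stay at identical coordinates:
   coincident points exert no repulsion on each other. Disconnected
   components are laid out independently in disjoint bounding boxes.
   We also evaluated a pure attraction spring refinement
   (stress-majorization over edges); without repulsion it contracts the
   layout and merges adjacent clusters, which is why the refinement
   includes a repulsive term.
5. **Mountain detection** (`detectMountains`). A Gaussian kernel
   density surface on a 128×128 grid; every grid cell is assigned to
   the basin of the local maximum reached by steepest ascent over its
   8-neighborhood (processed in decreasing density order, which is
   equivalent to watershed-by-flooding); proteins inherit the basin of
   their nearest cell. Historically this step was done by eye on a 3-D
   terrain view; the package formalizes it with three exposed
   parameters so it is deterministic and testable:
   * `bandwidth` — default ties the kernel standard deviation to the
     mean distance to each point's `minMembers`-th nearest neighbor
     (in `MASS::kde2d`'s convention, `h` is four times the kernel sd).
     The usual normal-reference rule is a poor default here because the
     spread *between* mountains inflates it, over-smoothing the map;
     the nearest-neighbor scale tracks the within-cluster spacing — the
     smallest structure worth calling — in both crowded and sparse
     maps.
   * `prominence` (default 0.1) — a basin whose peak rises above its
     highest saddle by less than 10% of the peak density is a sampling
     ripple of a larger mountain, and is merged across that saddle.
     Without this, a single tight cluster can split into two basins
     purely through kernel-density noise.
   * `minMembers` (default 5) and `densityFloor` (default 0) — basins
     with too few proteins are merged into the nearest qualifying basin
     (or left unassigned with `mergeSmall = FALSE`), and peaks below
     the floor never open a basin.
   Mountains are renumbered by descending member count, so labels are
   stable under permutation of the input.

## Enrichment statistics

Each mountain is characterized two ways:

* **GO over-representation** (`goEnrichment`): for each term carried by
  a mountain gene, the upper-tail hypergeometric probability
  P(X ≥ k) with X ~ Hypergeom(N = background, K = term carriers,
  n = mountain size). Bonferroni over the number of tested terms is the
  default correction — the convention of the classical term-finder
  tools — with BH and no correction as options. Parent-term propagation
  is deliberately off: annotations are consumed as given, not rebuilt.
  The top three terms per mountain are attached as a summary attribute.
* **Niche/taxonomy enrichment** (`profileCategoryCounts`,
  `fisherCategoryTest`): each protein in a mountain contributes one
  count per genome with a positive profile cell, to that genome's
  category (host-associated or not; gamma-proteobacteria or other).
  Counts are pooled over proteins *without* deduplicating organisms —
  the contingency compares per-gene profiles, not a set union. The 2×2
  table (mountain vs background-minus-mountain × category vs not) gets
  a two-sided Fisher exact test: the sum of all hypergeometric table
  probabilities not exceeding the observed one (with the customary
  1e-7 relative guard against floating-point ties), plus an
  Over/Under direction label from the sample odds ratio. The genome
  background includes the mountain's own genes in its totals; the
  mountain is subtracted so the table rows are disjoint, with
  `subtractMountain = FALSE` exposing the overlapping-totals variant.
  Zero-margin tables return p = 1, a degenerate flag, and no direction.

## Orthology

`callOrthologs` filters cross-genome hits by minLrap ≥ 0.6 and percent
identity ≥ 30 (both inclusive, following the printed "≥"), then keeps
reciprocal best hits by bit score within each genome pair. minLrap is
alignment length over the *shorter* protein, capped at 1; the source
annotation platform's convention, since no definition is printed where
the thresholds are stated. Reciprocal best hit is the minimal standard
rule that yields a one-to-one pair table; the threshold filter alone
would not. `vennPartition` assigns each gene of an anchor genome to the
region named by its presence set (anchor + genomes with an ortholog
pair to it) — counts are per anchor genome, so a shared region is
reported once per anchor and the counts need not coincide when
orthology is not one-to-one. `classExtract` implements
require/exclude queries such as "present in all four mutualist genomes,
absent from both enteric outgroups".

## Whole-genome identity

* **ANIb** (`fragmentGenome`, `anib`): the query genome is cut into
  consecutive 1,020-bp fragments (short tail retained and flagged);
  ANI is the mean identity of fragments whose best alignment reaches
  30% identity over at least 70% of the fragment. The retention rule
  and averaging are owned here; alignment records can come from any
  search tool. For collinear pairs — such as the simulator's
  indel-free output — `alignFragmentsCollinear` provides an exact
  gap-free aligner so the whole loop closes without an external
  program.
* **TETRA** (`tetraZscores`, `tetraCorrelation`): tetramer counts over
  both strands (sequence and reverse complement counted separately, so
  no word spans a junction), expectations from the maximal-order Markov
  model E(w₁w₂w₃w₄) = N(w₁w₂w₃)·N(w₂w₃w₄)/N(w₂w₃), z = (O − E)/√E
  (Poisson approximation to the Markov variance, the standard
  practice), z = 0 where E = 0, and Pearson correlation over the 256
  z-scores. Ambiguous bases break words. Note the Markov expectation is
  *almost* but not exactly the observed count even for a homopolymer:
  with both-strand counts O = L−3 and E = (L−2)²/(L−1), so
  z = −1/((L−1)√E) — tiny, but not zero; the tests assert the exact
  closed form.
* **16S identity** (`pairwiseIdentityPct`): Needleman–Wunsch global
  alignment (match +1, mismatch −1, gap −2 per column by default) with
  identity = matches / alignment columns.
* **Genome statistics** (`readGenBank`, `genomeStats`): a minimal
  GenBank flat-file parser (LOCUS, FEATURES intervals, ORIGIN) feeding
  length, G+C percent over unambiguous bases, CDS counts, the
  interval-union coding fraction, and rRNA/tRNA counts.

# The synthetic-data generator

Every stage is validated against data with known ground truth, built by
the package itself:

* `simulateProfileMatrix` plants correlated modules: each module draws
  one characteristic genome set (each genome joins with probability
  0.5), members produce hits inside it with probability 1 and outside
  with 0.05 by default, and every cell's presence is flipped with
  `noiseFlipProb`. Bit scores for present cells are normal
  (mean 150, sd 30), truncated just above 50 bits so every simulated
  hit passes the profile filter; absent cells are 0, matching the
  matrix contract. The standard recovery condition used by the tests is
  5 modules × 30 proteins over 60 genomes at flip probability 0.05.
* `simulateGenomePair` point-mutates a common ancestor with independent
  per-site substitutions, uniform over the three alternative bases
  (Jukes–Cantor-like — the simplest model whose "fraction of identical
  sites" semantics match ANI). Indels default to 0 and are single-base
  when enabled, which keeps the divergence bookkeeping exact; the
  realized divergence is reported as substituted (surviving) sites over
  aligned sites.
* `simulateAnnotations` plants one enriched category: background genes
  carry each category at its background frequency (default 0.1 across
  5 categories — the scale of a broad functional term), enriched-set
  genes carry the enriched category at min(1, frequency × factor),
  clamped with a warning (or an error with `clamp = FALSE`);
  `enrichmentFactor = Inf` gives the certain-annotation degenerate
  case.
* `simulateHomologyHits` builds per-genome gene sets from shared
  families plus unique genes and emits reciprocal hit tables in which
  the true co-family pair always outscores any planted paralog.

What the generator does *not* emulate — realistic protein evolution,
substitution matrices, domain architecture, rearrangements, GC skew,
compositional heterogeneity along the chromosome — bounds what a green
test suite shows: the pipeline's logic and statistics are correct and
its planted structure is recovered, not that any particular biological
dataset will produce clean mountains.

## Power of the planted-enrichment check

Detection probability for a planted enrichment is sharply non-monotone
in the background frequency: at factor 5, set 20 and background 1,000,
exact probability calculus (binomial carriers inside and outside the
set, hypergeometric tail threshold) gives power ≈ 0.89 at background
frequency 0.10 but ≈ 0.998 at 0.15. The acceptance check therefore
plants at 0.15, where a failure would indicate an implementation defect
rather than borderline power, and a separate calibration test verifies
that the *measured* detection rate matches the exact analytic power at
the weaker 0.10 plant within binomial error — so the statistics are
checked at both an easy and a hard operating point.

# Numerical choices and degenerate inputs

* Exact tests are computed from hypergeometric enumeration
  (`dhyper`/`phyper`), not normal approximations; the acceptance
  checks sweep every 2×2 table with N ≤ 60 (628,055 tables) and all
  hypergeometric margins with N ≤ 60 plus a dense margin grid to
  N = 200 against independent binomial-coefficient enumeration at
  1e-12.
* Layout: rho = 1 edges get length 1e-9 (not 0) so shortest paths stay
  valid; components of size 1 sit at the origin of their own box; the
  convergence flag reports whether the final refinement step moved any
  point more than 0.1% of the layout scale.
* `detectMountains` with every peak under `densityFloor` returns zero
  mountains and a warning; all-coincident coordinates fall back to a
  fixed fraction of the data range for the bandwidth.
* Ties in the flood are broken by processing order (decreasing
  density, then cell index), making labels deterministic.
* ANI with no qualifying fragment returns `NA` with a warning rather
  than 0, and zero-variance TETRA vectors return `NA` — both are
  sentinels for "undefined", distinct from any legitimate value.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: profile maps of 40–150 proteins over 24–60 genomes, genome pairs
of 20–100 kb, 100–200 replicate enrichment simulations, and the exact
p-value sweeps listed above. These sizes were chosen so the full suite
completes in well under a minute of compute per heavy block while
leaving every statistical check at its stated tolerance; the pipeline
itself has no hard size limits, though the all-pairs repulsion in the
layout is quadratic in protein count and becomes the dominant cost
beyond a few thousand proteins.

# Known limitations

* The 2-D embedding necessarily loses information: profiles that are
  distinct in rank space can land close on the map, and mountain
  boundaries depend on the kernel bandwidth. The mountain labels are a
  formalized, reproducible surrogate for what was originally a visual
  call on a 3-D terrain — not a model-based clustering with an
  uncertainty estimate.
* Reciprocal best hit yields at most one ortholog per genome pair per
  gene; in-paralogs and family expansions are out of scope, so Venn
  region counts are per-anchor-genome tallies, not family counts.
* The GenBank parser covers the subset of the format needed for
  chromosome statistics (interval locations, no qualifier parsing
  beyond raw text) and is not a general reader.
* ANI via maximal exact matches (the MUMmer variant) is not
  implemented; it requires an external match engine and is outside the
  package's retention-rule-and-averaging contract.
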