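# phylomapr

Comparative genomics of bacteria by **phylogenetic profiling**: build a
proteins × genomes matrix of best homology-search bit scores, embed the
proteins into a 2-D *phylogenomic map* whose density "mountains"
approximate functional modules, and test each mountain for gene-ontology
and niche (host-association / taxonomy) enrichment. Companion modules
provide threshold-based reciprocal-best-hit orthology with Venn
partitioning and gene-class extraction, whole-genome identity metrics
(fragment-based average nucleotide identity and tetranucleotide
z-score correlation), genome statistics from GenBank flat files, and a
fully seeded synthetic-data generator so every stage can be validated
against planted ground truth without downloading anything.

The package grew out of the comparative analysis of entomopathogenic
nematode symbionts (*Xenorhabdus*, *Photorhabdus*), where these methods
are used to ask which gene modules track a host-associated lifestyle;
all of the machinery is organism-agnostic.

## The methods in brief

* **Profiles.** From 12-column tabular all-vs-all protein search output,
  keep the best hit per (protein, genome); retain cells with bit score
  > 50 and e-value < 1e-5 (strict); drop proteins qualifying in < 5
  genomes. Absent hits are 0 bits.
* **Map.** Spearman rank correlation ρ between profile rows (average
  ranks for ties); per protein keep the top 50 positive correlates;
  embed with classical MDS on shortest-path distances (edge length
  1 − ρ) refined by deterministic force-directed iterations; call
  mountains as watershed basins of a Gaussian kernel density surface,
  with prominence-based merging of sampling ripples.
* **Enrichment.** Per mountain: hypergeometric upper-tail
  P(X ≥ k), X ~ Hypergeom(N, K, n), Bonferroni-corrected over tested
  terms; and two-sided Fisher exact tests of pooled per-gene profile
  category counts against the genome background, labeled Over/Under by
  the sample odds ratio.
* **Orthology.** minLrap = alignment length / shorter protein ≥ 0.6 and
  identity ≥ 30% (inclusive), reduced to reciprocal best hits per
  genome pair; Venn regions per anchor genome; require/exclude class
  queries.
* **Identity.** ANIb: mean identity of 1,020-bp fragments whose best
  hit reaches 30% identity over ≥ 70% of the fragment; TETRA: Pearson
  correlation of 256 tetranucleotide z-scores against maximal-order
  Markov expectations, counted on both strands.

See the methods vignette (`vignettes/phylogenomic-mapping.Rmd`) for the
full model, parameter rationale and design notes.

## Worked example

```r
library(phylomapr)

# plant 5 modules of 30 proteins across 60 genomes, 5% presence noise
sim <- simulateProfileMatrix(profileSimSpec(
  nProteins = 150, nGenomes = 60, nModules = 5, moduleSizes = rep(30, 5),
  noiseFlipProb = 0.05, seed = 42))
sim$matrix
#> ProfileMatrix: 150 proteins x 60 genomes
#>   filter: bit score > 50, e-value < 1e-05, >= 1 genomes
#>   positive cells: 4713 (52.4%)

mp <- phylogenomicMap(sim$matrix, k = 50, seed = 42)
mp
#> MountainMap: 150 proteins, 5 mountains (0 unassigned)
#>   largest mountains:
#>  mountain members peakDensity
#>         1      33   0.3608871
#>         2      30   0.3209945
#>         3      30   0.3015353
#>         4      29   0.2910292
#>         5      28   0.2618833

adjustedRand(mountainId(mp), sim$labels)
#> [1] 0.9495386
```

The five planted modules come back as the five mountains (adjusted Rand
index 0.95 against the planted labels — a handful of noise-flipped
proteins sit on the wrong slope). Niche enrichment of each mountain
against the genome background, here with arbitrary alternating labels,
is correctly null:

```r
host <- setNames(rep(c("host-associated", "not"), length.out = 60),
                 genomeIds(sim$matrix))
enr <- mountainCategoryEnrichment(mp, sim$matrix, host)
head(subset(enr, category == "host-associated"))
#>   mountain n_genes        category   a   b    c    d odds_ratio         p
#> 1        1      33 host-associated 469 430 1938 1876  1.0558044 0.4811068
#> 3        2      30 host-associated 431 410 1976 1896  1.0086600 0.9393397
#> 5        3      30 host-associated 491 505 1916 1801  0.9139203 0.2117447
#> 7        4      29 host-associated 452 462 1955 1844  0.9228064 0.2852733
#> 9        5      28 host-associated 564 499 1843 1807  1.1081827 0.1432809
```

Each row is a 2×2 contingency (`a`,`b` = mountain profile counts in /
out of the category; `c`,`d` = the rest of the genome's counts) with a
two-sided Fisher exact p and an Over/Under direction. And the identity
module recovers a simulated 5%-diverged genome pair to within a few
hundredths of a percentage point:

```r
g <- simulateGenomePair(genomePairSpec(1e5, substitutionRate = 0.05,
                                       seed = 42))
res <- anibPair(g$seqA, g$seqB)
sprintf("ANI %.3f%% vs expected %.3f%%", res$mean,
        100 * (1 - g$realizedDivergence))
#> [1] "ANI 94.927% vs expected 94.902%"
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/phylomap.R` (subcommands: `profiles`, `map`, `enrich`,
`orthologs`, `ani`, `tetra`, `stats`, `simulate`).

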