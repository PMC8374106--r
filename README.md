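# mchhislands

Statistical detection and comparative analysis of **mCHH islands** — short
regions of elevated CHH-context methylation that cluster immediately
upstream of genes in grass genomes — from per-cytosine bisulfite
sequencing counts.

Plant CHH methylation must be deposited de novo every generation, largely
by RNA-directed DNA methylation acting at transposable-element (TE)
edges. mCHH islands mark the boundary between gene-rich euchromatin and
TE-rich heterochromatin, and their presence correlates with genic
properties (TE proximity, gene length, expression, gene-body
methylation). This package is for epigenomics researchers who want to
call islands reproducibly across species with very different background
methylation levels, model their genic correlates, and ask whether island
state is evolutionarily conserved across one-to-one orthologs.

## The statistic at the core

Each chromosome is tiled into non-overlapping 100 bp windows. A window
with more than five covered CHH cytosines is tested for hypermethylation
with the exact one-sided binomial tail

P[X ≥ m],  X ~ Binomial(t, p₀),

where *m* and *t* are the window's methylated and total CHH read counts
and *p₀* is the genome-wide weighted CHH level (so each species is tested
against its own background). P-values are corrected by Benjamini–Yekutieli
across all tested windows; windows with q < 0.01 that overlap the
strand-aware 2 kb flank of a gene are mCHH islands. Downstream modules
attach per-gene predictors, fit logistic models of island presence with
variable-importance scores (|z|), test TE-superfamily enrichment against
the pooled proportion, and measure cross-species conservation as
observed/expected shared-island counts with permutation nulls and a
random (independence) model. A fully synthetic multi-species generator
with known ground truth backs every stage of the pipeline.

## Worked example

Simulate a grass-like methylome (1 Mb, 100 genes, islands planted in 40%
of genes), call islands and inspect the result:

```r
library(mchhislands)

cfg  <- sim_config(seed = 7, chrom_length = 1e6L, n_genes = 100L)
sim  <- simulate_species(cfg)
calls <- call_islands(sim$methylome, sim$genes)
summary(calls)
#> mCHH island calls (binomial mode)
#>   CHH background p0: 0.04479
#>   island windows: 105 of 10000 tested
#>   genes with a 5' island: 39 / 100
#>   genes with a 3' island: 0 / 100
#>   median island mCHH level: 0.3253
```

The estimated background (0.045) matches the configured 0.05 diluted by
low-methylation gene bodies; 39 of 100 genes gain a 5' island, matching
the planted 40%, and the median island methylation (~33%) sits in the
range reported for real grass islands. Fit the island model on a panel
with planted effects and rank the predictors:

```r
panel <- simulate_feature_panel(2000, seed = 42)
fit <- logistic_fit(panel, predictors = c("te_distance", "gene_length",
                                          "expression", "gbm"))
variable_importance(fit)
#>     predictor importance signed_importance
#> 1 te_distance  10.717710        -10.717710
#> 4         gbm  10.303335        -10.303335
#> 2 gene_length   7.223566          7.223566
#> 3  expression   4.462823          4.462823
```

TE distance and gbM are strong negative predictors of island presence,
gene length a positive one and expression the weakest — the planted
configuration, recovered with the correct signs. Cross-species
conservation arithmetic works directly on published per-species
proportions:

```r
p <- grass_island_summary()$pct_island_orthologs / 100
random_model_mean(p)
#> [1] 3.559
```

i.e. under independent gain/loss an ortholog is expected to carry an
island in ~3.56 of the eight species.

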