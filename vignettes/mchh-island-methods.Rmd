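---
title: "Statistical detection and comparative analysis of mCHH islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical detection and comparative analysis of mCHH islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mchhislands)
```

## The problem

Plant genomes methylate cytosines in three sequence contexts: CG, CHG and
CHH (H = A, C or T). CHH methylation is not copied through replication; it
must be deposited de novo each generation, largely by RNA-directed DNA
methylation (RdDM) acting at the edges of transposable elements (TEs). In
grasses, short regions of strongly elevated CHH methylation — *mCHH
islands* — concentrate immediately upstream of gene transcription start
sites (TSS), at the boundary between euchromatin and TE-rich
heterochromatin. This package implements a statistical pipeline that (i)
detects mCHH islands against each genome's own background methylation
level, (ii) relates island presence to genic properties (TE proximity,
gene length, expression, gene-body methylation) and (iii) quantifies how
well island state is conserved across species over one-to-one orthologs.

## Weighted methylation and the island test

All methylation levels are *weighted*: for a region and context, the
summed methylated read count divided by the summed total read count over
the region's covered cytosines of that context. A region with zero reads
has an *undefined* level, which propagates as `NA` rather than 0 — a
deliberately loud convention, since "no data" and "unmethylated" are
biologically different statements.

`call_islands()` tiles each chromosome into non-overlapping 100 bp
windows. A window enters testing only when it contains **more than five**
covered CHH cytosines; the rule is applied to covered sites, not
methylated ones, because a minimum-information filter should not
precondition on the alternative hypothesis. For each tested window the
p-value is the exact one-sided binomial upper tail
$P[X \ge m],\ X \sim \mathrm{Bin}(t, p_0)$, where $m$ and $t$ are the
window's methylated and total CHH read counts and $p_0$ is the
genome-wide weighted CHH level from `genome_background()`. Using the
genome's own $p_0$ — rather than a fixed empirical cutoff — makes calls
comparable between species whose background CHH levels differ several
fold.

P-values are adjusted with the Benjamini–Yekutieli (BY) step-up across
*all* tested windows genome-wide, before any gene-proximity rule. BY is
used rather than Benjamini–Hochberg because adjacent windows share reads,
read mapping and methylation machinery, so arbitrary dependence must be
tolerated; the cost is conservatism, which our null simulations confirm
(observed false-window rates are far below the nominal 1%). A window is an
island when its q-value is below `alpha` (default 0.01) **and** it
overlaps, by any base, the strand-aware 2 kb flank of at least one gene.
Any-base overlap is used because windows and flanks live on different
lattices; requiring containment would silently drop boundary islands.
Terminal partial windows are tested whenever they meet the site rule.

Two alternative calling routes are provided for robustness analysis: the
empirical cutoff mode (`empirical_cutoff_call()`, island iff weighted mCHH
$\ge$ 0.25, a closed bound) and the per-site route
(`call_site_methylation()`, which calls individual cytosines methylated or
not by a binomial test against the bisulfite non-conversion rate when they
have at least two reads). `method_agreement()` compares per-gene 5' status
between modes. The non-conversion rate has no hidden default — it is a
property of the experiment and must be supplied.

## Gene association and coverage

A gene's 5' (3') flank is the strand-aware 2 kb upstream of the TSS
(downstream of the termination site). `coverage_filter()` excludes a gene
when fewer than half of the CHH cytosines in its 5' flank exceed 2×
depth; excluded genes carry `NA` island status and drop out of every
downstream tally. `associate_genes()` reports, per gene, 5' and 3' island
status and the distance from the TSS to the nearest 5' island window
edge.

## Genic predictors and the logistic model

`gene_features()` assembles, per gene:

* **TE distance** — distance from the TSS to the nearer edge of the
  closest annotated repeat, strand-indiscriminate; 0 when a repeat
  overlaps the gene; missing (and excluded from TE analyses) when the
  scaffold has no repeat.
* **Gene length** — the full annotated span including introns; the
  exon-summed length of the longest transcript is carried as a secondary
  quantity. When a gene has several transcripts the longest one (ties:
  lexicographically smallest id) defines the exon set.
* **Expression quartile** — quartiles of log2 RPKM over expressed genes,
  using linear-interpolation quantiles; genes absent from the expression
  table are quartile 0, as are genes present with RPKM 0 (log2 undefined
  there; a switch includes them as expressed). Values equal to a
  breakpoint fall in the lower quartile, so a fully tied expressed set
  degenerates to quartile 1.
* **gbM** — gene-body methylation, both the quantitative weighted exonic
  CG level and a binary classification: one-sided binomial CG
  hypermethylation against the genomic CG background, BH-corrected across
  genes at FDR 0.05, and (classic definition, switchable) not CHG- or
  CHH-hypermethylated at the same threshold.

`logistic_fit()` models 5' island presence on these predictors after
rescaling each to [0, 1] by $(x - \min)/(\max - \min)$ — dividing by the
*shifted* maximum so the result genuinely spans the unit interval. Missing
data are dropped listwise with the count recorded. The fit is
maximum-likelihood IRLS (tolerance 1e-8, 100 iterations); complete
separation and aliased (collinear) coefficients are detected and flagged
rather than silently reported. `variable_importance()` scores each
predictor by the absolute Wald z of its coefficient, with a signed variant
for display, since the coefficients themselves sit on different scales
even after the rescaling. Either the binary or the quantitative gbM
variable may enter the model; binary is the default.

## Cross-species analyses

`ortholog_panel()` holds island state per ortholog per species, with `NA`
where an ortholog fails coverage in a species; pairwise quantities use
only doubly scored orthologs. `pairwise_enrichment()` compares the
observed count of orthologs with islands in both species against
$N p_i p_j$; `permutation_test()` obtains its null by shuffling one
species' labels (shuffling both is equivalent in distribution), with the
add-one p-value estimator. `random_model_mean()` gives the analytic
expectation of the per-ortholog species count under independence (the sum
of the per-species proportions) with a seeded Monte-Carlo variant;
the variant's p-value is two-sided by default because the scientific
claim being evaluated is indistinguishability from the random model, with
a one-sided option. `conservation_lm()` regresses the per-ortholog island
count (0–8) on a genic variable averaged over the species with data,
reporting the signed-r² display convention.

For phylogenetically structured regressions, `pgls_fit()` solves
generalized least squares with the Brownian tip covariance (shared
root-to-tip path lengths) taken from the supplied tree, with no Pagel's-λ
estimation; it reduces exactly to OLS on a star tree, which the tests
verify to machine tolerance.

## TE analyses

`superfamily_enrichment()` tests each Wicker superfamily's island
proportion against the pooled proportion with a two-sided exact binomial
test and BH correction; the two-sided default with direction labels
(Enriched/Under/NS) reproduces all 36 published labels for barley, rice
and maize, and a one-sided option exists. `classify_coincidence()`
restricts a species pair's orthologs to those with a lineage-specific
island and a lineage-specific TE and tests coincident versus dissonant
counts against 50:50 with a 1-df goodness-of-fit χ²; the per-superfamily
breakdown uses 2×2 contingency χ² with BH. `island_te_distances()`
anchors distances at the island window midpoint (edge-order invariant for
a 100 bp window) and compares the dispersion of island–TSS versus
island–TE-edge distances with the Feltz–Miller asymptotic CV-equality
test, implemented from the pooled-CV χ² statistic. BLAST homology is
summarised per query by the best e-value, with hitless queries assigned
1.0 and an equal-count seeded sample of non-island windows as the control
set.

## The synthetic generator

`simulate_species()` generates a random genome sequence and derives
cytosine contexts from it on both strands, so CG/CHG/CHH site densities
and strand handling are exercised realistically rather than painted on.
Study conditions (fixed defaults): CG/CHG/CHH backgrounds 0.60/0.40/0.05
— grass-like, with CHH well under the ~12% ceiling observed in real
backgrounds; read depth Poisson with mean 10; methylated counts
beta-binomial with concentration 50 to emulate biological overdispersion
(binomial mode available for exact-theory tests); islands planted in 40%
of genes as 100–300 bp tracts starting uniformly 0–1500 bp upstream of
the TSS, methylated at 0.40 (CHH) and background + 0.2 (CG, CHG),
mirroring the all-context elevation of real islands; gbM genes (30%) with
exonic CG 0.8 against 0.05 in unmethylated gene bodies; TEs with the
nearer edge within 2 kb upstream for half the genes, drawn from a
TIR-leaning superfamily mix; 80% of genes present in the expression table
with log2-normal RPKM. Genes are placed without overlap and with full 2 kb
flanks; infeasible packings are refused. All randomness flows from the
single mandatory seed and reruns are bit-identical.

`simulate_panel()` draws per-species island indicators with marginal
probabilities and exchangeable cross-species correlation ρ via a Gaussian
copula; ρ = 0 reproduces the independent (random-model) regime and ρ > 0
produces detectable conservation, which brackets the biological question
without asserting a mechanism. What the generator does **not** emulate:
mappability artefacts, unassembled gaps, annotation error, TE sequence
homology (islands are placed independently of TEs unless configured
otherwise) and tissue-specific expression. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under the
stated generative model, not performance on any particular real genome.

## Numerical choices and problem sizes

Window tests use exact binomial tails (no normal approximation); BY and
BH adjustments cap at 1; the BY step-up is implemented directly and
cross-checked in the tests against both an independent step-up
implementation and `p.adjust`. Degenerate inputs error loudly: background
levels of exactly 0 or 1, constant vectors in the 0–1 rescaling,
responses without variation, saturated PGLS fits, zero-variance OLS
predictors. Validation simulations use one 5 Mb chromosome with 300 genes
per replicate (20 null replicates for false-discovery control, one
planted-island replicate for recovery), 800–5,000-ortholog panels for
conservation calibration, and 200–500 replicates for type-I-error and
slope-recovery checks; these sizes give Monte-Carlo error comfortably
below the tested tolerances while keeping the suite quick. Recovery is
scored at the gene level for sensitivity (a planted island gene is
recovered when it gains 5' island status) and at the window level for
precision (a called window is correct when it overlaps a planted tract),
because tracts and the window lattice are offset, so partial-overlap
windows are genuinely elevated and should not count as errors.

## Known limitations

The caller assumes binomial read counts within a window; overdispersion
beyond what BY conservatism absorbs would inflate false calls. The
coverage filter and flank geometry clip at chromosome ends rather than
consulting assembly gaps. The per-site route shares the window route's
gene-association machinery but not its FDR scope. PGLS supports a single
predictor with Brownian covariance only. None of the analyses model
within-species biological replication; inputs are one methylome per
species.
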