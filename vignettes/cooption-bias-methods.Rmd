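---
title: "Methods: testing expression-driven gene co-option for C4 photosynthesis"
author: "c4coopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing expression-driven gene co-option for C4 photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4coopt)
```

## The scientific question

C4 photosynthesis is a carbon-concentrating pathway that evolved dozens of
times independently in flowering plants, each time by recruiting
("co-opting") members of pre-existing gene families into the new
biochemical cycle. Most C4 enzymes are encoded by multigene families, yet
across independent C4 origins within a clade the *same* few gene lineages
tend to be recruited again and again. `c4coopt` implements the inference
chain used to ask, for a clade with many independent C4 origins (the model
case is the grasses, with ten sampled origins):

1. Were fewer distinct gene lineages co-opted than expected by chance,
   given family sizes and the number of co-option events? (a resampling
   test)
2. Does the inferred *ancestral* leaf transcript abundance of a lineage —
   its expression before C4 evolved — predict how often it was co-opted?
   (Brownian-motion ancestral reconstruction followed by linear models)
3. Does leaf *specificity* (the leaf/root abundance ratio) add anything?

The premise is biological: a weak C4 cycle can only emerge through few
mutations if the needed enzymes are already present in leaves at
moderately high levels, so ancestral abundance should be a strong
predictor of which family member gets recruited.

## The pipeline, stage by stage

### Quantification

Transcript abundance is measured as **rpkm**: reads per kilobase of
aligned exons per million cleaned reads,

$$\mathrm{rpkm} = \frac{c}{(\ell/1000)\,(N/10^6)}$$

for mapped count $c$, effective length $\ell$ (bp) and cleaned-read total
$N$. The formula is applied per replicate library and replicates of the
same (species, tissue) are averaged arithmetically *on the rpkm scale*,
because libraries differ in depth; replicate counts are recorded in the
output. No pseudocounts, length-bias or GC corrections are applied —
downstream stages depend on the thresholded scale being interpretable in
raw rpkm units. Read mapping itself is out of scope: the package consumes
a count table with per-lineage effective lengths.

Leaf specificity is the ratio $(\text{leaf} + \epsilon)/(\text{root} +
\epsilon)$ with a pseudocount $\epsilon$ (default 1 rpkm, configurable)
guarding against zero denominators; with complete absence in both tissues
the ratio floors at 1 (no specificity information).

### Co-option calling

A lineage is called co-opted in a C4 origin when its replicate-mean leaf
rpkm reaches a threshold $T$ (default 500; the sweep re-runs everything at
300, 1000 and 1500) in **at least one** sampled C4 species of that origin.
Two design points matter:

* **Counting is per origin, not per species.** An origin sampled by two
  C4 species contributes at most one count per lineage, so per-lineage
  counts are bounded by the number of origins.
* **The non-C4 exclusion filter.** A lineage whose leaf abundance reaches
  $T$ in *any* non-C4 species is excluded outright (all calls false): its
  high expression is evidently not diagnostic of C4 function. This is the
  β-carbonic-anhydrase situation — an enzyme that participates in the C4
  cycle but is equally abundant in non-C4 leaves for other reasons.

The **modelling universe** is all lineages belonging to families with at
least one co-opted lineage. At the default study dimensions (58 lineages,
14 families) this reproduces the published degrees-of-freedom bookkeeping:
a single-predictor model leaves 56 residual df; two numeric predictors
plus the 14-level family factor leave term df (1, 1, 13) on 42 residual
df.

### The resampling bias test

The null model conditions on everything except lineage identity: every
observed co-option event keeps its (origin, family) label and picks a
lineage **uniformly at random within its family** — independently across
origins, without replacement among multiple events of one origin in one
family (preserving the observed event count exactly). The statistic is
the number of distinct lineages picked at least once; preferential reuse
shows up as an observed value in the null's lower tail. The one-sided
p-value uses the add-one correction $p = (\#\{S_b \le S_{obs}\} + 1)/(B +
1)$, so $p \ge 1/(B+1)$; the default $B = 10^5$ resolves p-values down to
$10^{-5}$. `exact_null()` enumerates the same null exactly (per family,
then convolving across families, with a refusal guard on the raw outcome
space) and serves as the oracle for the Monte Carlo version in the test
suite.

### Ancestral reconstruction

Expression traits are modelled as Brownian motion on the species tree:
tip values $x \sim \mathcal{N}(\mu \mathbf{1}, \sigma^2 C)$ with $C$ the
shared root-to-MRCA path-length matrix. The fit is maximum likelihood:
$\hat\mu$ is the GLS mean (also the ML root state) and $\hat\sigma^2 =
(x-\hat\mu)^\top C^{-1} (x-\hat\mu)/n$ divides by $n$, not $n-1$ — the
estimator therefore carries the known $(n-1)/n$ downward bias, which the
test suite checks explicitly. Ancestral states maximize the joint BM
likelihood over all internal nodes simultaneously; on the tree graph this
is harmonic interpolation with edge weights $1/\text{branch length}$, so
estimates and their curvature-based variances come from the internal-node
block of the weighted graph Laplacian. The 95% interval at each node is
$\hat{y}_j \pm 1.96\sqrt{\hat\sigma^2 [L_{yy}^{-1}]_{jj}}$. Polytomies
are handled natively by the graph formulation; zero-length terminal
branches are an error (singular covariance).

**Only non-C4 species enter the reconstruction** — C4 tips carry the
derived, massively upregulated state and would bias the inferred ancestral
condition upward. The tree is pruned accordingly, with unary nodes
suppressed and branch lengths summed so surviving root-to-tip depths are
unchanged. When no tree is available the arithmetic mean across non-C4
species (`c3_mean_proxy()`) stands in; on tree-structured data the two
track each other closely (the test suite requires squared correlation
above 0.9 across lineages), which is what justifies the proxy for clades
where only one or two non-C4 relatives have been sequenced.

Traits are reconstructed on the **raw rpkm scale by default**, with a
`log_scale` flag exposing a `log10(x+1)` alternative. Raw is the default
because the threshold rule and the published modelling operate on raw
rpkm; the log option exists because expression is log-normally distributed
across lineages and a user may prefer variance-stabilized reconstruction.
Leaf abundance and the leaf/root ratio are reconstructed as two separate
univariate analyses.

### Modelling co-option counts

Per-lineage co-option counts are regressed on ancestral leaf abundance
(`ala`), ancestral leaf/root ratio and gene family identity with ordinary
least squares (`stats::lm`), followed by **sequential (Type I) analysis of
variance** in the fixed order (ala, leaf/root, family) — each term's F is
computed on its extra sum of squares given the terms before it, which is
the classical `anova(lm(...))` workflow and reproduces the published df
accounting. Counts are small non-negative integers, so Gaussian OLS is an
approximation; a Poisson log-link option is exposed
(`fit_ols(..., family = "poisson")`) but the Gaussian fit is the default
and the one used throughout the acceptance checks, matching the original
analysis workflow. p-values are reported unadjusted. The
threshold-sensitivity sweep re-runs calling, counting and modelling at
each threshold; ancestral reconstructions depend only on non-C4
expression and are computed once.

## The synthetic-data generator

Every stochastic stage is testable without any sequencing data because
the generator emulates the full study design with a recorded truth table.
Defaults mirror the empirical dimensions: 25 species on a unit-depth
pure-birth tree; 10 disjoint monophyletic C4 origins totalling 13 C4
species (12 non-C4 remain); 14 gene families of sizes 8, 5, 5, 5, 5, 5,
5, 4, 4, 4, 4, 2, 1, 1 (58 lineages — family sizes of 2, 8, 1 and 1 are
fixed by the known sizes of the dikinase, translocator, carboxykinase and
antiporter families, the rest chosen in the published 1–8 range to reach
58). The tree topology is a stand-in: only the BM covariance structure
matters for the analyses.

Per lineage, leaf log10 abundance evolves by BM from a root value drawn
$\mathcal{N}(1.0, 0.45)$ (≈ 10 rpkm typical, tails to a few hundred) with
rate 0.1 per unit depth, and the leaf/root log10 ratio independently from
$\mathcal{N}(0, 0.4)$ with rate 0.15. These scales are set so that
co-optable lineages are "moderately abundant" in non-C4 leaves and the
non-C4 exclusion filter fires about once per dataset — one lineage in
~58, the regime observed empirically — rather than censoring the most
abundant lineages wholesale.

Co-option events: each (origin, family) pair experiences an event with
probability 0.6 (the published count table implies 90 events across 140
origin × family pairs, ≈ 0.64). Given an event, a lineage is chosen with
probability $\propto \exp(\beta z)$ where $z$ is its standardized
ancestral leaf log-abundance; $\beta = 0$ is the uniform null used for
calibration, $\beta = 3$ the default biased setting. The chosen lineage's
leaf expression in that origin's C4 tips becomes $\max(F \cdot x,\,
\tau)$ with fold change $F$ log-uniform on 10–480 and functional target
$\tau$ log-uniform on 1000–10000 rpkm: a weak C4 cycle demands high
absolute flux, so upregulation saturates at a functional level rather
than remaining a pure multiple of a possibly tiny ancestral value. (This
also keeps detection of true events essentially complete at all sweep
thresholds, so the $\beta = 0$ null is not confounded by
abundance-dependent detectability.) The leaf/root ratio of co-opted
lineages is multiplied by a specificity boost, log-uniform on 10–1000.

Counts are emitted per replicate library (2 biological replicates by
default) by inverting the rpkm formula with multiplicative log-normal
noise (sdlog 0.25), integer rounding, library depths uniform on 5–20
million reads and effective lengths uniform on 500–5000 bp. Reads compete
for sequencing depth: the expected mapped fraction of each library is
capped at 0.9 and saturated libraries are renormalized, which guarantees
that emitted counts can never exceed the library total; the truth table
records the post-saturation relative abundances.

What the generator does **not** emulate: real gene-tree/species-tree
discordance, lateral gene transfer, mapping ambiguity between close
paralogs, isoform structure, GC and length biases, cell-type composition
of whole-organ libraries, and correlated evolution between abundance and
specificity. Passing the recovery tests therefore shows the statistical
machinery is correct and well calibrated under the declared model, not
that the biological conclusions of any particular empirical dataset are
robust to those complications.

## Numerical and design choices

* **Tie-breaks and degenerate inputs.** Constant tip values give
  $\hat\sigma^2 = 0$ (flagged) and zero-width intervals; thresholds that
  call no lineage mark their sweep block degenerate rather than erroring;
  species missing a tissue yield absent cells and `NA` ratios, never
  exceptions; empty event sets skip the bias test with a warning.
* **Determinism.** Every stochastic function takes a seed;
  `simulate_dataset()` runs all stages under a single seeded stream, and
  reports echo the seeds, so a rerun of the same config reproduces every
  output exactly.
* **Chol-based GLS.** BM fitting uses a Cholesky factor of $C$ (never an
  explicit inverse); the per-lineage reconstruction caches the factor and
  the Laplacian block per tip set, since all lineages of a dataset share
  the same pruned tree.
* **Exact enumeration guard.** `exact_null()` refuses configurations
  whose raw outcome space exceeds $10^6$, even though its per-family
  factorization would often cope, so its cost is predictable.
* **Problem sizes in the test suite.** Calibration suites use 500
  unbiased datasets at $B = 2000$ for the bias test, 500 BM simulations
  for interval coverage on a 50-tip tree, and 200 end-to-end pipeline
  runs per $\beta$ at the default 25-species dimensions — sizes chosen so
  binomial 99% bounds are tight enough to detect miscalibration while the
  whole suite stays desk-scale.

## Limitations

Lineages are treated as independent observations in the count models, as
in the original workflow — no phylogenetic correction on the *gene* tree
is attempted. The BM model is the only trait-evolution model offered (no
Ornstein–Uhlenbeck or multi-rate variants). The bias test conditions on
the observed event count and family sizes; it cannot speak to why an
origin recruited a family at all. Whole-leaf transcriptomes cannot see
cellular or subcellular localization, which demonstrably matters for
which isoform is recruitable; the exclusion filter is a blunt but
transparent instrument for the one confound it targets.
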