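# c4coopt

Gene co-option bias analysis for C4 photosynthesis transcriptomes.

C4 photosynthesis evolved dozens of times in flowering plants by
recruiting ("co-opting") members of pre-existing multigene families into a
new biochemical cycle — and independent C4 origins within a clade keep
recruiting the *same* few gene lineages. `c4coopt` implements the full
inference chain for asking why, across a clade with many independent C4
origins (the model case is the grasses, with ten origins among 25
species):

* **Quantification** — rpkm per co-ortholog group from read-count tables
  (`rpkm = count / ((length/1000) · (total/10⁶))`), replicate-averaged per
  species and tissue, plus the leaf/root abundance ratio as a leaf
  specificity proxy.
* **Co-option calling** — a lineage is co-opted in an origin when its
  leaf abundance reaches a threshold (default 500 rpkm, sweepable over
  300/500/1000/1500) in ≥ 1 C4 species of that origin; lineages equally
  abundant in any non-C4 species are excluded as non-diagnostic. Counting
  is per origin, never per species.
* **Bias test** — a resampling null in which every co-option event keeps
  its (origin, family) identity but picks a lineage uniformly within its
  family; the statistic is the number of distinct lineages used at least
  once, with one-sided p = (#{null ≤ obs} + 1)/(B + 1), and an exact
  enumeration oracle for small configurations.
* **Ancestral reconstruction** — maximum-likelihood Brownian-motion
  estimation of each lineage's leaf abundance and leaf/root ratio at the
  root of the *non-C4* phylogeny: x ~ N(μ1, σ²C), μ̂ by GLS, σ̂² the ML
  (divide-by-n) rate, joint-ML internal states via the tree's weighted
  graph Laplacian with curvature-based 95% intervals; a non-C4 mean proxy
  covers tree-less datasets.
* **Modelling** — sequential (Type I) ANOVA on OLS models of per-lineage
  co-option counts against ancestral leaf abundance, leaf/root ratio and
  gene family, in that order, over the lineages of families co-opted at
  least once, with a threshold-sensitivity sweep.
* **Synthetic data** — a generator producing complete datasets (tree,
  origins, BM-evolving expression, biased co-option with functional
  upregulation, replicate counts with log-normal noise) and a truth
  table, so every stage is testable at desk scale.

The package ships a transcription of the published per-lineage co-option
counts for grasses (18 lineages co-opted at least once, up to 10 times)
in `inst/extdata/table1_cooption_counts.tsv`.

## Worked example

Simulate a study-sized dataset with co-option biased toward ancestrally
abundant lineages (β = 3), then run the whole pipeline:

```r
library(c4coopt)

sim <- simulate_dataset(sim_config(beta = 3), seed = 1)
sim
#> Synthetic C4 co-option dataset (seed 1 )
#>   25 species (13 C4 in 10 origins), 58 lineages in 14 families
#>   78 true co-option events, beta = 3

report <- run_all(sim)
report
#> C4 co-option pipeline report
#>   lineages co-opted >= once: 22 (max count 8)
#>   bias test: observed 22 vs null 40.66 +/- 2.15, P = 9.999e-05
#>   ancestral leaf abundance: F = 11.07 (df 1, 42), P = 0.00183, R^2 = 0.46
```

Reading the output: of 58 co-optable lineages, 22 were called co-opted at
least once — far fewer than the ~41 the family-conditional null expects
for 78 events, so the resampling test rejects at its resolution floor
(B = 10 000 resamples). The sequential ANOVA then attributes the reuse to
ancestral leaf abundance:

```r
report$model$anova
#>       term         F df_term df_resid          p
#>        ala 11.071414       1       42 0.00183000
#>  leaf_root  5.005280       1       42 0.03063384
#>     family  1.523871      13       42 0.14899528
```

Ancestral leaf abundance (`ala`) enters first and is strongly significant
(F = 11.07 on 1 and 42 df); family identity adds little once abundance is
known. The degrees of freedom (1, 1, 13 on 42 residual) are the full
bookkeeping for 58 lineages, two numeric predictors and a 14-level family
factor. `threshold_sensitivity()` repeats calling → counting → modelling
at 300/500/1000/1500 rpkm to show the conclusion does not hang on the
threshold, and `reconstruct_ancestral_traits()` exposes the per-lineage
root estimates with confidence intervals that the model consumes.

A thin command-line wrapper covers shell use:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "c4coopt.R", package = "c4coopt"))') \
    run-all --config config.yaml --out results/
```

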