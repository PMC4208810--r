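# icnx — integrative copy-number / expression clustering

`icnx` subtypes cancer cell-line panels by integrating gene-level DNA
copy-number calls (gain / loss / neutral, with a loss-of-heterozygosity
flag) with matched log2 expression profiles, and then asks whether the
resulting integrative clusters differ in drug sensitivity. It is aimed at
groups who have run aCGH (or any segmentation pipeline emitting gene-level
calls) on a panel of lines, have public or in-house expression for the same
lines, and want a reproducible, testable version of the standard
burden → drivers → consensus clusters → signature → pathways → drugs
workflow instead of a chain of one-off scripts.

## The methods at its core

* **Aberration burden and recurrence.** Per sample, the counts of GAIN,
  LOSS and LOH gene calls (flags counted independently, so the total is
  their exact sum); per gene, recurrence across samples as a rounded
  integer percent, optionally restricted to a gene list such as the
  531-kinase human kinome; per pathway, aggregated call counts.
* **Driver selection.** A gene is a putative driver when expression in its
  directional-aberrant samples differs from neutral samples
  (two-sided Mann–Whitney *U*, p < 0.05) *and* expression is rank-concordant
  with the copy dose (LOSS = −1, NEUTRAL = 0, GAIN = +1), Spearman ρ > 0.6.
* **Consensus clustering.** Resampled (500 × 80%) clustering of samples on
  driver-gene expression with 1 − Spearman distance and average linkage
  (UPGMA); the consensus matrix records co-clustering frequency among
  co-drawn pairs; the number of clusters is chosen from the change in area
  under the consensus CDF, Δ(k), and reported with all per-k statistics.
* **SAM signature.** Two-class d-statistic d = (x̄₁ − x̄₂)/(s + s₀) with an
  automatically tuned fudge constant s₀ and permutation q-values
  (median-count FDR); signature features at q < 0.02 feed a nearest-centroid
  classifier (Spearman correlation) for assigning new samples.
* **ssGSEA.** Rank-weighted (α = 0.25) running-sum enrichment score per gene
  set and sample, globally min–max normalized to [0, 1]; subtype-specific
  pathways are SAM-called at q < 0.2 with fold change > 2.0 (UP) or < 0.5
  (DOWN).
* **Drug sensitivity.** Four-parameter logistic IC50 refits with censoring
  at the top tested dose, and per-drug Mann–Whitney comparison of log10
  IC50 between the two clusters with medians and fold differences.
* **Synthetic cohorts.** A seeded generator plants two clusters, dose-driven
  driver genes, shifted marker gene sets and differential drugs, so every
  stage can be validated against known truth without any external data.

## Worked example

```r
library(icnx)
co  <- generate_cohort(cohort_spec(seed = 42))   # 60 samples, 2000 genes
res <- run_pipeline(co$calls, co$expr, co$gene_sets, co$ic50)

length(res$driver_genes)
#> [1] 91
res$k_advice$stats
#>   k       auc      delta
#> 1 2 0.5084746 0.50847458
#> 2 3 0.5324218 0.04709616
#> 3 4 0.5641403 0.05957404
#> 4 5 0.6040442 0.07073394
table(res$labels)
#> IC1 IC2
#>  30  30
head(res$drug_comparisons[, c("drug", "median1_uM", "median2_uM",
                              "fold_difference", "p_value",
                              "sensitive_cluster")], 3)
#>     drug median1_uM median2_uM fold_difference      p_value sensitive_cluster
#> 1 DRUG01  8.2791465  0.8891438        9.311369 3.019859e-11               IC2
#> 2 DRUG02  9.2675013  0.8816789       10.511198 3.019859e-11               IC2
#> 5 DRUG05  7.2833609  1.1792008        6.176523 3.338389e-11               IC2
```

Reading the output: 91 of the cohort's 100 planted driver genes pass both
filters; the Δ column collapses after k = 2, so two integrative clusters
are selected, and they coincide exactly with the planted ones (adjusted
Rand index 1). The drug table is sorted by p-value: the five planted
differential drugs surface first, with ~6–11-fold median IC50 differences
and IC2 the sensitive cluster, while null drugs show folds near 1.

The same stages are available from a shell via the thin CLI in
`inst/cli/icnx.R` (`simulate`, `aberrations`, `drivers`, `cluster`,
`signature`, `ssgsea`, `drugs`, `run-all`), each reading and writing the
documented TSV/GMT/JSON files.

## Layout

* `R/` — implementation (I/O, burden, drivers, consensus, SAM, ssGSEA,
  drugs, synthetic cohorts, pipeline).
* `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are generated in code.
* `vignettes/integrative-clustering.Rmd` — the model, its assumptions,
  parameter defaults and the design decisions behind them.
* `inst/cli/icnx.R` — command-line front end.
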