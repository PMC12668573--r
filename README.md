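# agrostack

Does stacking more sustainable agricultural practices — no-till plus
rotation plus residue retention plus cover crops … — deliver more
agroecosystem services than switching a single practice?  `agrostack` is an
R implementation of the full analysis pipeline used to answer that question
from paired field comparisons of sustainable versus intensive cereal
management: practice coding and counting, log-response-ratio effect sizes
with bootstrap confidence intervals, environmental driver analysis, and
random-forest spatial prediction with an applicability mask.  A synthetic
database generator with known ground truth makes every stage testable
without any external data.

## The statistics at the core

* **Effect size** — the log response ratio of paired treatment means,
  `LnRR = ln(X_s / X_i)`; positive values favour the sustainable
  treatment.  Attribute-level effects are averaged (unweighted) to
  observation-level service effects, then summarized per service ×
  practice-count bin (1–6, "7+") or per intensity class (low = 1–3,
  high = 4–8 practices), with a percentile bootstrap 95% CI
  (B = 4999); a group is significant when the CI excludes zero.
* **Environmental drivers** — VIF screening (flag > 5), Spearman
  correlations, per-block OLS fits (the univariate-response degeneration
  of RDA) with permutation p-values, and four-block variance partitioning
  of adjusted R² (spatial / climate / soil / vegetation) into all
  15 unique and shared fractions, re-derived from inclusion–exclusion
  rather than delegated.
* **Mapping** — a self-contained Rcpp regression random forest
  (999 trees × 100 independently seeded replicates at full scale, mean of
  replicate predictions), permutation importance with
  response-permutation significance, a Mahalanobis applicability mask at
  the 0.95 chi-square quantile, 0–1 standardization of unmasked cells,
  and low-vs-high scenario comparison maps.
* **Synthetic world** — true LnRR is linear in the number of practices per
  service (`alpha_s + beta_s * n`), modulated by standardized site
  covariates, with site random effects and residual noise; intensive means
  are lognormal and `X_s = X_i * exp(LnRR)`.  The generator returns the
  truth table so recovery is checkable.

## Worked example

```r
library(agrostack)
sim <- simulate_database(sim_config(seed = 1))   # 349 sites, 1570 rows
db  <- sim$database

tabulate_counts(db)
#>   bin   n percent
#> 1   1 471   30.00
#> 2   2 392   24.97
#> 3   3 254   16.18
#> 4   4 175   11.15
#> 5   5 135    8.60
#> 6   6  81    5.16
#> 7  7+  62    3.95
```

Most observations change only one or two practices; about 4% stack seven
or more, mirroring the scarcity of heavily stacked treatments in real
compilations.

```r
eff <- summarize_effects(db, group_by = "count", B = 1999, seed = 1)
subset(eff, service_id == "carbon_sequestration")
#>              service_id group  n n_studies mean_lnrr  ci_low ci_high significant
#> 8  carbon_sequestration     1 59        52    0.0739  0.0157  0.1369        TRUE
#> 9  carbon_sequestration     2 37        34   -0.0449 -0.1243  0.0346       FALSE
#> 10 carbon_sequestration     3 21        21    0.2233  0.0939  0.3604        TRUE
#> 11 carbon_sequestration     4 28        28    0.0334 -0.0769  0.1533       FALSE
#> 12 carbon_sequestration     5 13        13    0.2049  0.0729  0.3435        TRUE
#> 13 carbon_sequestration     6 10        10    0.0676 -0.1100  0.2589       FALSE
#> 14 carbon_sequestration    7+  7         7    0.1449 -0.0536  0.3130       FALSE
```

`mean_lnrr` is the group's mean effect (e.g. 0.22 at three practices is a
~25% gain, `exp(0.22) ≈ 1.25`, under sustainable management); the CI
columns are the percentile bootstrap interval, and `significant` records
whether it excludes zero.  With per-group samples this small the noisy
non-monotone sequence is expected; the underlying truth in this simulated
world rises linearly with the count.

```r
ea <- env_analysis(db, "carbon_sequestration", class = "high",
                   n_perm = 999, seed = 1)
ea$blocks
#>        block     r2  adj_r2 p_value df
#> 1    spatial 0.0167 -0.0379   0.842  3
#> 2    climate 0.2756  0.2059   0.005  5
#> 3       soil 0.1213  0.0550   0.153  4
#> 4 vegetation 0.0842  0.0333   0.186  3
ea$varpart
#> Variance partitioning over four predictor blocks (n = 58)
#> Full-model adjusted R2: 0.2280  (residual 0.7720)
#> Unique fractions:
#>    unique_spatial    unique_climate       unique_soil unique_vegetation
#>           -0.0050            0.1889           -0.0297           -0.0004
#> Pooled shared fraction: 0.0741
```

Climate is the only block with a significant fit (permutation p = 0.005)
and carries nearly all of the uniquely attributable variance — consistent
with the generator's aridity/temperature modulation.  Negative fractions
are a normal feature of adjusted-R² partitions.

The end-to-end pipeline (simulate → effects → environment → maps, with a
JSON run manifest and CSV outputs) is one call:

```r
out <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

and a command-line front end is installed at
`system.file("cli", "agrostack.R", package = "agrostack")` with subcommands
`simulate`, `effects`, `envpart`, `map`, `run-all`.

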