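---
title: "How many sustainable practices? Models and methods behind agrostack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many sustainable practices? Models and methods behind agrostack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrostack)
```

## The question and the estimand

Field experiments comparing sustainable and intensive cereal management
rarely vary one practice at a time: a "sustainable" treatment may stack
no-till, rotation, residue retention, organic fertilization and more.
`agrostack` treats the *number* of practices coded sustainable as the dose
and asks how six agroecosystem services — crop yield, soil fertility,
carbon sequestration, SOM decomposition, soil habitat and biodiversity —
respond to that dose.

The effect size is the log response ratio of paired treatment means,

$$\mathrm{LnRR} = \ln\!\frac{X_s}{X_i},$$

with $X_s$ the mean of an ecosystem attribute under sustainable management
and $X_i$ its mean under the intensive control in the same study.  LnRR is
antisymmetric and scale-free, but it is undefined for nonpositive means, so
such records are excluded with a logged reason rather than imputed.

Aggregation runs in a fixed order: attribute-level LnRR, then the
unweighted mean across the attributes one observation reports for a
service, then the group summary across observations.  The middle step
prevents studies that report many attributes from dominating a service.
All means are unweighted: the paired-means effect size carries no
within-study variance, so no inverse-variance weighting is available or
attempted.

Practice counts are binned 1–6 with 7 and 8 pooled as "7+" (treatments
stacking that many practices are rare), and dichotomized into low (1–3)
versus high (4–8) intensity for the environment and mapping analyses.
An aridity split uses the UNEP convention: arid means aridity index
(MAP/PET) strictly below 1; the boundary value 1 goes to non-arid because
arid is defined by a strict inequality.

## Uncertainty: percentile bootstrap

Group means get a nonparametric percentile bootstrap CI
(default `B = 4999`, seeded); a group is significant when the 95% interval
excludes zero, with no multiple-comparison correction — the analysis is a
descriptive synthesis, not a family of confirmatory tests.  A Student-t
interval is available (`method = "t"`) as a parametric cross-check.  With
fewer than two effects the CI is reported as undefined and the group is
never significant.  The percentile method at $n = 30$ holds its empirical
type-I error within the 0.05 ± 0.02 band checked in the acceptance suite;
it is known to be slightly liberal at much smaller group sizes, which is a
limitation inherited from the method, not a tuning choice.

## The synthetic world

There is no generative model in an observational synthesis, so the package
states one — the simplest structure consistent with a monotone benefit of
stacking practices — and uses it as ground truth for every downstream test:

$$\mathrm{LnRR}_{os} = \alpha_s + \beta_s\, g(n_o) + \gamma^\top
\tilde{z}_{site(o)} + u_{site(o)} + \varepsilon_{o},$$

where $g(n) = n$ by default (a saturating $g(n)=\log(1+n)$ is a switch),
$\tilde z$ are standardized site covariates, $u \sim N(0, \sigma^2_{site})$
and $\varepsilon \sim N(0, \sigma^2_\varepsilon)$.  Intensive means are
lognormal (positivity is required by the log ratio) and sustainable means
are $X_s = X_i e^{\mathrm{LnRR}}$, i.e. the effect-size model inverted.

Default scale parameters are chosen once, as field-plausible values, and
not revisited: 349 sites and 1570 paired rows (the compilation's headline
dimensions); per-service intercepts and slopes placed so that yield is
slightly negative at one practice and positive near seven, carbon becomes
positive around three practices, and fertility around six — the qualitative
pattern the dose–response synthesis reports; $\sigma_{site} = 0.1$ and
$\sigma_\varepsilon = 0.3$ (meta-analytic scatter is large relative to mean
effects of order 0.1); count probabilities right-skewed so that roughly 3%
of rows stack 7+ practices.  Environmental modulation defaults to small
loadings on aridity, sand and MAT ($\gamma$ = 0.05, 0.03, −0.02 per SD).
Because covariates enter standardized, the expected group mean at count $n$
is just $\alpha_s + \beta_s g(n)$, which is what `truth_expected()`
returns; the pooled 7+ bin mixes counts 7 and 8, so its exact expectation
is the truth line at the bin's realized mean count.

Site covariates (15, in four blocks: spatial, climate, soil, vegetation)
come from a Gaussian copula with configurable within-block and cross-block
latent correlation, then monotone-transformed to bounded, field-plausible
marginals (pH in 3.5–9, sand in 0–100%, lognormal elevation/SOC/total P,
logistic NDVI and cover).  Two deliberate departures from raw sampling:
practice counts 1..8 are guaranteed to appear whenever there are at least
eight observation units (the generator's contract promises the full span,
and a plain multinomial draw misses count 8 several percent of the time at
moderate sizes); and each site is used at least once when the unit count
allows.

What a green test on this world does *not* establish: the generator has no
geographic clustering, no publication bias, no heteroscedastic measurement
error, and its covariates are exchangeable across space — so passing
recovery tests says the estimators are correct, not that the real
compilation satisfies the model.

## Environmental analysis

Collinearity is screened by the variance inflation factor,
$\mathrm{VIF}_j = 1/(1-R^2_j)$, flagging values above 5; `vif_screen()`
drops the worst offender iteratively and accepts a `keep` list for
variables chosen a priori over a collinear partner (as total P is retained
over available P).  Spearman correlations are computed as rank-then-Pearson
with average ranks and a two-sided t-approximate p.

With a univariate response (one service's LnRR), redundancy analysis on a
predictor block degenerates to OLS; `block_fit()` implements it as such and
attaches a permutation p-value, $p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) /
(1 + n_{perm})$, which is never zero by construction.

`varpart4()` partitions the full model's *adjusted* $R^2$ over the four
blocks into 15 Venn fractions.  Rather than hard-coding the
inclusion–exclusion formulas, it fits all 15 block unions and solves the
linear system $A(S) = \sum_{T \cap S \neq \emptyset} f_T$ — 15 equations in
15 unknowns whose solution reproduces the classical partition exactly (the
test suite checks agreement with an independent implementation to 1e-8) and
makes the sum identity hold at machine precision by construction.  Negative
fractions are reported as-is; they are a known and meaningful feature of
adjusted-$R^2$ partitions.  The display-level pooled "shared" value is
`total − sum(unique)` since the pooling of the 11 shared fractions into one
number is otherwise unspecified.

## Mapping

The mapping stage trains a regression random forest of the service effect
on the 14 non-latitude covariates.  No forest implementation ships with
the target R stack, so the package implements one (Rcpp): CART trees with
variance-reduction splits, bootstrap resampling, `mtry = ceil(p/3)`,
minimum node size 5, out-of-bag predictions, and an internal seeded RNG so
fits are reproducible regardless of R's RNG state.  The full-scale
configuration is 999 trees × 100 replicates; "replicates" are read as
independently seeded forests whose predictions are averaged, with the
across-replicate spread retained as an uncertainty layer (the aggregation
is otherwise unspecified).  Tests and examples scale these down.

Predictor importance is the mean increase in MSE when a column is shuffled;
significance follows the response-permutation scheme (refit on permuted
$y$, compare observed importance with the null importances), with
$p = (1+\#\{null \ge obs\})/(1+n_{perm})$.

Predictions are only trusted inside the training data's environmental
envelope: cells whose squared Mahalanobis distance to the training mean
(under the training covariance, ridge-regularized if near-singular)
exceeds the 0.95 chi-square quantile are masked.  The degrees of freedom
default to the covariate dimension — the statistically consistent choice —
with an override (`mask_df = 6`) to replicate published masks that fix
df = 6.  Masking happens *before* 0–1 standardization, so the unit-interval
scaling is computed over analog cells only (the alternative order is a
configuration away via `standardize01()` directly).  Scenario maps (low vs
high practice number) are compared cell-wise with an equivalence band of
±0.1 on the standardized scale — a default chosen because no band is
published; it is configurable.

Grids are abstract lattices (matrix + origin + cell size) with block-mean
aggregation and conservative resampling to coarser resolutions only;
validation regresses observed on predicted (observed on the y-axis), so
perfect predictions give slope 1, intercept 0, $R^2 = 1$.

## Numerical choices and degenerate inputs

* Bootstrap and permutation p-values use the +1 convention and can never
  be zero; the smallest attainable p is $1/(n_{perm}+1)$.
* A degenerate bootstrap (all effects equal) collapses the CI to a point,
  significant iff the common value is nonzero.
* `standardize01()` maps a constant grid to all zeros with a warning.
* Exact collinearity in `vif()` reports `Inf` for every involved predictor
  instead of erroring, so screening can proceed.
* All randomness flows from one master seed through
  `derive_seed(master, stage)` — a fixed affine-mod rule that keeps seeds
  in the positive 32-bit range — so each stage is independently
  reproducible.

## Known limitations

* The practice taxonomy and attribute–service map are documented stand-ins
  for study-specific coding tables; both are overridable arguments.
* No meta-regression, mixed-effects weighting, or publication-bias
  diagnostics; the upstream analysis uses none.
* No spatial autocorrelation modelling; the synthetic world is
  exchangeable over sites, so spatial-dependence pathologies are untested.
* The forest implements regression defaults only (no quantile forests, no
  categorical split handling beyond numeric codes).
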