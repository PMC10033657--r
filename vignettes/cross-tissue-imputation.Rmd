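---
title: "Cross-tissue transcriptome imputation: model, evaluation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue transcriptome imputation: model, evaluation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ximpute)
```

## The problem and the model

Blood is the only transcriptome most human studies can sample at scale,
but for neuropsychiatric questions the tissue of interest is the brain.
The two tissues share systemic biology — genetic regulation, hormonal
and immune state, age — and that shared component is exactly what a
cross-tissue predictor can exploit. `ximpute` models it linearly: a
principal component analysis summarizes the normalized blood expression
matrix into `k` orthogonal scores per donor, and every brain gene gets
its own least-squares regression on those scores,

$$Y_g = \beta_0 + \beta_1 X_1 + \dots + \beta_k X_k + \varepsilon .$$

Training requires donors with *paired* blood and brain profiles; once
trained, the model needs only blood. The approach assumes (i) expression
is on a roughly Gaussian log scale, (ii) the blood–brain relationship is
captured by a low-dimensional linear map, and (iii) the deployment
cohort's blood data are normalized comparably to training. Nothing in
the model uses genotypes: it is complementary to eQTL-based
transcriptome imputation, which predicts only the genetically regulated
component.

## Parameters that matter

* **`k`, the number of blood PCs** (default 40). The conventional
  family is `k ∈ {5, 10, 20, 40}`; more components capture more blood
  variance, and training R² is provably non-decreasing in `k`, but
  out-of-fold accuracy is what should drive the choice. Train the
  family, cross-validate each, keep the best.
* **PCA scaling** (`scale`, default `FALSE`). Genes are centered but
  not standardized before the SVD; whether blood PCs should be computed
  on centered-only or unit-variance genes is genuinely open, so the
  flag exposes both. Centering-only is the default because log-scale
  expression variance is biologically meaningful.
* **Normalization recipe** (`normalize_expression`): log2(CPM + 1),
  keeping genes with log2(CPM + 1) > 1 in ≥ 20% of samples. These are
  standard bulk RNA-seq defaults, not a claim about any particular
  corpus's pipeline; every threshold is an argument so a user can match
  the preparation of their training data exactly. The function refuses
  to re-normalize data flagged as log-scale unless forced.
* **Significance criterion** (`call_significant`): mean CV R² ≥ 0.01
  and BH q ≤ 0.05, both boundaries inclusive. The R² floor keeps
  trivially-but-significantly correlated genes out; the FDR arm
  controls multiplicity across the tens of thousands of genes modeled
  per region. Both thresholds are arguments.
* **Residualization** (`residualize`): OLS on an intercept plus the
  named covariates, categoricals one-hot with a dropped reference
  level; gene means are added back so the expression scale survives.
  Blood and target matrices are residualized independently with the
  same covariate list, which avoids leaking target-tissue signal into
  the predictor side.

## Cross-validation and the per-gene p-value

Accuracy is estimated with a single k-fold cross-validation (default 5
folds, balanced, seeded): per fold, the PCA *and* all per-gene
regressions are refit on the training folds only and the held-out
donors are projected onto the training PCs. Per-gene `r` and `R² = r²`
are averaged over validation folds. `R²` is deliberately the squared
Pearson correlation — not `1 − SS_res/SS_tot` — so the paired
`(R², r)` columns reported per gene are exactly consistent; a gene
whose predictions anti-correlate with observation keeps its negative
`mean_cv_r` as the flag.

The per-gene p-value comes from a correlation test on the pooled
out-of-fold predictions, each donor held out exactly once. Pooling raw
predictions, however, is a trap: each fold's model carries its own
intercept (the training-fold mean), and under the null these
fold-specific offsets correlate systematically with the held-out fold
means, inflating the pooled correlation. In null simulations the naive
pooled test called up to ~10% of 500 pure-noise genes significant at
n = 200. The package therefore centers observations and predictions
within each validation fold before pooling — the partial correlation
given the fold factor — and spends the corresponding degrees of freedom
(`df = n − 2 − (folds − 1)`). With this correction the null fraction
called significant is well under the 5% FDR target (0.2–0.6% in the
acceptance runs).

## Numerical choices

* PCA is an SVD of the centered samples-by-genes matrix; each
  component's sign is fixed by making its largest-magnitude gene
  loading positive, so results are deterministic across platforms.
  Sign indeterminacy is harmless anyway — flipping a loading column
  together with its regression coefficients leaves every imputation
  unchanged, and a test asserts exactly that.
* Per-gene OLS is solved by one QR decomposition shared across genes;
  never iterative methods. The mega-analysis t-values use the same QR
  with per-gene residual variances.
* Constant vectors have no defined correlation: such genes get `NA`
  accuracy and are excluded from significance calls rather than
  silently scored.
* Degenerate inputs fail loudly with classed conditions: zero-variance
  matrices, `k > n − 1`, rank-deficient designs, mismatched donor sets
  (joined by ID, never by position), truncated model archives.
* Gene identifiers are opaque strings; version suffixes (`.N`) are
  stripped during alignment by default so versioned and unversioned
  annotations match. Absent genes are mean-imputed at the training
  centers (zero contribution to PC scores), with a coverage attribute
  and a low-coverage warning escalatable to an error.
* Odds ratios in enrichment tables use the Haldane–Anscombe 0.5
  correction only when a cell is zero; p-values always come from the
  exact test on raw counts.
* For comparing two concordances the default is the independent-samples
  Fisher r-to-z test; when both correlations share the reference brain
  vector, a Steiger test (`dependent = TRUE`, requiring the correlation
  between the two non-shared vectors) is available. Which the field's
  reports used is usually unstated, so both are exposed and neither is
  asserted as canonical.

## What the simulator emulates — and what it does not

`generator_spec`/`generate_paired` draw donors with `L` shared standard
normal latent factors. Blood gene *j* is `Z w_j + σ e` with unit-norm
loadings; brain gene *g* is `√v_g · Z w_g + √(1 − v_g) · e`, so the
population R² of predicting gene *g* from the factors is exactly
`v_g` — an analytic ceiling that cross-validated accuracy should
approach from below. Defaults (150 donors, 300 blood / 200 brain genes,
5 factors, shared variance 0.3, blood noise SD 1) are sized like a
single-region paired cohort: donor counts in the low hundreds, blood
measurement noise comparable to the factor signal, and a minority of
expression variance shared across tissues.

Case-control cohorts shift cases' latent factors by a vector `γ`. A
diagnosis effect transmitted to blood must lie in the span of the `L`
shared factors, so per-gene brain effect totals are derived from `γ`
(`δ_g = t_g/τ`, `t_g = √v_g · w_g'γ`), making exactly the fraction `τ`
of each effect recoverable by imputation; `τ = 0` instead draws
independent brain-only effects. The analytic brain DGE t-values
(`δ_g` over the unit within-group SD and the group sizes) serve as
ground truth without simulating brain tissue for the cohort.

The simulator does **not** emulate: count-level noise (data are
Gaussian on the log scale; there is no negative-binomial layer),
library-size or batch artifacts beyond the declared age/sex/study
effects, heavy-tailed expression, correlated gene modules beyond the
factor structure, or realistic effect-size distributions. Passing tests
on simulated data therefore demonstrate the estimator's correctness and
calibration under its own assumptions — not that any particular real
tissue pair shares this much variance. Notably, because the simulated
blood loadings of a gene are independent of its brain loadings,
blood-level DGE is nearly uncorrelated with the brain signature; real
blood shows small positive concordance, so the simulated
imputed-versus-blood gap is cleaner than reality.

## Design decisions that were genuinely open

* **Boundary convention**: significance uses `≥ 0.01` and `≤ 0.05`
  inclusively on both arms; both thresholds configurable.
* **BH scope**: FDR adjustment is applied across genes within one run
  (one region), not across regions; cross-region comparisons adjust the
  comparison p-values instead.
* **Fold p-value**: pooled-and-fold-centered correlation test, as
  motivated above; per-fold `R²` remains the accuracy metric.
* **Method comparison t-tests**: two-sample Welch by default — each
  method contributes its own significant-gene accuracies — with
  `paired = TRUE` available when both cover the same genes.
* **Serialization**: one self-describing RDS archive per region
  (schema version, PCA, coefficient table, metadata), verified on load.
* **Interface**: the exported functions are the primary surface; the
  CLI (`inst/cli/ximpute.R`) is a thin wrapper covering the deployment
  workflow (`simulate`, `train`, `impute`, `cv`).

## Problem sizes used in the shipped checks

The test-suite and acceptance script simulations are sized to exercise
the statistics, not to mimic genome scale: shared-variance recovery
uses 2000 donors with 300 blood genes and 20 target genes per level
(`v ∈ {0, 0.25, 0.5, 0.9}`, `k = L = 5`), null calibration uses 500
null genes at 2000 donors, and the end-to-end case-control comparison
trains on 300 paired donors over a 2000-gene universe and deploys on
250 cases / 250 controls. At these sizes recovered mean CV R² sits
within ±0.05 of the population `v` and the full acceptance run takes a
few seconds.

## Known limitations

* Linear-in-PCs only; nonlinear blood-brain maps are out of scope.
* No genotype-based component: purely expression-to-expression.
* The normalization defaults stand in for whatever pipeline produced a
  user's training corpus; matching it is the user's responsibility.
* Deployment assumes comparable normalization; the package checks gene
  coverage, not distributional drift.
* One CV repetition (a single seeded fold assignment), so fold-level
  accuracy estimates carry Monte Carlo noise; repeated or nested CV is
  intentionally not implemented.
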