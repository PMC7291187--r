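---
title: "Hybrid single/multiple imputation with sice: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid single/multiple imputation with sice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sice)
```

## The problem and the method

Single imputation (fill each missing cell with the column mean, median, or
mode) is cheap but treats the filled value as if it were observed: it
understates variance and can bias any downstream analysis. Multiple
imputation by chained equations (MICE, also called fully conditional
specification) instead produces $m$ completed datasets, each missing cell
receiving $m$ stochastic draws $x_i^1, \dots, x_i^m$ from models fit
conditionally on the other variables — but it leaves the analyst with $m$
datasets to carry through every later step.

`sice` implements the hybrid: run the chained-equations engine to get the
$m$-value array for every missing cell, then collapse each array back to a
single value,

* **categorical columns** — the most frequent element of the array
  (majority vote), and
* **numeric columns** — the arithmetic mean of the array,

yielding one completed dataset whose cell values still reflect the spread of
the $m$ conditional draws. With $m = 1$ the method degenerates to a single
chained-equations draw, so the pooled estimator is a strict generalization.

For a numeric cell with truth $t$ and chain draws $x^1,\dots,x^m$, the
root-mean-square norm is convex, so pooling can only help on average:
$\mathrm{RMSE}(\bar{x}) \le \frac{1}{m}\sum_j \mathrm{RMSE}(x^j)$. The
engine asserts this inequality on every numeric benchmark run
(`run_experiment()`), and the acceptance suite checks it across seeds.

## The chained engine

`run_mice(table, chain_spec(...))` runs $m$ independent chains. Each chain

1. fills every missing cell with a random draw from its column's observed
   values (so chains start from independent states);
2. sweeps the incomplete columns in visit order for `n_cycles` cycles; in
   each sweep the column's originally missing rows are re-imputed from a
   model of that column on the current completed values of all other
   columns, fit on the originally observed rows.

Chain $j$ uses an RNG substream derived from `(seed, j)`: results are
bit-reproducible, chains are exchangeable, and permuting chains permutes
the per-cell arrays without changing their multisets.

**Defaults and why.** `m = 7` follows the empirical choice of the benchmark
design this package reproduces (the usual recommendation is 3–10).
`n_cycles = 5` is the conventional burn-in for chained equations; with a
single incomplete column the sweeps are conditionally independent and the
value of `n_cycles` is immaterial, but multi-column missingness needs the
cycles to propagate information between columns. The visit order is
ascending missing count (ties by schema order), so later imputations
condition on better-populated columns. One reading ambiguity is worth
recording: "run the engine $m$ times" could count chains or total sweeps;
this implementation takes $m$ as the number of independent chains, which is
statistically identical to $m$ external runs of a one-chain engine.

## Univariate kernels

Each kernel fills the missing rows of one target column given complete
predictors; categorical predictors enter regression-type fits as
reference-level dummies and ordinal predictors as integer ranks.

* **pmm** — predictive mean matching. Regress the target on the predictors
  (least squares, coefficients $b$); draw $\sigma^{*2}$ from the scaled
  inverse-$\chi^2$ posterior of the residual variance and
  $b^* \sim N(b, \sigma^{*2}(X'X)^{-1})$; predict observed rows with $b$
  and missing rows with $b^*$; for each missing row take the `donors = 5`
  observed rows with the closest predictions and copy one of their observed
  values at random. Imputations are therefore confined to observed values —
  useful for bounded or discrete measurements. Ordinal and binary targets
  are handled as integer ranks and decoded back (confinement guarantees a
  valid level). Five donors is the de-facto standard in chained-equation
  engines.
* **blr** — Bayesian linear regression: the same posterior draw, imputing
  $x'b^* + \varepsilon$, $\varepsilon \sim N(0, \sigma^{*2})$. No prior is
  imposed beyond the standard noninformative one; an exactly collinear
  design falls back to a ridge of $10^{-6}$ with a warning, and a perfect
  fit collapses the posterior ($b^* = b$, $\sigma^{*2} = 0$).
* **logreg** (binary) — binomial GLM; each missing row is a Bernoulli draw
  at its fitted probability, *not* the argmax, so chains disagree where the
  model is uncertain — exactly the variability majority pooling averages
  over. A single observed class short-circuits to a constant fill with a
  warning.
* **polyreg** (categorical) — multinomial logistic fit (`nnet::multinom`);
  missing rows are drawn from their fitted category distribution.
* **lda** (categorical) — class means and pooled within-class scatter,
  eigendecomposition of the between/within problem, projection onto the
  leading discriminant directions, Gaussian posteriors with proportional
  priors; labels are drawn from the posteriors. A singular scatter is
  shrunk toward a scaled identity ($\lambda = 10^{-4}$) and classes with
  fewer than two observed rows are dropped, both with warnings. The
  posteriors match `MASS::lda` to machine precision on well-conditioned
  data (a unit test asserts this).
* **cart** — `rpart` tree (Gini splits for categorical targets, deviance
  for numeric; `min_leaf = 5`, no pruning); each missing row is routed to
  its leaf and imputed by a uniform draw from the leaf's *observed* values
  rather than the leaf mean/mode, again to preserve the uncertainty the
  pooling step needs.
* **mean / median / mode / random** — the single-imputation baselines.

**Tie-break for majority pooling.** With an even $m$ a two-way tie is
possible. Ties are broken deterministically: first toward the level more
frequent among the column's *observed* values, then toward the earlier
schema level. This uses data evidence before arbitrary order and keeps
pooling free of randomness, so a pooled dataset is a pure function of the
chain outputs.

## Amputation and scoring

`ampute_mcar()` masks exactly `floor(rate * n_rows)` cells of one fully
observed column, uniformly at random (MCAR), keeping the removed values as
ground truth. The floor convention reproduces both of the benchmark counts
this design is calibrated against (10% of 21,614 rows = 2,161 cells; 10% of
65,000 rows = 6,500). Only MCAR is generated: the benchmark's injections
are random, and because the synthetic generator plants structure on fully
observed predictors, MCAR masking of the target trivially satisfies the
missing-at-random assumption the chained engine relies on.

Categorical imputations are scored with confusion-matrix metrics
(accuracy, balanced accuracy, sensitivity, precision, specificity,
F-measure); multi-class metrics are macro-averaged one-vs-rest, a choice
the referenced confusion-matrix tooling leaves open — macro treats classes
symmetrically and is the documented convention here. Ratios with zero
denominators are reported as 0 with a note rather than `NaN`, so degenerate
predictors still produce a full report. Numeric imputations are scored by
RMSE over the masked cells only; observed cells are never scored.

## The synthetic generator

`generate_health_like()` emulates a compact clinical registry: `Gender`
(binary), `Region` (3 levels, probabilities 0.5/0.3/0.2), `Diagnosis`
(4 levels, 0.4/0.3/0.2/0.1), and `Age` (years). The two nominal columns
drive both outcomes:

* `Age` $= 30 + \{0, 8, 16\}_{\text{Region}} + \{0, 6, 12, 18\}_{\text{Diagnosis}}
  + N(0, 8.7)$ — the level offsets contribute a variance of about 75
  years², so with `noise_sd = 8.7` roughly half of the Age variance is
  explainable ($R^2 \approx 0.5$): a planted but noisy linear signal.
* `Gender` follows a logistic model on the same dummies,
  $\text{logit}\,P(\text{Male}) = -1.5 + \{0, 1.5, 3\}_{\text{Region}} +
  \{0, 1, 2, 3\}_{\text{Diagnosis}}$ — cell probabilities range from about
  0.18 to 0.99, a well-separated but overlapping signal.

These defaults are the study conditions of every benchmark in the test
suite and acceptance script (with `rate = 0.1`, `m = 7`); they are fixed,
not tuned. What the generator does *not* emulate: skewed or heavy-tailed
numeric columns, rare categories, correlated missingness across columns,
MNAR mechanisms, and measurement error. Passing benchmarks on this
generator therefore demonstrates that the machinery recovers planted
conditional structure under MCAR — not that it wins on any particular real
dataset.

## Numerical choices and degenerate inputs

* Residual degrees of freedom in the posterior draw are floored at 1, and a
  residual sum of squares below $10^{-12}\max(1, \|y\|^2)$ is treated as an
  exact fit.
* PMM donor distances are ranked with stable ordering, so donor pools are
  reproducible; inside the engine the donor count is clamped to the number
  of observed rows (with a warning) so sparse columns remain imputable,
  while direct kernel calls treat an oversized donor pool as an error.
* Fully missing columns are rejected; single-class categorical targets fall
  back to constant imputation with a warning everywhere.
* CSV round-trips preserve doubles exactly: cells are written with the
  shortest decimal text that parses back to the identical value.
* Problem sizes in the test suite (tables of tens of rows for kernel
  oracles; $n = 2000$, 20 replicates for the recovery benchmark; 1,000
  randomized tasks for PMM confinement) are the package's chosen benchmark
  scale: large enough for the signal margins above to dominate sampling
  noise, small enough to run routinely.

## Known limitations

* Rubin's-rules pooling of downstream *analysis* estimates is deliberately
  out of scope: the method's point is to hand the analyst one dataset.
  The price is that the pooled dataset understates imputation variance
  relative to carrying all $m$ datasets — the classic single-imputation
  caveat, mitigated but not removed by averaging over chains.
* Mode pooling of ordinal columns ignores level order (no median-of-ranks
  variant); that matches the categorical pooling rule as specified.
* The engine's predictor set is always "all other columns"; there is no
  predictor-matrix customization or convergence diagnostics.
* `ampute_mcar` generates MCAR only; structured MAR/MNAR patterns must come
  from the data-generating process, not the amputer.
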