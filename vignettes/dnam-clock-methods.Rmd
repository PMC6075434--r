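---
title: "Methods: building and applying a skin & blood style methylation clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and applying a skin & blood style methylation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamclock)
```

## The model

An epigenetic clock is a sparse linear predictor of age from methylation
beta values. `dnamclock` regresses a *calibrated* age on CpG betas: the
transform

$$F(x) = \begin{cases}
\log\frac{x+1}{a+1} & x \le a \\[4pt]
\dfrac{x-a}{a+1} & x > a
\end{cases}$$

with adult-age anchor $a$ (default 20 years) is logarithmic through
childhood and linear in adulthood, continuous and continuously
differentiable at $a$ (both one-sided slopes $1/(a+1)$), strictly
increasing on $(-1,\infty)$, and zero at $a$. The motivation is empirical:
clock-CpG methylation changes roughly an order of magnitude faster before
age twenty than after, so a linear model fits the transformed scale far
better than raw years. Ages are allowed slightly below zero so that
gestationally offset cord-blood samples ($x > -1$) stay in the domain. The
anchor is a tunable parameter (`adult_age`); we default to 20 because that
is where the pediatric-to-adult kink in clock-CpG trajectories sits, and
because it makes models comparable with the established pan-tissue clock
lineage.

Predictions are made on the transformed scale and mapped back to years with
the exact inverse, so "DNAm age" is always reported in years.

## Candidate CpGs and the elastic net

Training proceeds in two stages.

**Preselection** (`preselect_cpgs()`). Per stratum (by default the `tissue`
annotation), each probe's Pearson correlation with transformed age is
computed; the union over strata of the `k_pos` most positively and `k_neg`
most negatively correlated probes is kept, plus the `k_null` probes with
the least significant pooled age correlation (largest correlation-test
p-value, default 500). Defaults for `k_pos`/`k_neg` are 1000 each — large
enough not to be the bottleneck on array-scale data while keeping the
solver's problem small. Zero-variance probes count as correlation 0 with
p = 1; strata with fewer than three aged samples are skipped with a
warning; ties are broken lexicographically by probe ID so selection is
deterministic.

**Fitting** (`fit_elastic_net()`). The solver minimizes

$$\frac{1}{2n}\sum_i\bigl(y_i - b_0 - x_i^\top b\bigr)^2 +
\lambda\Bigl(\alpha\lVert b\rVert_1 + \tfrac{1-\alpha}{2}\lVert b\rVert_2^2\Bigr)$$

by cyclic coordinate descent with soft-threshold updates, warm starts down
a 100-point log-spaced $\lambda$ grid, and an active-set strategy.
Predictors are standardized internally to mean zero and unit $1/n$-variance
(the conventional contract for this estimator family); coefficients are
returned on the beta scale. $\alpha$ defaults to 0.5. $\lambda$ is chosen
by k-fold cross-validation (default 10 folds) at the minimum mean squared
held-out error; fold assignment is drawn from a private RNG seeded by the
`seed` argument, so training is bit-for-bit reproducible and never
disturbs the caller's RNG state.

Numerical choices worth knowing:

* **Convergence.** Sweeps stop when the largest squared coefficient update
  falls below `tol` (default 1e-12). The final solution is then *polished*
  at the selected $\lambda$ until the stationarity (KKT) residual of the
  penalized objective is below 1e-7, so downstream users can rely on the
  returned coefficients being an actual minimizer rather than a
  solver-tolerance artifact.
* **Path truncation.** Like standard solvers of this family, the
  cross-validation path stops refining once the explained variance
  saturates (relative gain < 1e-5 per step); later grid points inherit the
  last solution. The final fit at the selected $\lambda$ never truncates.
* **Degenerate columns.** Zero-variance probes are frozen at coefficient
  zero and cannot perturb other weights. A constant response is an error
  ("no age variation"), as is having fewer samples than folds.
* **Missing betas.** Training imputes missing values with the probe's
  training-column mean before fitting; the same means are stored in the
  model and reused at prediction time, so the imputation convention is
  consistent in both directions.

Note that the widely used reference solver for this problem rescales a
gaussian response to unit variance internally, which implicitly divides the
ridge part of the penalty by the response SD; our objective is exactly the
one printed above. The test suite cross-checks the two solvers under the
exact parameter mapping between the conventions.

## Prediction and the imputation report

`estimate_dnam_age()` computes $b_0 + \sum_j w_j \beta_j$ per sample and
inverse-transforms it to years. Model probes absent from the input (or
missing for a sample) are imputed with the stored training means, and every
output row carries `n_imputed`/`frac_imputed`; samples above
`max_missing_frac` (default 0.2) are flagged rather than dropped, so a
failed sample is always visible and never silently clean. Prediction is
invariant to probe order and to extra unweighted probes.

## Age acceleration

Epigenetic age acceleration is defined against a reference regression of
DNAm age on chronological age through control samples
(`fit_reference()`, degree 1 by default — a plain regression line — with an
optional quadratic for analyses where curvature over a wide age range
matters). A sample's acceleration is its vertical distance to that
reference (`residual_acceleration()`); by the least-squares property the
control mean is zero. The covariate-adjusted analysis
(`adjusted_acceleration()`) is ordinary least squares of DNAm age on any of
age, age², cumulative population doubling level, and a disease indicator,
with two-sided t-test p-values and a hard error (naming the offending
columns) on rank-deficient designs. No multiple-testing correction is
applied: these are single-model coefficient tables. Group contrasts use the
Kruskal–Wallis rank test with average ranks and the standard tie
correction, p-values from the $\chi^2_{k-1}$ tail; the chi-square
approximation is used throughout (no exact permutation), matching
conventional reporting.

## Ex vivo population doubling

Per-passage population doubling is
$(\log_{10}(\text{harvested}) - \log_{10}(\text{seeded})) \times 3.32$ —
the printed laboratory constant, kept verbatim by default so that numbers
match lab notebooks; `exact = TRUE` substitutes $1/\log_{10}2 = 3.32193$,
under which one cell doubling is exactly 1.0 PD. Cumulative PD is the
running sum, and `pd_age_trend()` reports the least-squares slope of DNAm
age on cumulative PD (years per doubling) with its Pearson correlation.

## What the synthetic generator does (and does not) emulate

`simulate_methylation()` plants "causal" CpGs whose mean beta follows
$\operatorname{logistic}(a_j + b_j z_i)$, where
$z_i = F(\text{age}_i) + \text{tissue offset} + \text{disease offset}
\cdot \mathbb{1}[\text{case}]$ is the sample's true biological age on the
transformed scale; intercepts are uniform on $(-1, 1)$, slope magnitudes
uniform on $(0.3, 0.8)$ with balanced signs, and truncated Gaussian noise
(default SD 0.03) is added on the beta scale. Null probes are age-flat.
Defaults (100 samples, 50 causal + 450 null probes, ages uniform on 0–90)
mirror the standard recovery experiment used in the tests; the disease
offset is injected on the *transformed* scale, which makes the planted
effect larger in years for young samples — the way progeroid acceleration
presents, and the reason case–control contrasts are strongest in children.
Two overlapping platform manifests are emitted (a configurable fraction of
probes is private to one platform) so the cross-platform intersection step
is exercised.

What it does **not** emulate: beta-distributed (heteroscedastic) noise,
probe-type chemistry differences, batch effects, correlated CpG modules,
or cell-composition heterogeneity. Passing the recovery tests therefore
shows the estimator recovers a planted monotone signal at realistic
signal-to-noise — not that it reproduces any published coefficient set,
which would require the original training arrays.

`simulate_pd_series()` drifts the causal-probe logits linearly in
cumulative population doubling (default 0.15 years per doubling, 20
passages seeding 10,000 cells) and draws harvest counts to hit a target
per-passage PD, so both the bookkeeping and the trend estimate can be
validated against ground truth.

## Problem sizes and design choices

The tests and the acceptance script run the recovery experiment at 400
samples (300 train / 100 held out) with 50 causal and 450 null CpGs —
small enough to train in about a minute on one core, large enough that
held-out correlation and support recovery are stable (r ≈ 0.998, recovery
0.80–0.92 across seeds). Replicate-based checks (type-I calibration of the
adjusted model, offset and slope recovery) use 100–200 replicates of
44-sample or 20-passage datasets.

Genuinely open choices we fixed, and why:

* **Probe universe.** No canonical 450K∩EPIC probe list ships with the
  package; platform restriction is driven entirely by user-supplied
  manifests, since any bundled list would be stale.
* **λ rule.** Minimum mean CV error (not the 1-SE rule): the goal is
  predictive accuracy of the clock, and the sparser 1-SE models trade
  accuracy for parsimony. Both the CV curve and its SEs are stored in the
  model for users who prefer otherwise.
* **Published coefficient files without probe means.** Loadable
  (`read_clock_coefficients()`), and usable as long as every model probe is
  present in the data; imputation then errors rather than guessing, since
  inventing means for someone else's clock would be silently wrong.
* **Acceleration residuals from published tables.** The bundled progeria
  table carries published acceleration values whose control reference was
  never released; group tests on that column use the published numbers
  as-is rather than refitting an unknowable reference.

## Limitations

The solver is dense and in-memory: it is meant for the post-preselection
problem (thousands of probes), not for raw 850k-probe matrices. The clock
assumes beta values on a common namespace and does no normalization or IDAT
processing. Acceleration inference is plain OLS — no robust or mixed-effect
variants — and the Kruskal–Wallis p-value is asymptotic, which is the
conventional but approximate choice at progeria-study group sizes.
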