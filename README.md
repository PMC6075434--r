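# dnamclock

Build, apply, and interrogate DNA methylation age clocks of the
skin & blood family.

## The problem

DNA methylation at a few hundred CpG sites changes so reproducibly with age
that a penalized linear model on array beta values ("an epigenetic clock")
predicts chronological age to within a few years. Clocks trained mostly on
whole tissues, however, are badly miscalibrated on cultured fibroblasts,
keratinocytes, and endothelial cells — exactly the material used in ex vivo
aging studies — and that miscalibration can hide real biology, such as the
accelerated epigenetic aging of fibroblasts from Hutchinson–Gilford progeria
(HGPS) patients. `dnamclock` implements the full workflow for building and
using a fibroblast-compatible clock:

* reading/validating Illumina-style beta matrices (probes × samples,
  values in [0,1]) and restricting them to probes shared by the 450K and
  EPIC platforms;
* the calibrated age transform
  `F(x) = log((x+1)/(a+1))` for `x ≤ a`, `(x−a)/(a+1)` for `x > a`
  (anchor `a` = 20 years by default), which linearizes the fast pre-adult
  methylation drift;
* CpG preselection by age correlation per cell type, plus a block of
  least-age-associated probes;
* elastic-net fitting, `min (1/2n)‖y − b₀ − Xb‖² + λ(α‖b‖₁ + (1−α)/2‖b‖₂²)`,
  by an in-package coordinate-descent solver with cross-validated λ
  (α = 0.5 by default);
* DNAm age prediction with training-mean imputation of missing probes and a
  mandatory per-sample imputation report;
* epigenetic age acceleration — the residual from a reference regression of
  DNAm age on age through controls — with covariate-adjusted OLS models and
  Kruskal–Wallis group comparisons;
* cell-culture population-doubling bookkeeping
  (`PD = (log10(harvested) − log10(seeded)) × 3.32`) and DNAm-age-per-doubling
  trend estimation;
* a synthetic methylation generator with known ground truth, so the whole
  pipeline is testable without array downloads.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`, `glance()`, and `autoplot()` methods.

## Worked example

Train a clock on synthetic data with 20 planted age-tracking CpGs, predict,
and run the published progeria group comparison:

```r
library(dnamclock)

sim <- simulate_methylation(n_samples = 120, n_causal = 20, n_null = 80, seed = 3)
clock <- train_clock(sim$beta, sim$annotation,
                     k_pos = 30, k_neg = 30, k_null = 20, folds = 5)
clock
#> <clock_model>
#>   probes: 17, intercept: -0.0692 (transformed-age scale)
#>   adult_age anchor: 20 years; alpha = 0.5; lambda = 0.02874
#>   trained on 120 samples (80 candidate probes)
#>   training fit: r = 0.998, median abs error = 1.23 years

estimate_dnam_age(clock, sim$beta)
#> # A tibble: 120 × 5
#>   sample_id dnam_age n_imputed frac_imputed flagged
#> 1 S0001         45.6         0            0 FALSE
#> 2 S0002         79.8         0            0 FALSE
#> ...
```

The elastic net kept 17 of 80 candidate probes; the training fit of
r = 0.998 with a median absolute error of 1.2 years is what a clock achieves
when the planted signal (logistic CpG trajectories in transformed age, noise
SD 0.03 on the beta scale) dominates the noise.

The bundled table of published clock results for HGPS fibroblast lines
reproduces the classic-progeria sex comparison:

```r
classic <- dplyr::filter(progeria_fibroblasts(), progeria == "Classic")
kruskal_wallis(classic$accel, classic$sex)
#> # A tibble: 1 × 4
#>   statistic    df p_value n_groups
#> 1      3.49     1  0.0618        2
```

i.e. marginal evidence (p = 0.062) that fibroblasts from classic-HGPS boys
are epigenetically older than those from girls.

Ex vivo tracking: a culture whose epigenetic age drifts 0.15 years per
population doubling is recovered from 20 passages with half-a-year noise:

```r
pd <- simulate_pd_series(n_passages = 20, drift = 0.15, seed = 9)
set.seed(9)
dnam <- pd$truth$bio_age + rnorm(20, 0, 0.5)
pd_age_trend(cum_pd = pd$truth$cum_pd, dnam_age = dnam)
#> # A tibble: 1 × 5
#>   slope intercept pearson_r slope_se     n
#> 1 0.150   -0.0809     0.876   0.0196    20
```

A command-line interface wrapping the same functions lives at
`exec/dnamclock` (subcommands `simulate`, `train`, `predict`, `accel`,
`pdtrack`).

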