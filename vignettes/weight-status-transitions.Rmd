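---
title: "Modelling childhood weight-status transitions from complex survey panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood weight-status transitions from complex survey panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightmsm)
```

## The model

`weightmsm` estimates movements of children between four ordinal weight
states — underweight (1), healthy weight (2), overweight (3) and obesity
(4) — from longitudinal surveys in which each child's state is observed only
at a handful of measurement waves. The underlying model is a continuous-time
Markov chain: a child in state $r$ moves to state $s$ with instantaneous
intensity $q_{rs}$ (per year), and the next move depends only on the current
state. Only clinically plausible instantaneous moves are allowed: adjacent
states communicate, everything else is structurally zero, giving exactly six
free intensities
$$q_{12},\; q_{21},\; q_{23},\; q_{32},\; q_{34},\; q_{43}.$$
A child can still be observed to go from healthy weight to obesity between
two waves; the model simply insists that it passed through overweight along
the way, and the likelihood integrates over all such unobserved paths.

With generator $Q$ (off-diagonal $q_{rs}$, diagonal $-\sum_{s\neq r}q_{rs}$),
the probability of occupying each state after $t$ years is the matrix
exponential
$$P(t) = \exp(Qt),$$
which is what `transition_probability_matrix()` computes and what connects
the fitted intensities to the annual transition matrices used by decision
models.

**Interval censoring.** Transition times between waves are never observed.
Each child contributes, for every pair of consecutive measurements
$(s_j, t_j) \to (s_{j+1}, t_{j+1})$, the factor
$P_{s_j s_{j+1}}(t_{j+1} - t_j)$. Elapsed times use the child's exact
decimal ages at measurement, not nominal wave ages, because measurement ages
vary around the wave means.

**Age heterogeneity.** Transition intensities in childhood are not constant
with age. The base-case analysis therefore splits the panel into
adjacent-wave pairs (ages 3–5, 5–7, 7–11, 11–14, 14–17), assumes time
homogeneity only *within* a pair, fits each pairwise dataset separately, and
links the fits piecewise when projecting. Two deliberately misspecified
comparators are available: fitting one homogeneous generator to all waves
(`scenario1`) and extrapolating the first pair's generator across childhood
(`scenario2`). `compare_scenarios()` scores all three against observed
prevalence by mean absolute error; on age-heterogeneous data the piecewise
model wins, which is exactly the test the validation machinery implements.

**Covariates.** Covariates act proportionally on each intensity,
$$q_{rs}(x) = q_{rs}^{0}\, e^{\beta_{rs}' x},$$
so $e^{\beta_{rs}}$ is a transition-specific hazard ratio relative to the
reference level. This log-linear form is the standard proportional-intensity
model and the only form consistent with reporting per-transition hazard
ratios against a reference category. `fit_msm()` adjusts mutually for all
covariates passed in one call; fitting one covariate at a time gives
univariable ratios, which is the package default in the pipeline because
published per-factor tables are most often univariable.

## Survey weighting and replicate variance

Cohorts with stratified, clustered, unequal-probability designs need two
separate corrections.

*Point estimates* use a design-weighted pseudo-likelihood: each child's whole
log-likelihood contribution is multiplied by its design weight
(`weighted_loglik()`). Constant weights reduce exactly to the unweighted
likelihood; doubling all weights doubles the objective and moves no optimum.

*Variances* must not come from the weighted Hessian, which ignores the
design. The package instead implements the delete-one-cluster (JKn)
jackknife: for a design with $n_h$ clusters in stratum $h$,
`jackknife_replicates()` builds one replicate per cluster in which that
cluster's children get weight zero and their stratum-mates are rescaled by
$n_h/(n_h-1)$. The model is refitted under every replicate weight
(`msm_replicate_fits()`, warm-started from the full-sample optimum, which
changes nothing at convergence but saves most of the run time), and
$$v(\hat\theta) = \sum_h \frac{n_h - 1}{n_h}
  \sum_{j \in h} (\hat\theta_{(hj)} - \hat\theta)^2 .$$

Confidence intervals are symmetric normal intervals on the log scale for
intensities and hazard ratios. Annual probabilities are *recomputed through
the full matrix-exponential pipeline for every replicate* rather than
delta-method propagated; this is the standard use of replication and is why
probability intervals can be asymmetric after clipping to $[0,1]$. When
replicate refits fail to converge they are dropped and the affected stratum
sums rescaled, but only up to 5% of replicates; beyond that the variance
estimator refuses loudly rather than biasing silently. A note on the JKn
weight totals: the $n_h/(n_h-1)$ rescaling preserves stratum weight totals
exactly when cluster totals within a stratum are equal, and in expectation
otherwise.

## Z-scores and state classification

BMI is mapped to an age- and sex-adjusted z-score by the Cole LMS transform,
$z = ((\mathrm{BMI}/M)^L - 1)/(LS)$ (or $\log(\mathrm{BMI}/M)/S$ when
$L=0$), with $L, M, S$ linearly interpolated at the child's exact age within
the reference table. Linear interpolation is immaterial at monthly table
granularity; the exact-age convention of any particular upstream software is
not reproducible and is documented as a stand-in choice. Two classification
schemes are built in: population-monitoring centile cut-offs (2nd / 85th /
95th, boundaries computed from the normal quantile function rather than
hard-coded decimals, boundary inclusion exactly as defined) and the
age-dependent z-score cut-offs used for international monitoring, which
switch rules at 60 months. Records with $|z| > 5$ are flagged implausible —
a common biological-plausibility rule, configurable — and excluded by the
pipeline rather than silently kept.

The package ships a *synthetic* LMS table
(`synthetic_growth_reference()`): smooth parametric curves with the
qualitative shape of a childhood BMI reference. Licensed reference tables
cannot be redistributed; users supply a real table as a CSV
(`sex,age_months,L,M,S`) for real analyses.

## What the synthetic cohort emulates

`simulate_cohort()` is first-class, tested code, not a fixture: it generates
panels with *known ground truth* so that estimation can be checked end to
end. Its defaults describe the study conditions the package targets:

* **10,000 children** observed at waves with mean ages 3, 5, 7, 11, 14 and
  17 years; child-specific measurement ages jittered around the wave mean
  (SD 0.15 years, matching the dispersion of real measurement ages).
* **Band-specific generators**: the default intensities per age band are
  rounded matrix logarithms of the published annual transition matrices
  bundled with the package, so the generator reproduces the empirical age
  gradient (for example $q_{23} \approx 0.040$/year at ages 3–5 falling to
  $0.015$/year at 7–11).
* **Baseline state mix** 0.78 / 72.70 / 15.90 / 10.63 percent — the
  published weighted baseline of the validation cohort.
* **Survey design**: 398 clusters nested in 9 strata, with a disadvantaged
  subgroup (superpopulation prevalence 0.30) sampled at twice the base rate
  and carrying inverse-probability weights; by default the subgroup is also
  more transition-prone (hazard ratio 1.5 on healthy→overweight, 1.3 on
  overweight→obesity), making the oversampling informative, as in real
  cohorts where deprivation predicts both sampling and weight gain.
* **Monotone attrition** at 7% per wave (once gone, gone) and 5% masked
  covariate values, so complete-case exclusion has something to do.

What it does *not* emulate: measurement error and state misclassification,
non-monotone return after dropout (available behind a flag only as absence),
informative (outcome-dependent) attrition, within-band age trends, secular
period effects, and raw anthropometry (paths are simulated at the state
level; the optional BMI back-transform through the synthetic LMS table
exists to exercise the z-score module, not to mimic real BMI
distributions). Passing tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
their violation in real data.

## Numerical choices

* Optimisation is on the unconstrained log-intensity scale, BFGS with
  finite-difference gradients, relative log-likelihood tolerance $10^{-6}$,
  at most 500 iterations, with a Nelder–Mead fallback if BFGS reports
  non-convergence. Starting values are crude count/person-time rates with
  zero-count transitions floored at $10^{-6}$/year to keep the start in the
  interior.
* A likelihood evaluation groups intervals by unique (elapsed time,
  covariate profile) and computes one matrix exponential per group — with
  nominal wave ages this is a handful of exponentials per evaluation
  regardless of cohort size.
* An observed transition with zero probability under the structure returns
  $-\infty$, never an error, so optimisers can back away. Parameter
  excursions extreme enough to break the numerical stochasticity of
  $\exp(Qt)$ are likewise treated as zero-likelihood; this guard matters,
  because without it an optimizer can chase spurious "probabilities" above
  one.
* Non-convergence is a flagged state that downstream reporting functions
  refuse to ignore; covariate levels with no observed transitions are warned
  about by name, and merging levels (`merge_levels()`) is always an explicit
  user action, never automatic.
* Markov traces run one cycle per year with no half-cycle correction (a
  downstream concern for cost-effectiveness use). When a trace horizon
  extends past the last band — e.g. to age 18 while the last fitted band
  ends at 17 — the final band's matrix is carried forward and a message says
  so; this extension is the only reading consistent with a 15-cycle
  projection from age 3. Cohort expansion for validation replicates each
  child `round(factor * w_i / mean(w))` times, rounding half away from
  zero; the published head-counts for this step are not internally
  reconcilable, so the package treats the resulting *distribution*, not the
  total, as the meaningful output.

## Problem sizes used by the test-suite

The package's tests run scaled versions of the analyses: parameter recovery
uses 5,000 children across all six waves with jackknife variance from a
30-cluster design; interval coverage is checked over 200 simulated cohorts
of 800 children; the weighting-bias demonstration uses 20,000 children with
3× informative oversampling; oracle comparisons (power-series matrix
exponential, hand-rolled likelihood products) run on 100 random generators
and tiny panels. These sizes were chosen to make Monte Carlo error small
relative to the effects being demonstrated.

## Known limitations

State misclassification (hidden Markov extensions) is out of scope, as are
time-inhomogeneous intensities *within* a band, exact-transition-time
likelihood contributions, Taylor-linearisation variance, bootstrap/BRR
weights, and imputation of missing covariates (the analysis is
complete-case, with a robustness mode that refits unadjusted models before
exclusion). Estimates from bands with wide wave gaps (7–11) average over
more within-band heterogeneity than narrow bands and should be read
accordingly.
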