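---
title: "Dynamic risk monitoring by landmarking: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic risk monitoring by landmarking: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods implemented in `dynrisk`,
the modelling assumptions behind them, and the reasoning for every
non-obvious design decision. It contains no empirical claims beyond what the
package's test suite computes.

## 1. The landmarking supermodel

### Schedule and windows

A landmark schedule is a grid of follow-up times $s_1 < \dots < s_K$ (default
$0, 30, \dots, 1080$ days: 37 monthly landmarks over three years) with a
fixed prediction window of $w$ days (default 730). At landmark $s$, the
dataset contains every subject still at risk at $s$: no event on or before
$s$, no censoring on or before $s$. An event on the landmark day itself means
the subject is *not* at risk at that landmark. Within-window follow-up is
administratively censored at $s + w$.

### The risk equation

All landmark datasets are stacked and fitted jointly as one stratified Cox
model (`survival::coxph`, Breslow ties), with the landmark as the stratum:
a single log-hazard-ratio vector $\beta$ shared across landmarks and a free
baseline hazard per landmark. The predicted window risk is

$$P\big(\text{event} \in (s, s+w]\,\big|\,\text{at risk at } s\big)
  = 1 - \exp\!\big(-BH_{LM}(s)\, e^{\beta^\top RF}\big),$$

where $BH_{LM}(s)$ is the within-stratum Breslow cumulative baseline hazard
evaluated at $w$, computed from the *uncentred* linear predictor (so the
equation above holds for raw covariate values; predictions are invariant to
recentring, which the tests verify). A stratum with no events yields
$BH_{LM}=0$ with a warning rather than an error.

The joint fit is a working-independence composite likelihood: rows of the
same subject at different landmarks are correlated, so naive model standard
errors understate sampling variability. Point estimates are consistent; the
acceptance test for parameter recovery therefore uses subject-clustered
robust (sandwich) standard errors for its 3-SE check.

### Model variants

* **DLM** — covariates updated to their last observed value at each landmark,
  plus trigger recency flags; per-landmark baseline hazards.
* **FLM** — baseline covariate values at every landmark; per-landmark
  baseline hazards. Isolates the value of covariate updating.
* **FBL** — baseline covariates and the landmark-0 baseline hazard applied
  at every landmark: the behaviour of a conventional static instrument used
  repeatedly. Because it ignores the decline of the baseline hazard with
  offense-free time (*desistance*), it over-predicts at late landmarks;
  this is the central qualitative phenomenon the package reproduces
  (positive calibration-in-the-large for FBL at landmarks $\ge$ 12 months,
  with the DLM's absolute miscalibration strictly smaller).

### Covariate carry-forward and triggers

Covariates follow last-observation-carried-forward between re-measurements
(annual by default); an update is effective on its own day. Sociodemographic
fields additionally keep their baseline value for the first 90 days
(register lag). Trigger events are encoded at landmark $s$ as three nested
indicators — acute $(s-7, s]$, short-term $(s-30, s]$, residual $[0, s]$ —
so acute and short-term act as modifiers on top of the residual effect.

### Censoring inside the window

By default, a row censored strictly inside $(s, s+w)$ is *removed* from that
landmark's dataset rather than kept as a censored observation. Rationale:
with near-complete register follow-up, within-window exits are dominated by
informative reasons (death, emigration, imprisonment), and removal mirrors
the complete-window convention of register studies. This biases the risk
set slightly but keeps the window outcome binary, which is what the
per-landmark AUC/Brier/calibration machinery evaluates.
`retain_censored = TRUE` restores standard landmarking. When a conviction
and a censoring event fall on the same day, the conviction wins. For the
violent outcome, a nonviolent conviction censors the subject at its day
(imprisonment proxy): the subject is typically incarcerated and no longer
observable for violent reoffending in the community.

## 2. The synthetic cohort generator

`simulate_cohort()` draws, per subject, a daily piecewise-constant hazard

$$h(d) = h_0\, e^{-\lambda (d-1)}\, e^{\beta^\top x(d) + \tau(d)},$$

with $x(d)$ the current covariate values (annual re-measurement; `switch`
covariates flip with probability 0.15 per year, `monotone` ones can only
switch on with probability 0.05) and $\tau(d)$ the sum of active trigger
window effects. Event times come from exact inverse-transform sampling of
the piecewise-constant cumulative hazard; competing censoring is exponential
(death, emigration, imprisonment) with end-of-follow-up at
`followup_days + horizon_days`.

Default generator constants and their rationale:

| constant | default | rationale |
|---|---|---|
| `baseline_hazard_day0` | 4e-4 /day | with the default covariate mix, yields a two-year general reconviction rate near 31% and violent near 7%, typical of sentenced cohorts in national register studies |
| `desistance_decay` | 0.001 /day | halves the baseline hazard roughly every two years; makes $\log BH_{LM}(s)$ exactly linear in $s$ with slope $-\lambda$, which the tests exploit |
| `censor_rates` | death 0.016, emigration 0.007, imprisonment 0.029 /yr | plausible register attrition |
| `violent_fraction` | 0.24 | violent subtype drawn as a Bernoulli thinning of general events |
| `missing_fraction` | 0.02 | MCAR masking of sociodemographic fields only; criminal-history and clinical registers are treated as complete |

Two deliberate simplifications:

* **Age is static.** Its within-window drift (at most 3 years) is small
  relative to its between-subject spread (SD 12); modelling it dynamically
  would change LOCF bookkeeping for a negligible effect.
* **Outcomes are observed through `followup_days + horizon_days`**
  (default 1095 + 730 = 1825 days). Landmarks run to day 1080 with 730-day
  windows; if observation stopped at day 1095, the end-of-follow-up censor
  would fall inside almost every late window and (under the removal rule)
  empty the late landmark datasets. Observing through day 1825 makes every
  window fully observable, so an event-free subject contributes all 37 DLM
  rows.

## 3. Missing data

Incomplete sociodemographic fields are imputed by a hand-written
multivariate-normal EM (`em_fit`): pattern-grouped E-step with
conditional-moment corrections, observed-data log-likelihood recorded each
iteration (non-decreasing, which the tests assert), complete-case
initialisation with a ridge fallback. The imputation table stacks baseline
and annual measurement rows with the measurement day as a time index and
includes all covariates plus the event indicator as predictors, so the
imputation model is at least as rich as the analysis model.

`draw_imputations()` draws missing entries from their conditional normal
given the observed entries; variables whose observed values are all 0/1 are
thresholded at 0.5 after the draw, keeping binary columns binary (a
pragmatic alternative to a full latent-threshold model; it preserves
marginal prevalences well at the default missingness levels). Columns that
are constant among observed values cannot inform a normal model and are
imputed with that constant. Estimates are pooled across the $m$ completed
datasets by Rubin's rules: $\bar Q$, $W$, $B$, $T = W + (1+1/m)B$, Wald
$p$-value against the standard normal.

Backward elimination refits the supermodel on every imputed superset at each
step and removes the candidate with the largest Rubin-pooled $p$-value while
it exceeds the threshold. The default threshold is the AIC-equivalence
point: dropping one parameter leaves AIC unchanged when the likelihood-ratio
statistic equals 2, i.e. $p = 1 - \chi^2_1(2) \approx 0.157$. Criminal
history and sociodemographic blocks are forced; clinical extras and trigger
flags are candidates, with each trigger's three time components removed
jointly (max member $p$).

## 4. Validation

* **Harrell's c** over pooled landmark rows (`survival::concordance`,
  reverse scale), i.e. comparable pairs within and across landmarks.
* **Time-varying AUC** per landmark: the window outcome is binary after the
  removal rule, so discrimination at landmark $s$ is a Mann–Whitney AUC.
  The 95% CI uses the DeLong placement variance, or Hanley–McNeil when
  either group has fewer than 10 observations. The implementation is
  hand-coded and cross-checked against `pROC` in the tests.
* **Brier score** and **Brier skill score** against the zero-probability
  naive reference (whose Brier score is the event rate): $BSS = 1 -
  Brier/\bar y$, undefined (NA) with no events.
* **Calibration**: equal-frequency decile tables (stable ties), calibration
  in the large (mean predicted minus observed), least-squares slope of
  observed on predicted across deciles.
* **Optimism correction**: subjects (with all their rows) are resampled with
  replacement; per replicate the model is refitted and evaluated on both the
  bootstrap and original rows; the mean difference is subtracted from the
  apparent c-index (default $B = 200$); the CI is the empirical 2.5–97.5%
  quantile range of the per-replicate corrected values. Failed refits are
  skipped and counted.
* **External validation** uses a region-stratified split: whole regions
  (never individual subjects) are greedily assigned to the validation set,
  one from each region group first, until the target share (default 20%) is
  best approximated. Geographic disjointness gives a stricter test of
  transportability than a random subject split.

## 5. Problem sizes and budget

The unit tests run on cohorts of 20–1,500 subjects (seconds). The acceptance
suite uses two 20,000-subject cohorts (about 1.5 minutes total on one CPU):
one with three static covariates and known effects for parameter recovery
and optimism, one under the full default generator for the desistance-bias
reproduction. `scripts/acceptance.R` runs the complete pipeline on 10,000
subjects in under a minute.

## 6. Limitations

* The generator's hazards are conditionally exponential between daily
  updates; it does not model frailty, seasonality, or dependence between
  trigger processes and covariates.
* Missingness is MCAR by construction, matching the imputation model's
  assumption; the EM machinery itself only requires MAR, but the package
  provides no MNAR sensitivity analysis.
* The supermodel's naive standard errors ignore within-subject correlation
  across landmarks (see §1); use cluster-robust errors for inference on
  $\beta$.
* Binary imputation by thresholding slightly attenuates covariances relative
  to a proper latent-variable draw.
* The removal rule for within-window censoring trades a small risk-set bias
  for binary window outcomes; results under `retain_censored = TRUE` can
  differ at landmarks with heavy within-window attrition.
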