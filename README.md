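# dynrisk

Dynamic landmark risk monitoring with Cox supermodels.

## The problem

Conventional prognostic models for time-to-event outcomes — for example the
risk that a sentenced individual is reconvicted within two years — are
*static*: they take covariates measured at a single baseline (sentencing) and
issue one fixed prediction. Two things make static predictions go stale:

1. **Desistance.** The hazard of reoffending declines as offense-free time
   accumulates. A baseline model keeps predicting with the day-0 hazard, so
   it systematically *over*-predicts risk for people who have already stayed
   event-free for a year or two.
2. **Time-varying risk factors.** Employment, income support, housing and
   relationship status change; psychiatric disorders have onsets; acute
   *trigger* events (psychiatric hospitalization, violent victimization)
   sharply and transiently elevate risk.

`dynrisk` implements dynamic prediction by **landmarking**: at each of a grid
of landmark times (by default every 30 days for 3 years, i.e. 37 landmarks
s = 0, 30, …, 1080), the at-risk set is refreshed, covariates are updated to
their last observed values, trigger recency is re-encoded, and a fresh
prediction is issued for the window (s, s + 730] days.

## The model

All landmark datasets are stacked into one **landmark superset** and fitted
jointly as a stratified Cox proportional-hazards model: a single coefficient
vector β shared across landmarks, with a **free Breslow baseline hazard per
landmark** (landmark = stratum, Breslow tie handling). The predicted
probability of an event within the window opening at landmark s, for risk
factor vector RF, is

    P(event in (s, s + w] | at risk at s) = 1 − exp( −BH_LM(s) · exp(Σ β·RF) )

where `BH_LM(s)` is the landmark-specific cumulative baseline hazard at the
window width w. The decline of `BH_LM(s)` with s is what captures
desistance.

Three variants are distinguished:

| variant | covariates | baseline hazard |
|---|---|---|
| **DLM** (dynamic landmark model) | updated at each landmark + trigger flags | per landmark |
| **FLM** (fixed-covariate landmark model) | frozen at baseline | per landmark |
| **FBL** (fixed baseline model) | frozen at baseline | landmark 0 only (a static model applied repeatedly) |

Trigger events are encoded at each landmark s as three nested indicators:
**acute** (occurred in (s−7, s]), **short-term** ((s−30, s]) and **residual**
(ever in [0, s]).

Rows censored *inside* a prediction window are removed from that landmark's
dataset by default (administrative censoring at the horizon still applies);
`retain_censored = TRUE` restores standard censored rows instead. For the
violent-reoffending outcome, a nonviolent conviction censors the subject at
its day (imprisonment proxy).

The package also provides:

- a **synthetic cohort generator** (daily piecewise-constant hazards with
  exponential desistance decay, annual covariate re-measurement, trigger
  processes, competing censoring, MCAR masking of sociodemographic fields);
- **EM multiple imputation** of incomplete covariates with **Rubin's rules**
  pooling and **backward elimination** at the AIC-equivalent p-threshold
  `1 − pchisq(2, 1) ≈ 0.157`;
- **dynamic validation**: Harrell's c, per-landmark time-varying AUC with
  DeLong/Hanley–McNeil CIs, Brier and Brier skill scores, decile calibration,
  calibration-in-the-large, threshold classification tables, bootstrap
  **optimism correction**, and side-by-side DLM/FLM/FBL comparison;
- a **region-stratified derivation/validation split** and a four-command
  pipeline (`cmd_simulate`, `cmd_fit`, `cmd_validate`, `cmd_predict`) with a
  thin command-line wrapper.

## Worked example

```r
library(dynrisk)

# 1. Simulate a sentenced cohort observed for 3 years with annual
#    re-measurement, acute triggers and declining baseline risk
cfg <- sim_config(n_subjects = 3000, seed = 7)
cohort <- simulate_cohort(cfg)
#> Cohort: 3000 subjects, 45000 covariate updates, 1003 trigger events
#>   events: 1213 (40.4%), of which violent: 296

# 2. Build the landmark superset: 37 monthly landmarks, 2-year windows
sched <- landmark_schedule()
superset <- stack_superset(cohort, sched, outcome_type = "general",
                           variant = "DLM")
nrow(superset)        #> 73252
sum(superset$status)  #> 15510

# 3. Fit the stratified Cox supermodel
fit <- fit_cox_supermodel(superset)
round(fit$bh[c("0", "360", "720", "1080")], 3)
#>     0   360   720  1080
#> 0.192 0.132 0.097 0.069     <- desistance: the baseline hazard declines

# 4. Predict a 2-year risk trajectory for one profile
rf <- c(sex_male = 1, age = 28, prior_criminal_history = 1,
        prior_violent_conviction = 0, prior_prison = 0, employed = 0,
        income_support = 1, single = 1, any_psychiatric_disorder = 1,
        substance_use_disorder = 1, unstable_housing = 0,
        self_harm_history = 0,
        psychiatric_hospitalization_acute = 0,
        psychiatric_hospitalization_short = 0,
        psychiatric_hospitalization_residual = 0,
        violent_victimization_acute = 0,
        violent_victimization_short = 0,
        violent_victimization_residual = 0)
predict_risk(fit, rf, landmark_day = 0)$probability    #> 0.574
predict_risk(fit, rf, landmark_day = 360)$probability  #> 0.444
# same person 12 months in, the week after a psychiatric hospitalization:
rf[c("psychiatric_hospitalization_acute",
     "psychiatric_hospitalization_short",
     "psychiatric_hospitalization_residual")] <- 1
predict_risk(fit, rf, landmark_day = 360)$probability  #> 0.478

# 5. Validate dynamically
rep <- validate_fit(fit, superset)
#> Validation report (DLM, general outcome, internal sample)
#>   pooled c-index: 0.665; mean AUC over 37 landmarks: 0.660
subset(rep$per_landmark, landmark %in% c(0, 360, 720))
#>    landmark    n events   auc brier   bss calibration_in_large
#> 1         0 2744    842 0.674 0.195 0.363          0.00056
#> 13      360 2121    476 0.643 0.166 0.259         -0.00086
#> 25      720 1744    301 0.650 0.137 0.206         -0.00034
```

The full pipeline (simulate → split by region → impute → eliminate → fit all
three variants → validate) is driven by a run configuration:

```r
cfg <- run_config(run_dir = "run1", n_subjects = 5000, seed = 1)
cmd_simulate(cfg); cmd_fit(cfg); cmd_validate(cfg)
```

or from the shell via the bundled script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dynrisk.R", package = "dynrisk"))') \
    simulate --config run.yaml --run-dir run1 --seed 1
```

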