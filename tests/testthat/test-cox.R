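# A bare superset: plain data.frame with the columns the fitter needs.
bare_superset <- function(time, status, x, landmark) {
  data.frame(subject_id = seq_along(time), landmark = landmark,
             x = x, time = time, status = status)
}

test_that("the stratified partial-likelihood maximiser matches a grid-search oracle", {
  ss <- bare_superset(
    time = c(3, 7, 11, 15, 2, 6, 10, 14),
    status = c(1, 0, 1, 0, 1, 1, 0, 1),
    x = c(1, 0, 1, 0, 0, 1, 1, 0),
    landmark = rep(c(0, 30), each = 4))
  fit <- fit_cox_supermodel(ss, covariates = "x")
  beta_grid <- grid_max_1cov(ss$time, ss$status, ss$x, ss$landmark)
  expect_lt(abs(fit$coef[["x"]] - beta_grid), 1e-3)
  # and on a simulated single-covariate cohort
  cfg <- sim_config(n_subjects = 60, covariates = make_cov_spec("x", beta = 0.5),
                    triggers = default_triggers()[0, ], seed = 14)
  ch <- simulate_cohort(cfg)
  ss2 <- stack_superset(ch, landmark_schedule(c(0L, 180L)), "general", "DLM")
  fit2 <- fit_cox_supermodel(ss2)
  beta2 <- grid_max_1cov(ss2$time, ss2$status, ss2$x, ss2$landmark)
  expect_lt(abs(fit2$coef[["x"]] - beta2), 1e-3)
})

test_that("the Breslow estimator reproduces hand-computed step functions", {
  # unit risk scores: increment = events / number still at risk
  b <- compute_breslow(time = c(1, 2, 3, 4, 5),
                       status = c(1, 0, 1, 1, 0),
                       risk = rep(1, 5), stratum = rep(0, 5))[["0"]]
  expect_equal(b$time, c(1, 3, 4))
  expect_equal(b$hazard, c(1 / 5, 1 / 5 + 1 / 3, 1 / 5 + 1 / 3 + 1 / 2),
               tolerance = 1e-12)
  # unequal risk scores, tied event times share one at-risk set
  b2 <- compute_breslow(time = c(2, 2, 5), status = c(1, 1, 1),
                        risk = c(1, 2, 4), stratum = rep(0, 3))[["0"]]
  expect_equal(b2$time, c(2, 5))
  expect_equal(b2$hazard, c(2 / 7, 2 / 7 + 1 / 4), tolerance = 1e-12)
  # strata are independent
  b3 <- compute_breslow(time = c(1, 1), status = c(1, 1), risk = c(1, 1),
                        stratum = c(0, 30))
  expect_equal(b3[["0"]]$hazard, 1)
  expect_equal(b3[["30"]]$hazard, 1)
})

test_that("the Breslow baseline agrees with survival::basehaz on a real fit", {
  cfg <- sim_config(n_subjects = 300,
                    covariates = make_cov_spec(c("x1", "x2"),
                                               beta = c(0.6, -0.4)),
                    triggers = default_triggers()[0, ], seed = 15)
  ch <- simulate_cohort(cfg)
  ss <- stack_superset(ch, landmark_schedule(0L), "general", "DLM")
  fit <- fit_cox_supermodel(ss)
  cox <- survival::coxph(survival::Surv(time, status) ~ x1 + x2,
                         data = as.data.frame(ss), ties = "breslow")
  bh_ref <- survival::basehaz(cox, centered = FALSE)
  b <- fit$basehaz[["0"]]
  ref_at <- approx(bh_ref$time, bh_ref$hazard, xout = b$time,
                   method = "constant", rule = 2)$y
  expect_equal(b$hazard, ref_at, tolerance = 1e-6)
  # horizon value matches the step function evaluated at 730
  expect_equal(fit$bh[["0"]], breslow_baseline(fit, 0, 730),
               tolerance = 1e-12)
})

test_that("baseline lookup is a right-continuous step function that is 0 before the first event", {
  fit <- list(basehaz = list("0" = data.frame(time = c(10, 20),
                                              hazard = c(0.1, 0.25))))
  class(fit) <- "cox_supermodel"
  expect_equal(breslow_baseline(fit, 0, 5), 0)
  expect_equal(breslow_baseline(fit, 0, 10), 0.1)
  expect_equal(breslow_baseline(fit, 0, 15), 0.1)
  expect_equal(breslow_baseline(fit, 0, 20), 0.25)
  expect_equal(breslow_baseline(fit, 0, 1000), 0.25)
  expect_error(breslow_baseline(fit, 99, 5), "unknown stratum")
})

test_that("risk prediction follows the closed-form equation", {
  fit <- structure(list(variant = "DLM", outcome_type = "general",
                        covariates = "x", coef = c(x = log(2)),
                        bh = c("0" = 0.1, "30" = 0.05), horizon = 730),
                   class = "cox_supermodel")
  # x = 0: P = 1 - exp(-0.1)
  p0 <- predict_risk(fit, c(x = 0), 0)
  expect_equal(p0$probability, 1 - exp(-0.1), tolerance = 1e-12)
  # x = 1: doubled hazard
  p1 <- predict_risk(fit, c(x = 1), 0)
  expect_equal(p1$probability, 1 - exp(-0.2), tolerance = 1e-12)
  # later landmark uses its own baseline
  p30 <- predict_risk(fit, c(x = 1), 30)
  expect_equal(p30$probability, 1 - exp(-0.1), tolerance = 1e-12)
  expect_error(predict_risk(fit, c(x = 1), 60), "unknown landmark")
  expect_error(predict_risk(fit, c(y = 1), 0), "missing covariate")
  # an FBL model always uses the landmark-0 baseline
  fbl <- fit
  fbl$variant <- "FBL"
  fbl$bh <- c("0" = 0.1)
  expect_equal(predict_risk(fbl, c(x = 0), 300)$probability,
               1 - exp(-0.1), tolerance = 1e-12)
})

test_that("recentring a covariate leaves coefficients and predicted risks unchanged", {
  cfg <- sim_config(n_subjects = 200,
                    covariates = make_cov_spec("x", beta = 0.5),
                    triggers = default_triggers()[0, ], seed = 16)
  ch <- simulate_cohort(cfg)
  ss <- stack_superset(ch, landmark_schedule(c(0L, 180L)), "general", "DLM")
  fit <- fit_cox_supermodel(ss)
  ss_shift <- ss
  ss_shift$x <- ss$x + 5
  fit_shift <- fit_cox_supermodel(ss_shift)
  expect_equal(fit_shift$coef, fit$coef, tolerance = 1e-6)
  p <- predict_superset(fit, ss)
  p_shift <- predict_superset(fit_shift, ss_shift)
  expect_equal(p_shift$probability, p$probability, tolerance = 1e-6)
})

test_that("FLM equals DLM when nothing varies over time; FBL has one baseline", {
  cfg <- sim_config(n_subjects = 400,
                    covariates = make_cov_spec(c("x1", "x2"),
                                               beta = c(0.5, -0.3)),
                    triggers = default_triggers()[0, ], seed = 17)
  ch <- simulate_cohort(cfg)
  sched <- landmark_schedule(seq(0L, 180L, 90L))
  fit_dlm <- fit_cox_supermodel(stack_superset(ch, sched, "general", "DLM"))
  fit_flm <- fit_cox_supermodel(stack_superset(ch, sched, "general", "FLM"))
  expect_equal(fit_dlm$coef, fit_flm$coef, tolerance = 1e-10)
  expect_equal(fit_dlm$bh, fit_flm$bh, tolerance = 1e-10)
  fit_fbl <- fit_cox_supermodel(stack_superset(ch, sched, "general", "FBL"))
  expect_equal(names(fit_fbl$bh), "0")
})

test_that("degenerate designs are rejected and empty strata warned about", {
  ss <- bare_superset(time = c(3, 7, 11, 15), status = c(1, 0, 1, 0),
                      x = c(1, 1, 1, 1), landmark = 0)
  expect_error(fit_cox_supermodel(ss, covariates = "x"), "degenerate")
  ss2 <- bare_superset(time = 1:4, status = rep(0L, 4),
                       x = c(0, 1, 0, 1), landmark = 0)
  expect_error(fit_cox_supermodel(ss2, covariates = "x"), "no events")
  expect_error(fit_cox_supermodel(ss2, covariates = "zz"),
               "not in superset")
  # one stratum has events, the other none: fit succeeds with a warning
  ss3 <- bare_superset(time = c(3, 7, 11, 15, 4, 8),
                       status = c(1, 0, 1, 0, 0, 0),
                       x = c(1, 0, 0, 1, 1, 0),
                       landmark = c(0, 0, 0, 0, 30, 30))
  expect_warning(fit3 <- fit_cox_supermodel(ss3, covariates = "x"),
                 "BH set to 0")
  expect_equal(fit3$bh[["30"]], 0)
})

test_that("variant fitting pools coefficients and averages baselines across imputations", {
  cfg <- sim_config(n_subjects = 300,
                    covariates = make_cov_spec(c("x1", "x2"),
                                               beta = c(0.5, 0)),
                    triggers = default_triggers()[0, ], seed = 18)
  ch <- simulate_cohort(cfg)
  sched <- landmark_schedule(c(0L, 90L))
  # identical copies: pooled coefficients equal the single fit, B = 0
  fv <- fit_variant(list(ch, ch), sched, "general", "DLM")
  single <- fit_cox_supermodel(stack_superset(ch, sched, "general", "DLM"))
  expect_equal(fv$fit$coef, single$coef, tolerance = 1e-12)
  expect_equal(fv$fit$bh, single$bh, tolerance = 1e-12)
  expect_equal(fv$pooled$between, c(0, 0), tolerance = 1e-12)
  # genuinely different imputations: pooled values are the Rubin combination
  ch2 <- simulate_cohort(sim_config(n_subjects = 300,
                                    covariates = make_cov_spec(
                                      c("x1", "x2"), beta = c(0.5, 0)),
                                    triggers = default_triggers()[0, ],
                                    seed = 19))
  ch2$subjects$outcome_day <- ch$subjects$outcome_day
  ch2$subjects$outcome_type <- ch$subjects$outcome_type
  ch2$subjects$censor_day <- ch$subjects$censor_day
  ch2$subjects$censor_reason <- ch$subjects$censor_reason
  fv2 <- fit_variant(list(ch, ch2), sched, "general", "DLM")
  f1 <- fv2$fits[[1]]; f2 <- fv2$fits[[2]]
  expect_equal(fv2$fit$coef[["x1"]],
               mean(c(f1$coef[["x1"]], f2$coef[["x1"]])), tolerance = 1e-12)
  pr <- pool_rubin(c(f1$coef[["x1"]], f2$coef[["x1"]]),
                   c(f1$vcov["x1", "x1"], f2$vcov["x1", "x1"]))
  expect_equal(fv2$pooled$se[fv2$pooled$term == "x1"], pr$se,
               tolerance = 1e-12)
  expect_equal(fv2$fit$bh, (f1$bh + f2$bh) / 2, tolerance = 1e-12)
})

test_that("supermodel JSON round-trip reproduces predictions exactly", {
  cfg <- sim_config(n_subjects = 250, triggers = default_triggers()[0, ],
                    seed = 20)
  ch <- simulate_cohort(cfg)
  sched <- landmark_schedule(seq(0L, 180L, 90L))
  ss <- stack_superset(ch, sched, "general", "DLM")
  fit <- fit_cox_supermodel(ss)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_supermodel(fit, path)
  back <- read_supermodel(path)
  expect_equal(back$coef, fit$coef, tolerance = 1e-14)
  expect_equal(back$bh, fit$bh, tolerance = 1e-14)
  p1 <- predict_superset(fit, ss)
  p2 <- predict_superset(back, ss)
  expect_equal(p2$probability, p1$probability, tolerance = 1e-14)
})
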