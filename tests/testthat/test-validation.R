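test_that("concordance matches hand fixtures and exhaustive pair counting", {
  # perfect ranking
  expect_equal(concordance_index(c(0.9, 0.5, 0.1), c(1, 2, 3), c(1, 1, 1)),
               1, tolerance = 1e-12)
  # fully reversed
  expect_equal(concordance_index(c(0.1, 0.5, 0.9), c(1, 2, 3), c(1, 1, 1)),
               0, tolerance = 1e-12)
  # one tied prediction pair counts half
  expect_equal(concordance_index(c(0.5, 0.5), c(1, 2), c(1, 1)), 0.5,
               tolerance = 1e-12)
  # censored rows only contribute as later controls
  expect_equal(concordance_index(c(0.8, 0.2), c(5, 9), c(1, 0)), 1,
               tolerance = 1e-12)
  expect_error(concordance_index(c(0.1, 0.9), c(1, 2), c(0, 0)),
               "no comparable pairs")
  # brute-force agreement on random data with distinct times
  set.seed(41)
  n <- 40
  pred <- round(runif(n), 2)  # prediction ties allowed
  time <- sample(seq_len(1000), n)  # distinct times
  status <- rbinom(n, 1, 0.6)
  expect_equal(concordance_index(pred, time, status),
               brute_cindex(pred, time, status), tolerance = 1e-12)
})

test_that("AUC matches hand counts, brute force and pROC", {
  # single case above both controls
  expect_equal(auc_binary(c(0.8, 0.5, 0.2), c(1, 0, 0))$auc, 1)
  # add a case between the controls: 3 of 4 pairs concordant
  expect_equal(auc_binary(c(0.8, 0.3, 0.5, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  # all scores tied
  expect_equal(auc_binary(rep(0.4, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(auc_binary(1:3, c(1, 1, 1)), "at least one case")
  set.seed(42)
  n <- 60
  scores <- round(runif(n), 2)
  labels <- rbinom(n, 1, 0.4)
  res <- auc_binary(scores, labels)
  expect_equal(res$auc, brute_auc(scores, labels), tolerance = 1e-12)
  expect_equal(res$method, "delong")
  # cross-check value and DeLong variance against pROC
  roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(res$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(res$se^2, as.numeric(pROC::var(roc)), tolerance = 1e-10)
  # small groups switch to the Hanley-McNeil approximation
  expect_equal(auc_binary(c(0.8, 0.5, 0.2), c(1, 0, 0))$method,
               "hanley-mcneil")
  # permuted labels: AUC near 0.5
  set.seed(43)
  big <- auc_binary(runif(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(big$auc - 0.5), 3 * big$se)
})

test_that("Brier and skill scores satisfy their algebraic identities", {
  y <- c(1, 0, 0, 1, 0, 0, 0, 1)
  # perfect forecast
  expect_equal(brier_bss(y, y)$brier, 0)
  expect_equal(brier_bss(y, y)$bss, 1)
  # constant base-rate forecast: Brier = ybar(1 - ybar), BSS = ybar
  ybar <- mean(y)
  bb <- brier_bss(rep(ybar, length(y)), y)
  expect_equal(bb$brier, ybar * (1 - ybar), tolerance = 1e-12)
  expect_equal(bb$bss, ybar, tolerance = 1e-12)
  # the zero forecast is the naive reference itself: BSS = 0
  bb0 <- brier_bss(rep(0, length(y)), y)
  expect_equal(bb0$brier, bb0$brier_naive, tolerance = 1e-12)
  expect_equal(bb0$bss, 0, tolerance = 1e-12)
  # no events: skill undefined
  expect_true(is.na(brier_bss(c(0.2, 0.3), c(0, 0))$bss))
})

test_that("calibration bins partition the rows and reproduce hand arithmetic", {
  set.seed(44)
  pred <- round(runif(20), 3)
  y <- rbinom(20, 1, pred)
  cal <- calibration_table(pred, y, n_bins = 4)
  tab <- cal$table
  expect_equal(tab$n, rep(5L, 4))
  expect_equal(sum(tab$n), 20L)
  # recount each bin by sorting
  ord <- order(pred)
  for (b in 1:4) {
    rows <- ord[((b - 1) * 5 + 1):(b * 5)]
    expect_equal(tab$mean_predicted[b], mean(pred[rows]), tolerance = 1e-12)
    expect_equal(tab$observed[b], mean(y[rows]), tolerance = 1e-12)
  }
  expect_equal(cal$calibration_in_large, mean(pred) - mean(y),
               tolerance = 1e-12)
  fit_ls <- lm(observed ~ mean_predicted, data = tab)
  expect_equal(cal$slope, unname(coef(fit_ls)[2]), tolerance = 1e-12)
  # uneven split: sizes differ by at most one
  cal7 <- calibration_table(pred, y, n_bins = 7)
  expect_equal(sum(cal7$table$n), 20L)
  expect_lte(diff(range(cal7$table$n)), 1L)
  # degenerate constant predictions collapse to one bin with a warning
  expect_warning(cal1 <- calibration_table(rep(0.3, 15), rbinom(15, 1, 0.3)),
                 "single bin")
  expect_equal(nrow(cal1$table), 1L)
  expect_true(is.na(cal1$slope))
  expect_error(calibration_table(pred[1:5], y[1:5], n_bins = 10),
               "fewer rows than bins")
})

test_that("threshold metrics agree with a confusion-matrix recount", {
  pred <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(0, 0, 1, 1)
  tt <- threshold_table(pred, y, thresholds = c(0.05, 0.3, 0.5, 0.95))
  # threshold below every prediction: everything positive
  expect_equal(tt$sensitivity[1], 1)
  expect_equal(tt$specificity[1], 0)
  # 0.3: positives are 0.4/0.6/0.9 -> tp=2 fp=1 tn=1 fn=0
  expect_equal(tt$sensitivity[2], 1)
  expect_equal(tt$specificity[2], 0.5)
  expect_equal(tt$ppv[2], 2 / 3, tolerance = 1e-12)
  expect_equal(tt$npv[2], 1)
  # 0.5: perfect split
  expect_equal(tt$sensitivity[3], 1)
  expect_equal(tt$specificity[3], 1)
  # threshold above every prediction: nothing positive
  expect_equal(tt$sensitivity[4], 0)
  expect_equal(tt$specificity[4], 1)
  expect_true(is.na(tt$ppv[4]))
  expect_error(threshold_table(pred, c(1, 1, 1, 1)), "both events")
})

test_that("metrics are invariant to row order", {
  set.seed(45)
  n <- 100
  pred <- runif(n)
  time <- sample.int(5000, n)
  status <- rbinom(n, 1, 0.5)
  perm <- sample.int(n)
  expect_equal(concordance_index(pred, time, status),
               concordance_index(pred[perm], time[perm], status[perm]),
               tolerance = 1e-12)
  expect_equal(auc_binary(pred, status)$auc,
               auc_binary(pred[perm], status[perm])$auc, tolerance = 1e-12)
  expect_equal(brier_bss(pred, status)$brier,
               brier_bss(pred[perm], status[perm])$brier, tolerance = 1e-12)
})

test_that("bootstrap optimism correction is deterministic and self-consistent", {
  cfg <- sim_config(n_subjects = 250,
                    covariates = make_cov_spec(c("x1", "x2"),
                                               beta = c(0.6, 0)),
                    triggers = default_triggers()[0, ], seed = 46)
  ch <- simulate_cohort(cfg)
  ss <- stack_superset(ch, landmark_schedule(c(0L, 90L)), "general", "DLM")
  oc1 <- optimism_corrected_cindex(fit_cox_supermodel, ss, B = 20, seed = 5)
  oc2 <- optimism_corrected_cindex(fit_cox_supermodel, ss, B = 20, seed = 5)
  expect_identical(oc1, oc2)
  expect_equal(oc1$corrected, oc1$apparent - oc1$optimism, tolerance = 1e-12)
  expect_equal(oc1$apparent, concordance_index(
    predict_superset(fit_cox_supermodel(ss), ss)$probability,
    ss$time, ss$status), tolerance = 1e-12)
  expect_lte(oc1$ci[1], oc1$ci[2])
  expect_equal(oc1$B + oc1$failures, 20L)
  expect_error(optimism_corrected_cindex(fit_cox_supermodel, ss, B = 1),
               "at least 2")
})

test_that("the validation report assembles per-landmark metrics consistently", {
  cfg <- sim_config(n_subjects = 500, triggers = default_triggers()[0, ],
                    seed = 47)
  ch <- simulate_cohort(cfg)
  sched <- landmark_schedule(seq(0L, 360L, 180L))
  ss <- stack_superset(ch, sched, "general", "DLM")
  fit <- fit_cox_supermodel(ss)
  rep1 <- validate_fit(fit, ss, sample_tag = "internal")
  expect_s3_class(rep1, "validation_report")
  expect_equal(rep1$per_landmark$landmark, c(0, 180, 360))
  expect_equal(sum(rep1$per_landmark$n), nrow(ss))
  # per-landmark AUC recomputed directly
  a0 <- time_varying_auc(fit, ss, 0)
  expect_equal(rep1$per_landmark$auc[1], a0$auc, tolerance = 1e-12)
  b0 <- brier_and_bss(fit, ss, 0)
  expect_equal(rep1$per_landmark$brier[1], b0$brier, tolerance = 1e-12)
  expect_equal(rep1$cindex, concordance_index(
    predict_superset(fit, ss)$probability, ss$time, ss$status),
    tolerance = 1e-12)
  # persisted outputs
  d <- withr::local_tempdir()
  write_validation_report(rep1, file.path(d, "r.json"),
                          file.path(d, "r.csv"))
  js <- jsonlite::read_json(file.path(d, "r.json"), simplifyVector = TRUE)
  expect_equal(js$cindex, rep1$cindex, tolerance = 1e-12)
  csv <- read.csv(file.path(d, "r.csv"))
  expect_setequal(unique(csv$landmark), c(0, 180, 360))
  expect_true(all(c("auc", "brier", "bss") %in% csv$metric))
})

test_that("the three variants are compared on matched validation rows", {
  cfg <- sim_config(n_subjects = 600, seed = 48)
  ch <- simulate_cohort(cfg)
  sp <- split_by_region(ch, 0.25, seed = 2)
  sched <- landmark_schedule(seq(0L, 360L, 180L))
  covs <- cfg$covariates$name
  fits <- list(
    DLM = fit_variant(sp$derivation, sched, "general", "DLM",
                      covariates = covs)$fit,
    FLM = fit_variant(sp$derivation, sched, "general", "FLM",
                      covariates = covs)$fit,
    FBL = fit_variant(sp$derivation, sched, "general", "FBL",
                      covariates = covs)$fit)
  cmp <- compare_models(fits, sp$validation, sched, "general")
  expect_setequal(cmp$summary$variant, c("DLM", "FLM", "FBL"))
  expect_equal(nrow(cmp$per_landmark), 3L * 3L)
  # FLM and FBL are evaluated on identical rows: same n and events
  pf <- cmp$per_landmark
  expect_equal(pf$n[pf$variant == "FLM"], pf$n[pf$variant == "FBL"])
  expect_equal(pf$events[pf$variant == "FLM"],
               pf$events[pf$variant == "FBL"])
  bad <- fits
  bad$DLM$outcome_type <- "violent"
  expect_error(compare_models(bad, sp$validation, sched, "general"),
               "different outcome")
})
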