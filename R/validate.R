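#' Harrell's concordance index over landmark rows
#'
#' Among comparable pairs (the row with the shorter \code{time} experienced
#' the event), the fraction where the higher predicted risk belongs to the
#' earlier event; prediction ties count 0.5. Pairs of window survivors are
#' not comparable.
#'
#' @param pred predicted risk (higher = riskier).
#' @param time time in window.
#' @param status 1 event, 0 window survivor / censored.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(pred, time, status) {
  cf <- survival::concordance(survival::Surv(time, status) ~ pred,
                              reverse = TRUE)
  comparable <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (comparable == 0) stop("no comparable pairs")
  unname(cf$concordance)
}

#' Binary AUC with confidence interval
#'
#' Mann-Whitney AUC of scores for cases versus controls. The 95\% CI uses
#' the DeLong placement variance, or the Hanley-McNeil approximation when
#' either group has fewer than 10 observations.
#'
#' @param scores numeric predictions.
#' @param labels logical or 0/1; TRUE/1 = case.
#' @return list: auc, se, ci (length 2), method.
#' @export
auc_binary <- function(scores, labels) {
  y <- as.logical(labels)
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  if (m == 0L || n == 0L) stop("need at least one case and one control")
  r_all <- rank(c(x, z))
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  if (min(m, n) >= 10L) {
    v10 <- (r_all[seq_len(m)] - rank(x)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(z)) / m
    va <- stats::var(v10) / m + stats::var(v01) / n
    method <- "delong"
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    va <- (auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
             (n - 1) * (q2 - auc^2)) / (m * n)
    method <- "hanley-mcneil"
  }
  se <- sqrt(max(va, 0))
  list(auc = auc, se = se,
       ci = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
       method = method)
}

#' Time-varying AUC at a landmark
#'
#' Binary discrimination at landmark \code{s}: cases are rows with an event
#' inside the prediction window, controls are window survivors.
#'
#' @param fit a fitted supermodel.
#' @param superset evaluation rows.
#' @param s landmark day.
#' @return list as in [auc_binary()].
#' @export
time_varying_auc <- function(fit, superset, s) {
  df <- as.data.frame(superset)
  sel <- df$landmark == s
  if (!any(sel)) stop("no rows at landmark ", s)
  p <- predict_superset(fit, superset[sel, , drop = FALSE])$probability
  y <- df$status[sel] == 1L
  if (all(y) || !any(y)) stop("degenerate class at landmark ", s)
  auc_binary(p, y)
}

#' Brier score and Brier skill score
#'
#' Brier score is the mean squared error of the predicted probability against
#' the binary window outcome. The skill score is computed against a naive
#' reference that assigns zero event probability to everyone, whose Brier
#' score equals the event proportion: \eqn{BSS = 1 - Brier / Brier_{naive}}.
#' With no events the reference score is 0 and the BSS is undefined
#' (\code{NA}).
#'
#' @param pred predicted probabilities.
#' @param y binary outcomes.
#' @return list: brier, brier_naive, bss.
#' @export
brier_bss <- function(pred, y) {
  brier <- mean((pred - y)^2)
  naive <- mean(y)
  list(brier = brier, brier_naive = naive,
       bss = if (naive > 0) 1 - brier / naive else NA_real_)
}

#' @rdname brier_bss
#' @param fit a fitted supermodel.
#' @param superset evaluation rows.
#' @param s landmark day.
#' @export
brier_and_bss <- function(fit, superset, s) {
  df <- as.data.frame(superset)
  sel <- df$landmark == s
  if (!any(sel)) stop("no rows at landmark ", s)
  p <- predict_superset(fit, superset[sel, , drop = FALSE])$probability
  brier_bss(p, df$status[sel])
}

#' Decile calibration table
#'
#' Rows are split into \code{n_bins} equal-frequency groups of predicted
#' probability (group sizes differ by at most 1; ties are broken by stable
#' row order). Reports per group the mean predicted probability, the
#' observed event proportion and the count, plus calibration-in-the-large
#' (mean predicted minus observed event rate) and the least-squares slope of
#' observed on predicted across the group points.
#'
#' @param pred predicted probabilities.
#' @param y binary outcomes.
#' @param n_bins number of groups (default 10, i.e. deciles).
#' @return list: table (data.frame bin / n / mean_predicted / observed),
#'   calibration_in_large, slope.
#' @export
calibration_table <- function(pred, y, n_bins = 10L) {
  n <- length(pred)
  if (n < n_bins) stop("fewer rows than bins")
  if (length(unique(pred)) == 1L) {
    warning("all predictions identical; returning a single bin")
    tab <- data.frame(bin = 1L, n = n, mean_predicted = pred[1L],
                      observed = mean(y))
  } else {
    ord <- order(pred)  # stable: ties keep row order
    sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
    bin <- integer(n)
    bin[ord] <- rep(seq_len(n_bins), sizes)
    tab <- data.frame(
      bin = seq_len(n_bins),
      n = as.integer(tapply(y, bin, length)),
      mean_predicted = as.numeric(tapply(pred, bin, mean)),
      observed = as.numeric(tapply(y, bin, mean)))
  }
  slope <- if (nrow(tab) > 1L)
    unname(stats::coef(stats::lm(observed ~ mean_predicted, data = tab))[2L])
  else NA_real_
  list(table = tab,
       calibration_in_large = mean(pred) - mean(y),
       slope = slope)
}

#' @rdname calibration_table
#' @param fit a fitted supermodel.
#' @param superset evaluation rows.
#' @param s landmark day.
#' @export
calibration_deciles <- function(fit, superset, s, n_bins = 10L) {
  df <- as.data.frame(superset)
  sel <- df$landmark == s
  if (sum(sel) < n_bins) stop("fewer rows than bins at landmark ", s)
  p <- predict_superset(fit, superset[sel, , drop = FALSE])$probability
  calibration_table(p, df$status[sel], n_bins)
}

#' Threshold classification metrics
#'
#' Classifies \code{P >= threshold} as positive over the pooled landmark rows
#' and reports sensitivity, specificity, PPV and NPV per threshold.
#'
#' @param fit a fitted supermodel.
#' @param superset evaluation rows.
#' @param thresholds probability thresholds in (0, 1).
#' @return data.frame: threshold, sensitivity, specificity, ppv, npv.
#' @export
threshold_metrics <- function(fit, superset,
                              thresholds = seq(0.1, 0.9, by = 0.1)) {
  df <- as.data.frame(superset)
  p <- predict_superset(fit, superset)$probability
  threshold_table(p, df$status, thresholds)
}

#' @rdname threshold_metrics
#' @param pred predicted probabilities.
#' @param y binary outcomes.
#' @export
threshold_table <- function(pred, y, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (all(y == 1) || all(y == 0)) stop("need both events and non-events")
  do.call(rbind, lapply(thresholds, function(thr) {
    pos <- pred >= thr
    tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
    fp <- sum(pos & y == 0); tn <- sum(!pos & y == 0)
    data.frame(threshold = thr,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }))
}

# Subset a superset's rows, keeping its construction attributes.
subset_superset <- function(superset, rows) {
  out <- as.data.frame(superset)[rows, , drop = FALSE]
  rownames(out) <- NULL
  meta <- superset_meta(superset)
  structure(out, class = c("landmark_superset", "data.frame"),
            variant = meta$variant, outcome_type = meta$outcome_type,
            schedule = meta$schedule, retain_censored = meta$retain_censored,
            covariate_names = meta$covariate_names)
}

#' Bootstrap optimism-corrected c-index
#'
#' Harrell's bias correction: subjects (with all their landmark rows) are
#' resampled with replacement; per replicate the model is refitted on the
#' bootstrap superset and its concordance evaluated both on the bootstrap
#' rows and on the original rows; the mean difference (optimism) is
#' subtracted from the apparent concordance. The 95\% CI comes from the
#' empirical quantiles of the per-replicate corrected values. Replicates
#' where the refit fails are skipped and counted.
#'
#' @param fit_fun deterministic function: superset -> fitted supermodel.
#' @param superset derivation superset.
#' @param B number of bootstrap replicates (at least 2).
#' @param seed RNG seed; identical seed gives identical output.
#' @return list: apparent, optimism, corrected, ci, B, failures.
#' @export
optimism_corrected_cindex <- function(fit_fun, superset, B = 200L,
                                      seed = 1L) {
  if (B < 2L) stop("B must be at least 2")
  df <- as.data.frame(superset)
  full_fit <- fit_fun(superset)
  apparent <- concordance_index(
    predict_superset(full_fit, superset)$probability, df$time, df$status)
  idx_by_subj <- split(seq_len(nrow(df)), df$subject_id)
  ids <- names(idx_by_subj)
  set.seed(seed)
  opt <- rep(NA_real_, B)
  failures <- 0L
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(idx_by_subj[take], use.names = FALSE)
    boot <- subset_superset(superset, rows)
    res <- tryCatch({
      fb <- fit_fun(boot)
      c_boot <- concordance_index(
        predict_superset(fb, boot)$probability, boot$time, boot$status)
      c_orig <- concordance_index(
        predict_superset(fb, superset)$probability, df$time, df$status)
      c_boot - c_orig
    }, error = function(e) NA_real_)
    if (is.na(res)) failures <- failures + 1L else opt[b] <- res
  }
  opt_ok <- opt[!is.na(opt)]
  optimism <- mean(opt_ok)
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism,
       ci = unname(stats::quantile(apparent - opt_ok, c(0.025, 0.975))),
       B = length(opt_ok), failures = failures)
}

#' Dynamic validation report for one fitted model
#'
#' Per landmark: AUC with 95\% CI, Brier score, Brier skill score,
#' calibration-in-the-large; overall: pooled-row concordance and a threshold
#' classification table; decile calibration tables for selected landmarks.
#'
#' @param fit a fitted supermodel.
#' @param superset evaluation rows (internal or external sample).
#' @param thresholds thresholds for the classification table.
#' @param calibration_landmarks landmarks for which full decile tables are
#'   kept (default: first, middle, last).
#' @param sample_tag label, e.g. "internal" or "external".
#' @return object of class \code{validation_report}.
#' @export
validate_fit <- function(fit, superset,
                         thresholds = seq(0.1, 0.9, by = 0.1),
                         calibration_landmarks = NULL,
                         sample_tag = "internal") {
  df <- as.data.frame(superset)
  pr <- predict_superset(fit, superset)
  lms <- sort(unique(df$landmark))
  per <- do.call(rbind, lapply(lms, function(s) {
    sel <- df$landmark == s
    y <- df$status[sel]; p <- pr$probability[sel]
    auc <- tryCatch(auc_binary(p, y == 1L), error = function(e) NULL)
    bb <- brier_bss(p, y)
    data.frame(landmark = s, n = sum(sel), events = sum(y),
               auc = if (is.null(auc)) NA_real_ else auc$auc,
               auc_lo = if (is.null(auc)) NA_real_ else auc$ci[1L],
               auc_hi = if (is.null(auc)) NA_real_ else auc$ci[2L],
               brier = bb$brier, bss = bb$bss,
               calibration_in_large = mean(p) - mean(y))
  }))
  if (is.null(calibration_landmarks))
    calibration_landmarks <-
      unique(lms[c(1L, ceiling(length(lms) / 2), length(lms))])
  calib <- lapply(stats::setNames(nm = as.character(calibration_landmarks)),
                  function(sc) {
    s <- as.numeric(sc)
    tryCatch(calibration_deciles(fit, superset, s),
             error = function(e) NULL)
  })
  structure(list(
    variant = fit$variant, outcome_type = fit$outcome_type,
    sample = sample_tag,
    per_landmark = per,
    cindex = concordance_index(pr$probability, df$time, df$status),
    thresholds = threshold_table(pr$probability, df$status, thresholds),
    calibration = calib
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s, %s outcome, %s sample)\n",
              x$variant, x$outcome_type, x$sample))
  cat(sprintf("  pooled c-index: %.3f; mean AUC over %d landmarks: %.3f\n",
              x$cindex, nrow(x$per_landmark),
              mean(x$per_landmark$auc, na.rm = TRUE)))
  invisible(x)
}

#' Side-by-side comparison of DLM, FLM and FBL
#'
#' Evaluates the three model variants on the same validation subjects and
#' landmarks: the dynamic model on rows with updated covariates and trigger
#' flags, the fixed-covariate landmark model on baseline-covariate rows with
#' its per-landmark baseline hazards, and the fixed-baseline model on the
#' same baseline-covariate rows but always using its landmark-0 baseline
#' hazard. The DLM and FLM supersets share (subject, landmark) keys and
#' outcomes by construction.
#'
#' @param fits named list with any of elements \code{DLM}, \code{FLM},
#'   \code{FBL} (fitted on the same derivation cohort and outcome).
#' @param cohort validation cohort.
#' @param schedule landmark schedule.
#' @param outcome_type outcome the fits were trained on.
#' @param retain_censored see [build_landmark_dataset()].
#' @return list: \code{summary} (one row per variant) and
#'   \code{per_landmark} (long table of per-landmark metrics).
#' @export
compare_models <- function(fits, cohort, schedule,
                           outcome_type = c("general", "violent"),
                           retain_censored = FALSE) {
  outcome_type <- match.arg(outcome_type)
  ot <- vapply(fits, function(f) f$outcome_type, character(1))
  if (any(ot != outcome_type))
    stop("fits were trained on a different outcome")
  need_flm_rows <- any(names(fits) %in% c("FLM", "FBL"))
  ss <- list()
  if ("DLM" %in% names(fits))
    ss$DLM <- stack_superset(cohort, schedule, outcome_type, "DLM",
                             retain_censored)
  if (need_flm_rows) {
    flm_rows <- stack_superset(cohort, schedule, outcome_type, "FLM",
                               retain_censored)
    if ("FLM" %in% names(fits)) ss$FLM <- flm_rows
    if ("FBL" %in% names(fits)) ss$FBL <- flm_rows
  }
  per <- list(); summ <- list()
  for (v in names(fits)) {
    rep_v <- validate_fit(fits[[v]], ss[[v]], sample_tag = "comparison")
    pl <- rep_v$per_landmark
    pl$variant <- v
    per[[v]] <- pl
    summ[[v]] <- data.frame(
      variant = v,
      cindex = rep_v$cindex,
      mean_auc = mean(pl$auc, na.rm = TRUE),
      mean_brier = mean(pl$brier, na.rm = TRUE),
      mean_bss = mean(pl$bss, na.rm = TRUE),
      mean_calibration_in_large = mean(pl$calibration_in_large))
  }
  list(summary = do.call(rbind, summ), per_landmark = do.call(rbind, per))
}

#' Write a validation report as JSON plus a tidy CSV
#'
#' @param report a [validate_fit()] result.
#' @param json_path output JSON path.
#' @param csv_path optional tidy CSV (one row per landmark x metric).
#' @export
write_validation_report <- function(report, json_path, csv_path = NULL) {
  obj <- unclass(report)
  obj$calibration <- lapply(obj$calibration, function(cl)
    if (is.null(cl)) NULL else cl)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    pl <- report$per_landmark
    long <- stats::reshape(
      pl, direction = "long",
      varying = setdiff(names(pl), "landmark"),
      v.names = "value",
      times = setdiff(names(pl), "landmark"),
      timevar = "metric", idvar = "landmark")
    long <- long[order(long$landmark, long$metric), ]
    rownames(long) <- NULL
    utils::write.csv(long, csv_path, row.names = FALSE, na = "")
  }
  invisible(json_path)
}
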