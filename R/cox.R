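#' Fit a Cox landmark supermodel
#'
#' Maximises the stratified Cox partial likelihood over the landmark superset
#' with landmark as stratum: one coefficient vector shared across landmarks,
#' a free baseline hazard per landmark, Breslow tie handling. The
#' landmark-specific baseline cumulative hazard at the prediction horizon,
#' \eqn{BH_{LM}(s)}, is then computed by the Breslow estimator within each
#' stratum; its decline from one landmark to the next is what captures
#' desistance. A stratum with no events gets \eqn{BH_{LM} = 0} with a
#' warning.
#'
#' @param superset a [stack_superset()] result (one imputed copy).
#' @param covariates covariate columns to use; defaults to all covariate
#'   columns of the superset.
#' @return object of class \code{cox_supermodel}: coefficients, covariance,
#'   per-landmark Breslow cumulative-hazard step functions and their value
#'   \code{bh} at the horizon, plus fit metadata.
#' @export
fit_cox_supermodel <- function(superset,
                               covariates = attr(superset, "covariate_names")) {
  df <- as.data.frame(superset)
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols))
    stop("covariates not in superset: ", paste(missing_cols, collapse = ", "))
  const <- covariates[vapply(covariates, function(v)
    length(unique(df[[v]])) < 2L, logical(1))]
  if (length(const))
    stop("degenerate covariate (constant in the data): ",
         paste(const, collapse = ", "))
  if (sum(df$status) == 0L) stop("no events in the superset")

  fml <- stats::as.formula(paste(
    "survival::Surv(time, status) ~",
    paste(sprintf("`%s`", covariates), collapse = " + "),
    "+ survival::strata(landmark)"))
  # separation is re-checked explicitly below; muffle coxph's own warning
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  names(beta) <- covariates
  if (anyNA(beta))
    stop("degenerate fit (singular design), offending covariate: ",
         paste(covariates[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  if (any(abs(beta) > 15))
    stop("separation (monotone likelihood), offending covariate: ",
         paste(covariates[abs(beta) > 15], collapse = ", "))

  meta <- superset_meta(superset)
  w <- if (!is.null(meta$schedule)) meta$schedule$horizon_days
       else max(df$time)
  lp <- as.numeric(as.matrix(df[, covariates, drop = FALSE]) %*% beta)
  basehaz <- compute_breslow(df$time, df$status, exp(lp), df$landmark)
  bh <- vapply(basehaz, function(b) {
    idx <- if (nrow(b)) findInterval(w, b$time) else 0L
    if (idx == 0L) 0 else b$hazard[idx]
  }, numeric(1))
  zero_ev <- names(bh)[vapply(basehaz, nrow, integer(1)) == 0L]
  if (length(zero_ev))
    warning("no events in landmark stratum ",
            paste(zero_ev, collapse = ", "), "; BH set to 0")

  structure(list(
    variant = meta$variant %||% "DLM",
    outcome_type = meta$outcome_type %||% "general",
    covariates = covariates,
    coef = beta,
    vcov = structure(fit$var, dimnames = list(covariates, covariates)),
    se = stats::setNames(se, covariates),
    basehaz = basehaz,
    bh = bh,
    horizon = w,
    retain_censored = isTRUE(meta$retain_censored),
    n = nrow(df), nevent = sum(df$status),
    loglik = fit$loglik[2L], iter = fit$iter,
    converged = fit$iter < 100
  ), class = "cox_supermodel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Breslow cumulative baseline hazard step functions, one per stratum:
# at each distinct event time t_i, increment = d_i / sum of risk scores over
# the at-risk set {j : time_j >= t_i} within the stratum.
compute_breslow <- function(time, status, risk, stratum) {
  out <- list()
  for (s in sort(unique(stratum))) {
    sel <- stratum == s
    t_s <- time[sel]; st <- status[sel]; r_s <- risk[sel]
    ord <- order(t_s)
    t_s <- t_s[ord]; st <- st[ord]; r_s <- r_s[ord]
    atrisk <- rev(cumsum(rev(r_s)))
    ev_times <- unique(t_s[st == 1L])
    if (length(ev_times) == 0L) {
      out[[as.character(s)]] <- data.frame(time = numeric(0),
                                           hazard = numeric(0))
      next
    }
    first_idx <- match(ev_times, t_s)  # ties share the same at-risk set
    d <- vapply(ev_times, function(tt) sum(st[t_s == tt]), numeric(1))
    out[[as.character(s)]] <- data.frame(
      time = ev_times,
      hazard = cumsum(d / atrisk[first_idx]))
  }
  out
}

#' Breslow cumulative baseline hazard of a fitted supermodel
#'
#' Evaluates the within-stratum Breslow estimator at time \code{t}: the sum
#' over event times up to \code{t} of the event count divided by the
#' risk-score total of the at-risk set. A non-decreasing step function that
#' is 0 before the first event time.
#'
#' @param fit a [fit_cox_supermodel()] result.
#' @param stratum a landmark day present in the training superset.
#' @param t time (days since the landmark) at which to evaluate.
#' @return cumulative baseline hazard.
#' @export
breslow_baseline <- function(fit, stratum, t) {
  b <- fit$basehaz[[as.character(stratum)]]
  if (is.null(b)) stop("unknown stratum: ", stratum)
  if (nrow(b) == 0L || t < b$time[1L]) return(0)
  b$hazard[findInterval(t, b$time)]
}

#' Predicted risk at a landmark
#'
#' Evaluates the supermodel risk equation
#' \deqn{P = 1 - \exp(-BH_{LM} \cdot \exp(\beta' RF))}
#' for a covariate vector at a landmark. A fixed-baseline (FBL) model always
#' uses its landmark-0 baseline hazard, whatever \code{landmark_day} is.
#'
#' @param fit a fitted (or pooled) supermodel.
#' @param rf named covariate vector (or single-row data.frame / list)
#'   covering all model covariates.
#' @param landmark_day landmark at which to predict.
#' @return list with \code{landmark_day}, \code{linear_predictor} and
#'   \code{probability}.
#' @export
predict_risk <- function(fit, rf, landmark_day) {
  rf <- unlist(rf)
  missing_cov <- setdiff(fit$covariates, names(rf))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  key <- if (fit$variant == "FBL") "0" else as.character(landmark_day)
  if (!key %in% names(fit$bh))
    stop("unknown landmark for this model: ", landmark_day)
  lp <- sum(fit$coef * rf[fit$covariates])
  list(landmark_day = landmark_day,
       linear_predictor = lp,
       probability = 1 - exp(-fit$bh[[key]] * exp(lp)))
}

#' Predicted risks for every row of a landmark superset
#'
#' @param fit a fitted supermodel.
#' @param superset rows to predict for; each row uses its own landmark's
#'   baseline hazard (landmark 0's for an FBL model).
#' @return data.frame: subject_id, landmark, linear_predictor, probability.
#' @export
predict_superset <- function(fit, superset) {
  df <- as.data.frame(superset)
  lp <- as.numeric(as.matrix(df[, fit$covariates, drop = FALSE]) %*%
                     fit$coef)
  key <- if (fit$variant == "FBL") rep("0", nrow(df))
         else as.character(df$landmark)
  bad <- setdiff(unique(key), names(fit$bh))
  if (length(bad))
    stop("unknown landmark(s) for this model: ", paste(bad, collapse = ", "))
  bh <- fit$bh[key]
  data.frame(subject_id = df$subject_id, landmark = df$landmark,
             linear_predictor = lp,
             probability = 1 - exp(-bh * exp(lp)))
}

#' @export
print.cox_supermodel <- function(x, ...) {
  cat(sprintf("Cox landmark supermodel (%s, %s outcome)\n", x$variant,
              x$outcome_type))
  cat(sprintf("  %d rows, %d events, %d landmarks, horizon %d d\n",
              x$n, x$nevent, length(x$bh), x$horizon))
  print(round(x$coef, 4))
  invisible(x)
}

#' Fit a model variant across imputations and pool
#'
#' Builds the variant's landmark superset for each imputed cohort, fits the
#' Cox supermodel per copy, pools the coefficients with Rubin's rules and
#' averages the per-landmark baseline hazards at the horizon. The returned
#' \code{fit} element is a prediction-ready supermodel carrying the pooled
#' coefficients and averaged baseline hazards.
#'
#' @param imputed_cohorts list of cohorts (one per imputation), or a single
#'   cohort for a complete-data fit.
#' @param schedule a [landmark_schedule()].
#' @param outcome_type \code{"general"} or \code{"violent"}.
#' @param variant \code{"DLM"}, \code{"FLM"} or \code{"FBL"}.
#' @param covariates covariate subset to fit (default: all).
#' @param retain_censored see [build_landmark_dataset()].
#' @return list with \code{fits} (per-imputation supermodels), \code{pooled}
#'   (coefficient table with Rubin variances, NULL for a single cohort) and
#'   \code{fit} (the pooled supermodel).
#' @export
fit_variant <- function(imputed_cohorts, schedule,
                        outcome_type = c("general", "violent"),
                        variant = c("DLM", "FLM", "FBL"),
                        covariates = NULL, retain_censored = FALSE) {
  outcome_type <- match.arg(outcome_type)
  variant <- match.arg(variant)
  if (inherits(imputed_cohorts, "cohort"))
    imputed_cohorts <- list(imputed_cohorts)
  fits <- lapply(imputed_cohorts, function(ch) {
    ss <- stack_superset(ch, schedule, outcome_type, variant,
                         retain_censored)
    if (is.null(covariates)) fit_cox_supermodel(ss)
    else fit_cox_supermodel(ss, covariates = covariates)
  })
  m <- length(fits)
  combined <- fits[[1L]]
  pooled <- NULL
  if (m >= 2L) {
    terms <- fits[[1L]]$covariates
    pooled <- do.call(rbind, lapply(terms, function(tm) {
      pr <- pool_rubin(vapply(fits, function(f) f$coef[[tm]], numeric(1)),
                       vapply(fits, function(f) diag(f$vcov)[[tm]],
                              numeric(1)))
      data.frame(term = tm, estimate = pr$estimate, se = pr$se,
                 within = pr$within, between = pr$between, p = pr$p)
    }))
    combined$coef <- stats::setNames(pooled$estimate, pooled$term)
    combined$se <- stats::setNames(pooled$se, pooled$term)
    bh_mat <- vapply(fits, function(f) f$bh, numeric(length(fits[[1L]]$bh)))
    combined$bh <- if (is.matrix(bh_mat)) rowMeans(bh_mat) else mean(bh_mat)
    names(combined$bh) <- names(fits[[1L]]$bh)
    combined$basehaz <- NULL  # step functions are per-imputation objects
    combined$pooled <- TRUE
  }
  list(fits = fits, pooled = pooled, fit = combined)
}

#' Serialize / restore a fitted supermodel as JSON
#'
#' Writes everything needed to reproduce predictions exactly: variant,
#' outcome, covariate order, coefficients, the per-landmark baseline hazard
#' table at the horizon, and fit metadata.
#'
#' @param fit a supermodel.
#' @param path JSON path.
#' @export
write_supermodel <- function(fit, path) {
  obj <- list(variant = fit$variant, outcome_type = fit$outcome_type,
              covariates = fit$covariates,
              coef = as.list(fit$coef),
              se = as.list(fit$se),
              bh = as.list(fit$bh),
              horizon = fit$horizon,
              retain_censored = fit$retain_censored,
              n = fit$n, nevent = fit$nevent, loglik = fit$loglik,
              pooled = isTRUE(fit$pooled))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_supermodel
#' @export
read_supermodel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    variant = obj$variant, outcome_type = obj$outcome_type,
    covariates = obj$covariates,
    coef = unlist(obj$coef), se = unlist(obj$se),
    basehaz = NULL,
    bh = unlist(obj$bh),
    horizon = obj$horizon,
    retain_censored = obj$retain_censored,
    n = obj$n, nevent = obj$nevent, loglik = obj$loglik,
    pooled = obj$pooled, converged = TRUE
  ), class = "cox_supermodel")
}
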