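# Shared fixtures and independent oracles used across the test files.

# Build a covariate-spec row set from plain names (binary, group 1, static,
# beta 0) with per-column overrides.
make_cov_spec <- function(names, ...) {
  n <- length(names)
  spec <- data.frame(name = names, type = "binary", group = 1L,
                     p = 0.5, mean = NA_real_, sd = NA_real_, beta = 0,
                     dynamics = "static", sociodemo = FALSE,
                     stringsAsFactors = FALSE)
  over <- list(...)
  for (col in names(over)) spec[[col]] <- over[[col]]
  spec
}

# Hand-assembled cohort: subjects is a data.frame with subject_id plus
# covariate columns plus outcome/censor fields; updates/triggers optional.
make_test_cohort <- function(subjects, updates = NULL, triggers = NULL,
                             cov_spec = NULL, trigger_spec = NULL,
                             followup_days = 1095L, horizon_days = 730L) {
  if (is.null(cov_spec)) {
    covnames <- setdiff(names(subjects),
                        c("subject_id", "region", "region_group",
                          "outcome_day", "outcome_type", "censor_day",
                          "censor_reason"))
    cov_spec <- make_cov_spec(covnames)
  }
  if (is.null(trigger_spec))
    trigger_spec <- data.frame(name = character(0), rate = numeric(0),
                               acute_loghr = numeric(0),
                               short_loghr = numeric(0),
                               residual_loghr = numeric(0))
  if (is.null(updates))
    updates <- data.frame(subject_id = integer(0), day = integer(0),
                          name = character(0), value = numeric(0))
  if (is.null(triggers))
    triggers <- data.frame(subject_id = integer(0), day = integer(0),
                           trigger_name = character(0))
  if (is.null(subjects$region)) subjects$region <- "R01"
  if (is.null(subjects$region_group)) subjects$region_group <- 1L
  if (is.null(subjects$outcome_day)) subjects$outcome_day <- NA_real_
  if (is.null(subjects$outcome_type)) subjects$outcome_type <- NA_character_
  if (is.null(subjects$censor_day))
    subjects$censor_day <- followup_days + horizon_days
  if (is.null(subjects$censor_reason)) subjects$censor_reason <-
    ifelse(is.na(subjects$outcome_day), "end_of_followup", NA_character_)
  subjects$censor_day[!is.na(subjects$outcome_day)] <- NA_real_
  cfg <- sim_config(n_subjects = nrow(subjects),
                    followup_days = followup_days,
                    horizon_days = horizon_days,
                    covariates = cov_spec, triggers = trigger_spec,
                    seed = 1L)
  structure(list(subjects = subjects, updates = updates,
                 triggers = triggers, config = cfg),
            class = "cohort")
}

# --- independent oracles ----------------------------------------------------

# Brute-force landmark-row construction: plain loops re-deriving the at-risk,
# event-window and censoring-removal rules from their definitions.
brute_landmark_rows <- function(cohort, schedule, s, outcome_type, variant,
                                retain_censored = FALSE) {
  w <- schedule$horizon_days
  subj <- cohort$subjects
  out <- list()
  for (i in seq_len(nrow(subj))) {
    ev <- subj$outcome_day[i]
    ot <- subj$outcome_type[i]
    cs <- subj$censor_day[i]
    if (outcome_type == "violent") {
      if (!is.na(ev) && !identical(ot, "violent")) { cs <- ev; ev <- NA }
    }
    if (!is.na(ev) && ev <= s) next
    if (!is.na(cs) && cs <= s) next
    if (!is.na(ev) && ev <= s + w && (is.na(cs) || ev <= cs)) {
      status <- 1L; tim <- ev - s
    } else if (!is.na(cs) && cs < s + w) {
      if (!retain_censored) next
      status <- 0L; tim <- cs - s
    } else {
      status <- 0L; tim <- w
    }
    cov <- cohort$config$covariates
    vals <- list()
    for (v in cov$name) {
      vals[[v]] <- if (variant == "DLM")
        covariate_at(cohort, subj$subject_id[i], v, s)
      else subj[[v]][i]
    }
    if (variant == "DLM") {
      for (tn in cohort$config$triggers$name) {
        fl <- encode_triggers(cohort, subj$subject_id[i], tn, s)
        vals[[paste(tn, "acute", sep = "_")]] <- fl[["acute"]]
        vals[[paste(tn, "short", sep = "_")]] <- fl[["short"]]
        vals[[paste(tn, "residual", sep = "_")]] <- fl[["residual"]]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      subject_id = subj$subject_id[i], landmark = s, vals,
      time = as.numeric(tim), status = status)
  }
  if (length(out)) do.call(rbind, out)
  else NULL
}

# Hand-coded stratified Cox partial log-likelihood (Breslow ties) for a
# single covariate.
partial_loglik_1cov <- function(beta, time, status, x, stratum) {
  ll <- 0
  for (s in unique(stratum)) {
    sel <- stratum == s
    t_s <- time[sel]; st <- status[sel]; x_s <- x[sel]
    for (i in which(st == 1L)) {
      risk <- t_s >= t_s[i]
      ll <- ll + beta * x_s[i] - log(sum(exp(beta * x_s[risk])))
    }
  }
  ll
}

grid_max_1cov <- function(time, status, x, stratum,
                          lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, partial_loglik_1cov, numeric(1),
               time = time, status = status, x = x, stratum = stratum)
  grid[which.max(ll)]
}

# Exhaustive-pair Harrell concordance.
brute_cindex <- function(pred, time, status) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable: the shorter time is an event
    if (time[i] == time[j]) {
      if (status[i] + status[j] != 1L) next
      # equal times, one event: not usable under Harrell's rule
      next
    }
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (status[a] != 1L) next
    den <- den + 1
    if (pred[a] > pred[b]) num <- num + 1
    else if (pred[a] == pred[b]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Mann-Whitney AUC by exhaustive pair counting.
brute_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]; y <- scores[!as.logical(labels)]
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Small simulated cohort cached across test files (built once per run).
shared_cohort <- local({
  ch <- NULL
  function() {
    if (is.null(ch))
      ch <<- simulate_cohort(sim_config(n_subjects = 1500, seed = 42))
    ch
  }
})
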