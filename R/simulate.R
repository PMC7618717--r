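#' Sample an event time from a piecewise-constant hazard
#'
#' Inverse-transform sampling: given a hazard that is constant within
#' consecutive segments, returns the smallest time t with cumulative hazard
#' \eqn{\Lambda(t) \ge -\log(u)}, or \code{NA} if the horizon is reached
#' first.
#'
#' @param segments data.frame with columns \code{start_day} (strictly
#'   increasing, first element 0) and \code{rate} (nonnegative, per day);
#'   each segment runs to the next start, the last to \code{horizon}.
#' @param horizon end of the observation period (days).
#' @param u a uniform(0, 1) draw.
#' @return event time (possibly fractional) or \code{NA_real_}.
#' @export
sample_event_time <- function(segments, horizon, u) {
  starts <- segments$start_day
  rates <- segments$rate
  if (length(starts) == 0L) stop("no segments")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (is.unsorted(starts, strictly = TRUE))
    stop("segments must be sorted with strictly increasing starts")
  if (starts[1L] != 0) stop("segments must cover [0, horizon)")
  if (u <= 0 || u >= 1) stop("u must lie in (0, 1)")
  ends <- c(starts[-1L], horizon)
  widths <- ends - starts
  if (any(widths <= 0)) stop("segments must not overlap")
  target <- -log(u)
  cum <- cumsum(rates * widths)
  idx <- which(cum >= target)[1L]
  if (is.na(idx)) return(NA_real_)
  cum_prev <- if (idx > 1L) cum[idx - 1L] else 0
  if (rates[idx] > 0) starts[idx] + (target - cum_prev) / rates[idx]
  else starts[idx]
}

# Daily trigger-effect log-hazard contribution for one subject.
# Residual applies from the first occurrence day onwards; short-term and
# acute surges apply over (te, te+30] and (te, te+7] after each occurrence.
trigger_loghaz <- function(event_days, acute, short, residual, n_days) {
  add <- numeric(n_days)
  if (length(event_days) == 0L) return(add)
  first <- min(event_days)
  if (first <= n_days) add[first:n_days] <- add[first:n_days] + residual
  short_ind <- logical(n_days)
  acute_ind <- logical(n_days)
  for (te in event_days) {
    if (te + 1L <= n_days) {
      short_ind[(te + 1L):min(te + 30L, n_days)] <- TRUE
      acute_ind[(te + 1L):min(te + 7L, n_days)] <- TRUE
    }
  }
  add + short * short_ind + acute * acute_ind
}

#' Simulate a longitudinal cohort
#'
#' Generates subject histories with baseline covariates, annual covariate
#' re-measurement, Poisson trigger events, competing censoring and a daily
#' event hazard
#' \deqn{h(t) = h_0 \exp(-\lambda t)\, \exp(\beta' x(t) + \mathrm{trigger}(t)),}
#' where \eqn{x(t)} is the step-function covariate path, \eqn{\lambda} the
#' desistance decay and the trigger term the binary acute/short-term/residual
#' encoding evaluated at time t. Event days are drawn by inverse-transform
#' sampling of the daily cumulative hazard; censoring days come from
#' independent exponential competing processes. The first event ends the
#' subject's at-risk period; events are flagged violent by Bernoulli
#' thinning.
#'
#' Outcomes and censoring are observed through
#' \code{followup_days + horizon_days}, so that every landmark window of
#' width \code{horizon_days} opened during the landmark period is fully
#' observable; subjects still event-free and uncensored at that point carry
#' an administrative \code{end_of_followup} censoring day.
#'
#' @param config a [sim_config()].
#' @return object of class \code{cohort}: a list with data.frames
#'   \code{subjects} (one row per subject), \code{updates} (long-format
#'   re-measurements: subject_id, day, name, value) and \code{triggers}
#'   (subject_id, day, trigger_name), plus the config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  fup <- config$followup_days
  obs_days <- fup + config$horizon_days
  cov <- config$covariates
  trig <- config$triggers

  ## regions
  n_reg <- config$n_regions
  region_ids <- sprintf("R%02d", seq_len(sum(n_reg)))
  region_group <- rep(seq_along(n_reg), n_reg)
  reg_idx <- sample.int(length(region_ids), n, replace = TRUE)

  ## baseline covariates
  base <- matrix(NA_real_, n, nrow(cov), dimnames = list(NULL, cov$name))
  for (j in seq_len(nrow(cov))) {
    base[, j] <- if (cov$type[j] == "binary") {
      stats::rbinom(n, 1L, cov$p[j])
    } else {
      pmax(18, stats::rnorm(n, cov$mean[j], cov$sd[j]))
    }
  }

  ## annual re-measurement paths for dynamic covariates
  meas_days <- if (fup >= config$update_interval_days)
    seq(config$update_interval_days, fup, by = config$update_interval_days)
  else integer(0)
  dyn <- cov[cov$dynamics != "static", , drop = FALSE]
  n_meas <- length(meas_days)
  # paths[[v]] is an n x n_meas matrix of measured values
  paths <- list()
  for (j in seq_len(nrow(dyn))) {
    v <- dyn$name[j]
    cur <- base[, v]
    pm <- matrix(NA_real_, n, n_meas)
    for (k in seq_len(n_meas)) {
      if (dyn$dynamics[j] == "switch") {
        flip <- stats::rbinom(n, 1L, config$switch_prob) == 1L
        cur <- ifelse(flip, 1 - cur, cur)
      } else { # monotone onset
        onset <- stats::rbinom(n, 1L, config$onset_prob) == 1L
        cur <- pmax(cur, as.numeric(onset))
      }
      pm[, k] <- cur
    }
    paths[[v]] <- pm
  }

  ## trigger events
  trig_sub <- integer(0); trig_day <- integer(0); trig_name <- character(0)
  if (nrow(trig)) {
    for (j in seq_len(nrow(trig))) {
      counts <- stats::rpois(n, trig$rate[j] * fup / 365)
      tot <- sum(counts)
      if (tot > 0) {
        days <- sample.int(fup, tot, replace = TRUE)
        trig_sub <- c(trig_sub, rep.int(seq_len(n), counts))
        trig_day <- c(trig_day, days)
        trig_name <- c(trig_name, rep.int(trig$name[j], tot))
      }
    }
  }
  trig_by_sub <- if (length(trig_sub)) split(seq_along(trig_sub), trig_sub)
                 else list()

  ## event sampling per subject
  beta <- cov$beta
  names(beta) <- cov$name
  static_names <- cov$name[cov$dynamics == "static"]
  lp_base <- as.numeric(base %*% beta)  # full baseline linear predictor
  h0_decay <- config$baseline_hazard_day0 *
    exp(-config$desistance_decay * (seq_len(obs_days) - 1))
  E <- stats::rexp(n)
  violent <- stats::rbinom(n, 1L, config$violent_fraction) == 1L

  ## censoring (independent exponentials, rate per person-year)
  cens_mat <- matrix(Inf, n, 3L,
                     dimnames = list(NULL, c("death", "emigration",
                                             "imprisonment")))
  for (cz in colnames(cens_mat)) {
    r <- config$censor_rates[[cz]]
    if (r > 0) cens_mat[, cz] <- ceiling(stats::rexp(n, r / 365))
  }

  event_day <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    lp <- rep(lp_base[i], obs_days)
    for (v in names(paths)) {
      vals <- c(base[i, v], paths[[v]][i, ])
      dv <- diff(vals)
      chg <- which(dv != 0)
      for (k in chg) {
        d0 <- meas_days[k]
        if (d0 <= obs_days) lp[d0:obs_days] <- lp[d0:obs_days] + beta[v] * dv[k]
      }
    }
    idx <- trig_by_sub[[as.character(i)]]
    if (!is.null(idx) && nrow(trig)) {
      for (j in seq_len(nrow(trig))) {
        td <- trig_day[idx][trig_name[idx] == trig$name[j]]
        if (length(td)) {
          lp <- lp + trigger_loghaz(td, trig$acute_loghr[j],
                                    trig$short_loghr[j],
                                    trig$residual_loghr[j], obs_days)
        }
      }
    }
    cum <- cumsum(h0_decay * exp(lp))
    d <- which(cum >= E[i])[1L]
    if (!is.na(d)) event_day[i] <- d
  }

  cens_day <- pmin(cens_mat[, 1L], cens_mat[, 2L], cens_mat[, 3L])
  cens_reason <- c("death", "emigration", "imprisonment")[
    max.col(-cens_mat, ties.method = "first")]
  admin <- !is.finite(cens_day) | cens_day > obs_days
  cens_day[admin] <- obs_days
  cens_reason[admin] <- "end_of_followup"

  has_event <- !is.na(event_day) & event_day <= cens_day
  subjects <- data.frame(
    subject_id = seq_len(n),
    region = region_ids[reg_idx],
    region_group = region_group[reg_idx],
    base,
    outcome_day = ifelse(has_event, event_day, NA_integer_),
    outcome_type = ifelse(has_event,
                          ifelse(violent, "violent", "general"),
                          NA_character_),
    censor_day = ifelse(has_event, NA_integer_, as.integer(cens_day)),
    censor_reason = ifelse(has_event, NA_character_, cens_reason),
    stringsAsFactors = FALSE
  )

  ## long-format update records (annual measurements, recorded regardless
  ## of change, mirroring register snapshots)
  if (length(paths) && n_meas > 0) {
    upd <- do.call(rbind, lapply(names(paths), function(v) {
      data.frame(subject_id = rep(seq_len(n), n_meas),
                 day = rep(meas_days, each = n),
                 name = v,
                 value = as.numeric(paths[[v]]),
                 stringsAsFactors = FALSE)
    }))
    upd <- upd[order(upd$subject_id, upd$day, upd$name), ]
    rownames(upd) <- NULL
  } else {
    upd <- data.frame(subject_id = integer(0), day = integer(0),
                      name = character(0), value = numeric(0))
  }

  triggers <- data.frame(subject_id = trig_sub, day = trig_day,
                         trigger_name = trig_name, stringsAsFactors = FALSE)
  if (nrow(triggers)) {
    triggers <- triggers[order(triggers$subject_id, triggers$day,
                               triggers$trigger_name), ]
    rownames(triggers) <- NULL
  }

  structure(list(subjects = subjects, updates = upd, triggers = triggers,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Cohort: %d subjects, %d covariate updates, %d trigger events\n",
              nrow(s), nrow(x$updates), nrow(x$triggers)))
  cat(sprintf("  events: %d (%.1f%%), of which violent: %d\n",
              sum(!is.na(s$outcome_day)),
              100 * mean(!is.na(s$outcome_day)),
              sum(s$outcome_type == "violent", na.rm = TRUE)))
  invisible(x)
}

#' Mask sociodemographic values completely at random
#'
#' Applies MCAR masking at the given per-field rate to sociodemographic
#' covariates only, in both the baseline table and the long-format update
#' records. Criminal-history (Group 1) and clinical covariates, triggers and
#' outcomes are never masked: those are event-driven register records that
#' exist exactly when the event occurred.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param missing_fraction masking probability per field, in [0, 1).
#' @param seed RNG seed.
#' @return the cohort with masked entries set to \code{NA}.
#' @export
inject_missingness <- function(cohort,
                               missing_fraction = cohort$config$missing_fraction,
                               seed = cohort$config$seed + 1L) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  if (missing_fraction == 0) return(cohort)
  set.seed(seed)
  cov <- cohort$config$covariates
  maskable <- cov$name[cov$sociodemo]
  for (v in maskable) {
    hit <- stats::runif(nrow(cohort$subjects)) < missing_fraction
    cohort$subjects[[v]][hit] <- NA
  }
  upd_mask <- cohort$updates$name %in% maskable &
    stats::runif(nrow(cohort$updates)) < missing_fraction
  cohort$updates$value[upd_mask] <- NA
  cohort
}

# Restrict a cohort to a set of subject ids.
subset_cohort <- function(cohort, ids) {
  out <- cohort
  out$subjects <- cohort$subjects[cohort$subjects$subject_id %in% ids, ]
  out$updates <- cohort$updates[cohort$updates$subject_id %in% ids, ]
  out$triggers <- cohort$triggers[cohort$triggers$subject_id %in% ids, ]
  rownames(out$subjects) <- rownames(out$updates) <-
    rownames(out$triggers) <- NULL
  out
}

#' Region-level derivation/validation split
#'
#' Assigns whole regions (never individual subjects) to the validation set,
#' selecting regions at random within region-groups — one candidate from each
#' of the first three groups, then the fourth group, then any remaining —
#' and greedily adding regions while the validation share moves closer to the
#' target fraction. The two outputs partition the cohort and are
#' geographically disjoint.
#'
#' @param cohort a cohort object.
#' @param validation_fraction target share of subjects in the validation set.
#' @param seed RNG seed.
#' @return list with elements \code{derivation} and \code{validation}.
#' @export
split_by_region <- function(cohort, validation_fraction = 0.2,
                            seed = cohort$config$seed + 2L) {
  s <- cohort$subjects
  if (is.null(s$region) || anyNA(s$region))
    stop("every subject must have a region")
  regs <- unique(s[, c("region", "region_group")])
  if (nrow(regs) < 2L) stop("need at least 2 regions to split")
  set.seed(seed)
  sizes <- table(s$region)
  # candidate order: one random region from each of groups 1-3, then the
  # group-4 regions in random order, then remaining regions shuffled
  pick <- character(0)
  rest <- character(0)
  for (g in 1:3) {
    rg <- regs$region[regs$region_group == g]
    if (length(rg)) {
      first <- rg[sample.int(length(rg), 1L)]
      pick <- c(pick, first)
      rest <- c(rest, setdiff(rg, first))
    }
  }
  g4 <- regs$region[regs$region_group == 4]
  if (length(g4)) pick <- c(pick, g4[sample.int(length(g4))])
  if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
  order_cand <- c(pick, rest)

  n_total <- nrow(s)
  val_regions <- character(0)
  val_n <- 0L
  for (r in order_cand) {
    if (length(val_regions) == nrow(regs) - 1L) break  # keep derivation nonempty
    new_n <- val_n + sizes[[r]]
    if (abs(new_n / n_total - validation_fraction) <
        abs(val_n / n_total - validation_fraction)) {
      val_regions <- c(val_regions, r)
      val_n <- new_n
    } else break
  }
  if (length(val_regions) == 0L) val_regions <- order_cand[1L]
  val_ids <- s$subject_id[s$region %in% val_regions]
  list(derivation = subset_cohort(cohort, setdiff(s$subject_id, val_ids)),
       validation = subset_cohort(cohort, val_ids))
}

#' Write / read a cohort as CSV files
#'
#' Persists the three cohort tables as \code{subjects.csv},
#' \code{updates.csv} and \code{triggers.csv} (UTF-8, header row, missing
#' values as empty fields). Output is byte-identical for identical input.
#'
#' @param cohort a cohort object.
#' @param dir output directory (created if needed).
#' @return \code{write_cohort} returns the directory invisibly;
#'   \code{read_cohort} returns a \code{cohort}.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$updates, file.path(dir, "updates.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$triggers, file.path(dir, "triggers.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @param config optionally, the [sim_config()] the cohort was generated
#'   with; attached so downstream stages know the covariate grouping.
#' @export
read_cohort <- function(dir, config = NULL) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              na.strings = "", stringsAsFactors = FALSE)
  updates <- utils::read.csv(file.path(dir, "updates.csv"),
                             na.strings = "", stringsAsFactors = FALSE)
  triggers <- utils::read.csv(file.path(dir, "triggers.csv"),
                              na.strings = "", stringsAsFactors = FALSE)
  if (nrow(updates) == 0L)
    updates <- data.frame(subject_id = integer(0), day = integer(0),
                          name = character(0), value = numeric(0))
  if (nrow(triggers) == 0L)
    triggers <- data.frame(subject_id = integer(0), day = integer(0),
                           trigger_name = character(0))
  structure(list(subjects = subjects, updates = updates, triggers = triggers,
                 config = config),
            class = "cohort")
}
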