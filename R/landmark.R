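#' Landmark schedule
#'
#' The grid of prediction time points. The default is monthly landmarks over
#' a 3-year follow-up: days 0, 30, ..., 1080 (37 landmarks), each opening a
#' 2-year (730-day) prediction window.
#'
#' @param landmark_days strictly increasing nonnegative days, first element 0.
#' @param horizon_days prediction-window width w in days.
#' @param spacing_days nominal spacing (metadata only when
#'   \code{landmark_days} is supplied explicitly).
#' @return object of class \code{landmark_schedule}.
#' @export
landmark_schedule <- function(landmark_days = seq(0L, 1080L, by = 30L),
                              horizon_days = 730L,
                              spacing_days = 30L) {
  landmark_days <- as.integer(landmark_days)
  if (length(landmark_days) == 0L || landmark_days[1L] != 0L)
    stop("the first landmark must be day 0")
  if (is.unsorted(landmark_days, strictly = TRUE))
    stop("landmark days must be strictly increasing")
  if (horizon_days < 1) stop("horizon_days must be positive")
  structure(list(landmark_days = landmark_days,
                 horizon_days = as.integer(horizon_days),
                 spacing_days = as.integer(spacing_days)),
            class = "landmark_schedule")
}

#' @export
print.landmark_schedule <- function(x, ...) {
  cat(sprintf("Landmark schedule: %d landmarks (day %d to %d), window %d d\n",
              length(x$landmark_days), min(x$landmark_days),
              max(x$landmark_days), x$horizon_days))
  invisible(x)
}

#' Covariate value at a landmark (last observation carried forward)
#'
#' Returns the most recent recorded value at or before day \code{s} (an
#' update is effective on its own day). Sociodemographic covariates keep
#' their baseline value for the first 90 days of follow-up, 3 months being
#' the typical gap between the start of follow-up and the first annual
#' register measurement.
#'
#' @param cohort a cohort object (with its config attached).
#' @param subject_id a single subject id.
#' @param name covariate name.
#' @param s landmark day.
#' @return the covariate value.
#' @export
covariate_at <- function(cohort, subject_id, name, s) {
  cov <- cohort$config$covariates
  if (!name %in% cov$name) stop("unknown covariate: ", name)
  row <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  if (nrow(row) != 1L) stop("unknown subject: ", subject_id)
  val <- row[[name]]
  if (cov$dynamics[cov$name == name] == "static") return(val)
  if (cov$sociodemo[cov$name == name] && s < 90) return(val)
  u <- cohort$updates
  u <- u[u$subject_id == subject_id & u$name == name & u$day <= s, ]
  if (nrow(u)) val <- u$value[which.max(u$day)]
  val
}

#' Trigger encoding at a landmark
#'
#' Three nested binary flags per trigger type: acute if an event occurred in
#' \code{(s-7, s]}, short-term if in \code{(s-30, s]}, residual if at any
#' time in \code{[0, s]}. By construction acute implies short-term implies
#' residual.
#'
#' @param cohort a cohort object.
#' @param subject_id a single subject id.
#' @param trigger_name trigger type.
#' @param s landmark day (nonnegative).
#' @return named numeric vector \code{c(acute=, short=, residual=)}.
#' @export
encode_triggers <- function(cohort, subject_id, trigger_name, s) {
  stopifnot(s >= 0)
  tr <- cohort$triggers
  d <- tr$day[tr$subject_id == subject_id & tr$trigger_name == trigger_name]
  c(acute = as.numeric(any(d > s - 7 & d <= s)),
    short = as.numeric(any(d > s - 30 & d <= s)),
    residual = as.numeric(any(d >= 0 & d <= s)))
}

# Vectorised covariate matrix at landmark s for the given subjects table.
# dynamic = FALSE returns pure baseline values (FLM/FBL rows).
cov_matrix_at <- function(cohort, s, dynamic = TRUE) {
  cov <- cohort$config$covariates
  subj <- cohort$subjects
  m <- as.matrix(subj[, cov$name, drop = FALSE])
  if (dynamic && nrow(cohort$updates)) {
    dyn_names <- cov$name[cov$dynamics != "static"]
    for (v in dyn_names) {
      if (cov$sociodemo[cov$name == v] && s < 90) next
      u <- cohort$updates
      u <- u[u$name == v & u$day <= s, ]
      if (nrow(u)) {
        u <- u[order(u$subject_id, u$day), ]
        u <- u[!duplicated(u$subject_id, fromLast = TRUE), ]
        idx <- match(subj$subject_id, u$subject_id)
        hit <- !is.na(idx)
        m[hit, v] <- u$value[idx[hit]]
      }
    }
  }
  m
}

# Vectorised trigger-flag matrix at landmark s (3 columns per trigger type).
trigger_matrix_at <- function(cohort, s) {
  trig <- cohort$config$triggers
  subj_id <- cohort$subjects$subject_id
  if (is.null(trig) || nrow(trig) == 0L)
    return(matrix(numeric(0), nrow = length(subj_id), ncol = 0L))
  out <- matrix(0, length(subj_id), 3L * nrow(trig))
  cn <- character(0)
  tr <- cohort$triggers
  for (j in seq_len(nrow(trig))) {
    tj <- tr[tr$trigger_name == trig$name[j], ]
    acute <- unique(tj$subject_id[tj$day > s - 7 & tj$day <= s])
    short <- unique(tj$subject_id[tj$day > s - 30 & tj$day <= s])
    resid <- unique(tj$subject_id[tj$day <= s])
    out[subj_id %in% acute, 3L * j - 2L] <- 1
    out[subj_id %in% short, 3L * j - 1L] <- 1
    out[subj_id %in% resid, 3L * j] <- 1
    cn <- c(cn, paste(trig$name[j], c("acute", "short", "residual"),
                      sep = "_"))
  }
  colnames(out) <- cn
  out
}

# Effective event/censoring days for the outcome under analysis.
# For the violent outcome a nonviolent conviction censors the subject at its
# day (imprisonment for a nonviolent crime).
effective_outcome <- function(subjects, outcome_type) {
  if (outcome_type == "general") {
    list(ev = subjects$outcome_day, cens = subjects$censor_day)
  } else {
    is_viol <- !is.na(subjects$outcome_day) &
      subjects$outcome_type == "violent"
    ev <- ifelse(is_viol, subjects$outcome_day, NA_real_)
    nonviol <- !is.na(subjects$outcome_day) & !is_viol
    cens <- ifelse(nonviol, subjects$outcome_day, subjects$censor_day)
    list(ev = ev, cens = cens)
  }
}

#' Build the landmark dataset for a single landmark
#'
#' Selects the subjects at risk at day \code{s} (no prior event of the
#' outcome under analysis and no prior censoring; a subject whose event or
#' censoring falls exactly on \code{s} is no longer at risk), attaches the
#' covariate vector appropriate to the model variant, and resolves the
#' outcome within the window \code{(s, s+w]}:
#' \itemize{
#'   \item event in the window: \code{status = 1},
#'     \code{time = outcome_day - s};
#'   \item censored strictly inside \code{(s, s+w)}: the row is removed by
#'     default; with \code{retain_censored = TRUE} it is kept with
#'     \code{status = 0} and \code{time = censor_day - s};
#'   \item otherwise a window survivor: \code{status = 0}, \code{time = w}.
#' }
#' When event and censoring fall on the same day the event wins (convictions
#' are definitive records). Variant \code{"DLM"} rows carry covariates
#' updated to \code{s} plus trigger flags; \code{"FLM"}/\code{"FBL"} rows
#' carry baseline values and no trigger flags.
#'
#' @param cohort a cohort object.
#' @param schedule a [landmark_schedule()].
#' @param s landmark day, must belong to the schedule.
#' @param outcome_type \code{"general"} or \code{"violent"}.
#' @param variant \code{"DLM"}, \code{"FLM"} or \code{"FBL"}.
#' @param retain_censored keep within-window censored rows as censored
#'   observations instead of removing them.
#' @return data.frame with subject_id, landmark, covariate columns, time,
#'   status.
#' @export
build_landmark_dataset <- function(cohort, schedule, s,
                                   outcome_type = c("general", "violent"),
                                   variant = c("DLM", "FLM", "FBL"),
                                   retain_censored = FALSE) {
  outcome_type <- match.arg(outcome_type)
  variant <- match.arg(variant)
  if (!s %in% schedule$landmark_days)
    stop("landmark day ", s, " is not in the schedule")
  w <- schedule$horizon_days
  subj <- cohort$subjects
  eo <- effective_outcome(subj, outcome_type)
  ev <- eo$ev; cs <- eo$cens

  at_risk <- (is.na(ev) | ev > s) & (is.na(cs) | cs > s)
  event_in <- at_risk & !is.na(ev) & ev <= s + w & (is.na(cs) | ev <= cs)
  cens_in <- at_risk & !event_in & !is.na(cs) & cs < s + w
  keep <- if (retain_censored) at_risk else (at_risk & !cens_in)

  sub <- cohort
  sub$subjects <- subj[keep, , drop = FALSE]
  covm <- cov_matrix_at(sub, s, dynamic = (variant == "DLM"))
  out <- data.frame(subject_id = subj$subject_id[keep],
                    landmark = s,
                    covm,
                    stringsAsFactors = FALSE)
  if (variant == "DLM") {
    tm <- trigger_matrix_at(sub, s)
    if (ncol(tm)) out <- cbind(out, tm)
  }
  ev_k <- event_in[keep]
  cens_k <- cens_in[keep] & retain_censored
  time <- ifelse(ev_k, ev[keep] - s, ifelse(cens_k, cs[keep] - s, w))
  out$time <- as.numeric(time)
  out$status <- as.integer(ev_k)
  rownames(out) <- NULL
  out
}

#' Stack per-landmark datasets into a landmark superset
#'
#' The union of the per-landmark datasets over the whole schedule, each row
#' tagged with its landmark, fitted jointly downstream with one coefficient
#' vector and landmark-specific baseline hazards. The \code{"FBL"} variant is
#' restricted to landmark 0.
#'
#' @inheritParams build_landmark_dataset
#' @return data.frame of class \code{landmark_superset} with attributes
#'   \code{variant}, \code{outcome_type}, \code{schedule},
#'   \code{retain_censored} and \code{covariate_names}.
#' @export
stack_superset <- function(cohort, schedule,
                           outcome_type = c("general", "violent"),
                           variant = c("DLM", "FLM", "FBL"),
                           retain_censored = FALSE) {
  outcome_type <- match.arg(outcome_type)
  variant <- match.arg(variant)
  if (nrow(cohort$subjects) == 0L) stop("empty cohort")
  days <- if (variant == "FBL") 0L else schedule$landmark_days
  parts <- lapply(days, function(s)
    build_landmark_dataset(cohort, schedule, s, outcome_type, variant,
                           retain_censored))
  ss <- do.call(rbind, parts)
  covariate_names <- setdiff(names(ss),
                             c("subject_id", "landmark", "time", "status"))
  structure(ss,
            class = c("landmark_superset", "data.frame"),
            variant = variant, outcome_type = outcome_type,
            schedule = schedule, retain_censored = retain_censored,
            covariate_names = covariate_names)
}

# Pull construction metadata off a superset.
superset_meta <- function(ss) {
  list(variant = attr(ss, "variant"),
       outcome_type = attr(ss, "outcome_type"),
       schedule = attr(ss, "schedule"),
       retain_censored = attr(ss, "retain_censored"),
       covariate_names = attr(ss, "covariate_names"))
}

#' Persist a landmark superset as CSV plus a JSON sidecar
#'
#' @param ss a landmark superset.
#' @param path CSV path; the sidecar records schedule, horizon, variant and
#'   construction flags next to it as \code{<path>.json}.
#' @return \code{write_superset} returns \code{path} invisibly;
#'   \code{read_superset} the superset.
#' @export
write_superset <- function(ss, path) {
  utils::write.csv(as.data.frame(ss), path, row.names = FALSE, na = "")
  meta <- superset_meta(ss)
  meta$schedule <- unclass(meta$schedule)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_superset
#' @export
read_superset <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- do.call(landmark_schedule, meta$schedule)
  structure(df, class = c("landmark_superset", "data.frame"),
            variant = meta$variant, outcome_type = meta$outcome_type,
            schedule = sched, retain_censored = meta$retain_censored,
            covariate_names = meta$covariate_names)
}
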