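#' EM estimation of a multivariate normal for incomplete data
#'
#' Fits mean vector and covariance matrix by
#' expectation-maximisation over the observed-data likelihood, assuming
#' values are missing at random. The E-step computes conditional expectations
#' of missing entries and their cross-products given the observed entries
#' under the current normal model; the M-step updates the moments.
#' Iteration stops when the largest absolute parameter change falls below
#' \code{tol}. The observed-data log-likelihood is recorded at every
#' iteration and is non-decreasing.
#'
#' @param data data.frame or matrix of numeric variables, possibly with
#'   \code{NA}s; at least two variables, each observed at least once. A time
#'   index column (e.g. measurement day) can simply be included as one of
#'   the variables.
#' @param tol convergence tolerance on parameters.
#' @param max_iter maximum EM iterations; non-convergence is reported with a
#'   warning, never silently.
#' @param ridge diagonal inflation applied to the initial covariance when it
#'   is not positive definite.
#' @return object of class \code{em_model}: variables, \code{mu},
#'   \code{sigma}, \code{loglik} trace, \code{iterations}, \code{converged}.
#' @export
em_fit <- function(data, tol = 1e-6, max_iter = 500L, ridge = 1e-6) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  p <- ncol(X)
  n <- nrow(X)
  if (p < 2L) stop("need at least 2 variables")
  obs_count <- colSums(!is.na(X))
  if (any(obs_count == 0L))
    stop("every variable must be observed at least once")
  v_obs <- apply(X, 2L, stats::var, na.rm = TRUE)
  if (any(is.na(v_obs)) || any(v_obs == 0))
    stop("degenerate covariance: constant or single-observation column: ",
         paste(colnames(X)[is.na(v_obs) | v_obs == 0], collapse = ", "))

  ## init at complete-case moments, falling back to available-case
  cc <- stats::complete.cases(X)
  if (sum(cc) > p + 1L) {
    mu <- colMeans(X[cc, , drop = FALSE])
    sigma <- stats::cov(X[cc, , drop = FALSE])
  } else {
    mu <- colMeans(X, na.rm = TRUE)
    sigma <- stats::cov(X, use = "pairwise.complete.obs")
    sigma[is.na(sigma)] <- 0
  }
  if (inherits(try(chol(sigma), silent = TRUE), "try-error"))
    sigma <- sigma + diag(ridge + max(diag(sigma)) * 1e-6, p)

  pat_key <- apply(is.na(X), 1L, function(z) paste(as.integer(z),
                                                   collapse = ""))
  pat_rows <- split(seq_len(n), pat_key)
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (rows in pat_rows) {
      miss <- is.na(X[rows[1L], ])
      Xr <- X[rows, , drop = FALSE]
      if (!any(miss)) {
        S1 <- S1 + colSums(Xr)
        S2 <- S2 + crossprod(Xr)
        ll <- ll + sum(dmvnorm_log(Xr, mu, sigma))
        next
      }
      o <- which(!miss); m_ <- which(miss)
      if (length(o) == 0L) {
        Xr[, m_] <- matrix(mu[m_], length(rows), length(m_), byrow = TRUE)
        Cm <- sigma[m_, m_, drop = FALSE]
      } else {
        So_inv_Som <- solve(sigma[o, o, drop = FALSE],
                            sigma[o, m_, drop = FALSE])
        dev <- sweep(Xr[, o, drop = FALSE], 2L, mu[o])
        Xr[, m_] <- matrix(mu[m_], length(rows), length(m_), byrow = TRUE) +
          dev %*% So_inv_Som
        Cm <- sigma[m_, m_, drop = FALSE] -
          crossprod(sigma[o, m_, drop = FALSE], So_inv_Som)
        ll <- ll + sum(dmvnorm_log(Xr[, o, drop = FALSE], mu[o],
                                   sigma[o, o, drop = FALSE]))
      }
      S1 <- S1 + colSums(Xr)
      S2 <- S2 + crossprod(Xr)
      S2[m_, m_] <- S2[m_, m_] + length(rows) * Cm
    }
    mu_new <- S1 / n
    sigma_new <- S2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    delta <- max(abs(c(mu_new - mu, sigma_new - sigma)))
    mu <- mu_new
    sigma <- sigma_new
    loglik <- c(loglik, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  structure(list(variables = colnames(X), mu = mu, sigma = sigma,
                 loglik = loglik, iterations = it, converged = converged,
                 n = n),
            class = "em_model")
}

# Log-density of rows of X under N(mu, sigma).
dmvnorm_log <- function(X, mu, sigma) {
  X <- as.matrix(X)
  R <- chol(sigma)
  dev <- sweep(X, 2L, mu)
  z <- dev %*% backsolve(R, diag(ncol(X)))
  -0.5 * rowSums(z^2) - sum(log(diag(R))) -
    0.5 * ncol(X) * log(2 * pi)
}

#' @export
print.em_model <- function(x, ...) {
  cat(sprintf("EM multivariate-normal model: %d variables, %d rows, %d iterations (%s)\n",
              length(x$variables), x$n, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Draw multiple imputations from a fitted EM model
#'
#' Missing entries are drawn from their conditional normal given the observed
#' entries in the same row; observed entries are never touched. Variables
#' whose observed values are all 0/1 are thresholded at 0.5 after the draw,
#' so imputed binary columns stay binary.
#'
#' @param model an [em_fit()] result.
#' @param data the data the model was fitted on (same variables).
#' @param m number of imputations, at least 2.
#' @param seed RNG seed; identical seed gives identical draws.
#' @param binary_cols optional character vector overriding the automatic
#'   binary-column detection.
#' @return list of m completed data.frames.
#' @export
draw_imputations <- function(model, data, m = 5L, seed = 1L,
                             binary_cols = NULL) {
  if (m < 2L) stop("m must be at least 2")
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (!identical(colnames(X), model$variables))
    stop("data variables do not match the fitted model")
  if (is.null(binary_cols)) {
    binary_cols <- colnames(X)[apply(X, 2L, function(v)
      all(stats::na.omit(v) %in% c(0, 1)))]
  }
  set.seed(seed)
  mu <- model$mu; sigma <- model$sigma
  pat_key <- apply(is.na(X), 1L, function(z) paste(as.integer(z),
                                                   collapse = ""))
  pat_rows <- split(seq_len(nrow(X)), pat_key)
  out <- replicate(m, X, simplify = FALSE)
  for (rows in pat_rows) {
    miss <- is.na(X[rows[1L], ])
    if (!any(miss)) next
    o <- which(!miss); m_ <- which(miss)
    if (length(o)) {
      So_inv_Som <- solve(sigma[o, o, drop = FALSE],
                          sigma[o, m_, drop = FALSE])
      cond_mu <- matrix(mu[m_], length(rows), length(m_), byrow = TRUE) +
        sweep(X[rows, o, drop = FALSE], 2L, mu[o]) %*% So_inv_Som
      C <- sigma[m_, m_, drop = FALSE] -
        crossprod(sigma[o, m_, drop = FALSE], So_inv_Som)
    } else {
      cond_mu <- matrix(mu[m_], length(rows), length(m_), byrow = TRUE)
      C <- sigma[m_, m_, drop = FALSE]
    }
    C <- (C + t(C)) / 2
    ev <- eigen(C, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)),
                             length(m_)) %*% t(ev$vectors)
    for (k in seq_len(m)) {
      z <- matrix(stats::rnorm(length(rows) * length(m_)),
                  length(rows), length(m_))
      draw <- cond_mu + z %*% A
      bc <- which(colnames(X)[m_] %in% binary_cols)
      if (length(bc)) draw[, bc] <- as.numeric(draw[, bc] >= 0.5)
      out[[k]][rows, m_] <- draw
    }
  }
  lapply(out, as.data.frame)
}

#' Rubin's rules pooling
#'
#' Combines an estimate across m imputed datasets: pooled point estimate
#' \eqn{\bar Q} (mean of the estimates), within-imputation variance W (mean
#' of the variances), between-imputation variance B (sample variance of the
#' estimates), total variance \eqn{T = W + (1 + 1/m)B}, and a two-sided Wald
#' p-value from \eqn{\bar Q / \sqrt{T}} against the standard normal.
#'
#' @param estimates numeric vector of per-imputation estimates (length m >= 2).
#' @param variances numeric vector of per-imputation squared standard errors.
#' @return object of class \code{pooled_estimate}.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances lengths differ")
  if (m < 2L) stop("need at least 2 imputations")
  if (any(variances < 0)) stop("variances must be nonnegative")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tot <- W + (1 + 1 / m) * B
  z <- if (Tot > 0) qbar / sqrt(Tot) else 0
  structure(list(estimate = qbar, within = W, between = B, total = Tot,
                 se = sqrt(Tot), statistic = z,
                 p = 2 * stats::pnorm(-abs(z)), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate %.4g (se %.4g, W %.4g, B %.4g, p %.4g, m=%d)\n",
              x$estimate, x$se, x$within, x$between, x$p, x$m))
  invisible(x)
}

# Build the stacked measurement table used for imputation: one row per
# (subject, measurement day), with sociodemographic values at that day,
# static and clinical covariates as predictors, the measurement day as time
# index, and the outcome indicator. Returns the table plus the bookkeeping
# needed to write imputed values back into a cohort.
measurement_table <- function(cohort) {
  cov <- cohort$config$covariates
  sd_dyn <- cov$name[cov$sociodemo & cov$dynamics != "static"]
  sd_stat <- cov$name[cov$sociodemo & cov$dynamics == "static"]
  clin_dyn <- cov$name[!cov$sociodemo & cov$dynamics != "static"]
  static <- cov$name[!cov$sociodemo & cov$dynamics == "static"]
  subj <- cohort$subjects
  event01 <- as.numeric(!is.na(subj$outcome_day))

  days <- sort(unique(cohort$updates$day))
  mk_row <- function(d) {
    df <- data.frame(subject_id = subj$subject_id, day = d)
    for (v in c(sd_dyn, clin_dyn)) {
      if (d == 0) {
        df[[v]] <- subj[[v]]
      } else {
        u <- cohort$updates
        u <- u[u$name == v & u$day == d, ]
        df[[v]] <- u$value[match(subj$subject_id, u$subject_id)]
      }
    }
    for (v in c(sd_stat, static)) df[[v]] <- subj[[v]]
    df$event <- event01
    df
  }
  tab <- do.call(rbind, lapply(c(0, days), mk_row))
  rownames(tab) <- NULL
  list(table = tab, sd_dyn = sd_dyn, sd_stat = sd_stat)
}

#' EM multiple imputation of a cohort's sociodemographic covariates
#'
#' Stacks baseline and annual measurement records into a single table (with
#' the measurement day as a time index and all covariates plus the outcome
#' indicator as predictors), fits the EM normal model, and draws m completed
#' tables. Imputed sociodemographic values are written back into the cohort:
#' dynamic values into the update records at their measurement day, static
#' ones into the baseline table (taken from the day-0 row).
#'
#' @param cohort a cohort with masked (NA) sociodemographic values.
#' @param m number of imputations.
#' @param seed RNG seed.
#' @param ... passed to [em_fit()].
#' @return list of m completed cohorts. If the cohort has no missing values
#'   the list holds m identical copies.
#' @export
impute_cohort <- function(cohort, m = 5L, seed = 1L, ...) {
  mt <- measurement_table(cohort)
  tab <- mt$table
  vars <- setdiff(names(tab), "subject_id")
  # with a single measurement day the time index is constant: drop it
  if (length(unique(tab$day)) < 2L) vars <- setdiff(vars, "day")
  if (!anyNA(tab[, vars]))
    return(replicate(m, cohort, simplify = FALSE))
  # a column constant among its observed values cannot inform the normal
  # model: impute it with that constant and keep it out of the EM
  const <- vars[vapply(vars, function(v)
    length(unique(stats::na.omit(tab[[v]]))) < 2L, logical(1))]
  for (v in const)
    tab[[v]][is.na(tab[[v]])] <- stats::na.omit(tab[[v]])[1L]
  vars <- setdiff(vars, const)
  model <- em_fit(tab[, vars], ...)
  done <- draw_imputations(model, tab[, vars], m = m, seed = seed)
  done <- lapply(done, function(dk) cbind(dk, tab[, const, drop = FALSE]))
  lapply(done, function(dk) {
    out <- cohort
    base_rows <- which(tab$day == 0)
    for (v in c(mt$sd_dyn, mt$sd_stat)) {
      out$subjects[[v]] <- dk[[v]][base_rows][
        match(out$subjects$subject_id, tab$subject_id[base_rows])]
    }
    if (nrow(out$updates)) {
      for (v in mt$sd_dyn) {
        ur <- which(out$updates$name == v)
        key_u <- paste(out$updates$subject_id[ur], out$updates$day[ur])
        key_t <- paste(tab$subject_id, tab$day)
        out$updates$value[ur] <- dk[[v]][match(key_u, key_t)]
      }
    }
    out
  })
}

#' Backward elimination with Rubin-pooled Wald tests
#'
#' Iteratively refits the Cox supermodel on every imputed superset, pools
#' each candidate coefficient across imputations with Rubin's rules, and
#' removes the candidate with the largest pooled p-value while it exceeds
#' \code{p_threshold}. Forced covariates are never removed. Multi-column
#' blocks (e.g. the three time components of one trigger, or levels of a
#' categorical) can be removed jointly using the maximum of their member
#' p-values via \code{blocks}.
#'
#' The default threshold 0.157 is the two-sided Wald p-value at which
#' dropping one parameter leaves the AIC unchanged, making the procedure
#' AIC-equivalent selection.
#'
#' @param imputed_supersets list of landmark supersets (one per imputation),
#'   identical rows up to imputed covariate values.
#' @param forced covariate names always kept.
#' @param candidates covariate names subject to elimination (disjoint from
#'   \code{forced}).
#' @param p_threshold removal threshold on the pooled p-value.
#' @param blocks optional named list of covariate-name vectors removed as a
#'   unit; candidates not mentioned form singleton blocks.
#' @return list with \code{selected} (covariates retained, forced first) and
#'   \code{trace} (data.frame: step, variable, pooled p, removed).
#' @export
backward_eliminate <- function(imputed_supersets, forced, candidates,
                               p_threshold = 0.157, blocks = NULL) {
  if (length(intersect(forced, candidates)))
    stop("forced and candidate sets must be disjoint")
  if (length(candidates) == 0L) {
    return(list(selected = forced,
                trace = data.frame(step = integer(0), variable = character(0),
                                   p = numeric(0), removed = logical(0))))
  }
  blk <- blocks
  singles <- setdiff(candidates, unlist(blocks))
  blk <- c(blk, stats::setNames(as.list(singles), singles))
  trace <- data.frame(step = integer(0), variable = character(0),
                      p = numeric(0), removed = logical(0))
  step <- 0L
  repeat {
    step <- step + 1L
    current <- c(forced, unlist(blk, use.names = FALSE))
    fits <- tryCatch(
      lapply(imputed_supersets, fit_cox_supermodel, covariates = current),
      error = function(e)
        stop("model fit failed at elimination step ", step, ": ",
             conditionMessage(e), call. = FALSE))
    pool_p <- function(term) {
      est <- vapply(fits, function(f) f$coef[[term]], numeric(1))
      va <- vapply(fits, function(f) diag(f$vcov)[[term]], numeric(1))
      pool_rubin(est, va)$p
    }
    block_p <- vapply(blk, function(members)
      max(vapply(members, pool_p, numeric(1))), numeric(1))
    worst <- which.max(block_p)
    if (block_p[worst] > p_threshold) {
      trace <- rbind(trace,
                     data.frame(step = step, variable = names(blk)[worst],
                                p = block_p[worst], removed = TRUE))
      blk <- blk[-worst]
      if (length(blk) == 0L) break
    } else break
  }
  list(selected = c(forced, unlist(blk, use.names = FALSE)), trace = trace)
}
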