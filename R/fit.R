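# Per-subject maximum-likelihood estimation of the CPT parameters.
#
# The likelihood is the product over usable (non-timeout) trials of the
# logistic choice probability of the observed choice, with utilities from the
# CPT value and weighting functions. Optimization runs over log-parameters
# (positivity by construction) with box bounds and a fixed multi-start
# schedule; the optimum is the subject's estimate.

# Join one subject's records with the task and precompute everything the
# likelihood needs. Trials are ordered by trial_id so fits are invariant to
# record order.
make_subject_data <- function(records, task) {
  usable <- !is.na(records$choice) & !(records$timeout %in% TRUE)
  records <- records[usable, , drop = FALSE]
  records <- records[order(records$trial_id), , drop = FALSE]
  idx <- match(records$trial_id, task$trial_id)
  if (anyNA(idx))
    stop("records reference trial_ids absent from the task", call. = FALSE)
  t <- task[idx, , drop = FALSE]
  list(ax = t$ax, ay = t$ay, ap = t$ap, bx = t$bx, by = t$by, bp = t$bp,
       mixed = t$trial_type == "MIXED", chose_a = records$choice == "A",
       n = nrow(records))
}

# Fast negative log-likelihood over log-parameters eta = log(alpha, lam,
# gamma, delta); algebraically identical to summing -log P(observed choice)
# with cpt_utility/choice_probability trial by trial.
nll_eta <- function(eta, dat, k = 1, clip = 1e-12) {
  a <- exp(eta[1]); l <- exp(eta[2]); g <- exp(eta[3]); d <- exp(eta[4])
  v <- function(x) ifelse(x >= 0, x^a, -l * (-x)^a)
  w <- function(p) {
    la <- log(d) + g * log(p)
    lb <- g * log1p(-p)
    1 / (1 + exp(lb - la))
  }
  wa <- w(dat$ap); wb <- w(dat$bp)
  fa <- wa * v(dat$ax)
  fb <- wb * v(dat$bx)
  cwa <- ifelse(dat$mixed, w(1 - dat$ap), 1 - wa)
  cwb <- ifelse(dat$mixed, w(1 - dat$bp), 1 - wb)
  fa <- fa + cwa * v(dat$ay)
  fb <- fb + cwb * v(dat$by)
  pr <- stats::plogis(k * ifelse(dat$chose_a, fa - fb, fb - fa))
  -sum(log(pmin(pmax(pr, clip), 1 - clip)))
}

#' Negative log-likelihood of choice records under given CPT parameters
#'
#' Sums `-log P(observed choice)` over a subject's usable (non-timeout)
#' trials, with choice probabilities from the logistic rule on the CPT
#' utilities of each trial's gamble pair. Probabilities are clipped away from
#' 0/1 so the result is finite for all positive parameters.
#'
#' @param records data.frame of one subject's choices (`trial_id`, `choice`,
#'   optionally `timeout`).
#' @param task the `mdm_task` the choices were made on.
#' @param params a [cpt_params()].
#' @return Negative log-likelihood in nats (>= 0).
#' @export
cpt_nll <- function(records, task, params) {
  params <- as_cpt_params(params)
  if (is.null(records$timeout)) records$timeout <- FALSE
  dat <- make_subject_data(records, task)
  if (dat$n == 0L)
    stop("no usable (non-timeout) trials for this subject", call. = FALSE)
  nll_eta(log(unclass(params)[c("alpha", "lam", "gamma", "delta")]), dat,
          k = params[["k"]])
}

#' Optimizer settings for CPT fitting
#'
#' @param min_trials minimum usable trials required to fit a subject.
#' @param n_starts number of multi-start initial points: a fixed schedule of
#'   identity, conventional-magnitude and box-corner starts, padded with
#'   seeded jitter.
#' @param seed seed for the jittered starts (fits are deterministic given it).
#' @param lower,upper box bounds on each parameter (natural scale).
#' @param k choice sensitivity; fixed at 1 in the standard model, exposed for
#'   sensitivity analysis only.
#' @param compute_se compute per-parameter standard errors from the numerical
#'   Hessian at the optimum?
#' @return List of class `fit_settings`.
#' @export
fit_settings <- function(min_trials = 50L, n_starts = 8L, seed = 1L,
                         lower = 0.05, upper = 20, k = 1,
                         compute_se = FALSE) {
  structure(list(min_trials = as.integer(min_trials),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 lower = lower, upper = upper, k = k,
                 compute_se = isTRUE(compute_se)),
            class = "fit_settings")
}

# Multi-start schedule on the log scale: identity, conventional CPT
# magnitudes, box-corner mixes, then seeded jitter.
start_points <- function(settings) {
  fixed <- rbind(
    c(0, 0, 0, 0),
    log(c(0.85, 1.3, 0.7, 0.9)),
    log(c(0.4, 0.4, 0.4, 0.4)),
    log(c(2.5, 2.5, 2.5, 2.5)),
    log(c(0.4, 2.5, 0.4, 2.5)),
    log(c(2.5, 0.4, 2.5, 0.4))
  )
  n <- settings$n_starts
  if (n <= nrow(fixed)) return(fixed[seq_len(n), , drop = FALSE])
  extra <- with_seed(settings$seed,
                     matrix(stats::runif((n - nrow(fixed)) * 4L,
                                         log(0.2), log(5)),
                            ncol = 4L))
  rbind(fixed, extra)
}

#' Fit the CPT model to one subject's choices by maximum likelihood
#'
#' Minimizes the choice negative log-likelihood over `log(alpha)`,
#' `log(lam)`, `log(gamma)`, `log(delta)` with box bounds, from a fixed
#' multi-start schedule; the best local optimum is returned. Fits are
#' deterministic given the settings seed and invariant to trial order.
#'
#' @param records one subject's choice records (`trial_id`, `choice`,
#'   optionally `timeout`); timeouts are excluded from the likelihood.
#' @param task the `mdm_task` the choices were made on.
#' @param settings a [fit_settings()].
#' @param subject_id optional label carried into the result.
#' @return An object of class `cpt_fit` with components `params`
#'   (a [cpt_params()]), `neg_log_lik`, `n_trials_used`, `converged`,
#'   `n_restarts_used`, `std_errors` (natural scale, when requested),
#'   `subject_id`. Supports `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `residuals`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' task <- generate_task(0)
#' truth <- data.frame(subject_id = "S1", alpha = 0.8, lam = 1.3,
#'                     gamma = 0.7, delta = 0.9)
#' ds <- simulate_choices(task, truth, seed = 1)
#' fit <- cpt_fit(ds, task)
#' coef(fit)
#' }
#' @export
cpt_fit <- function(records, task, settings = fit_settings(),
                    subject_id = NULL) {
  if (is.null(records$timeout)) records$timeout <- FALSE
  dat <- make_subject_data(records, task)
  if (dat$n < settings$min_trials)
    stop(sprintf("only %d usable trials (< min_trials = %d)", dat$n,
                 settings$min_trials), call. = FALSE)
  lo <- rep(log(settings$lower), 4L); hi <- rep(log(settings$upper), 4L)
  obj <- function(eta) nll_eta(eta, dat, k = settings$k)
  starts <- start_points(settings)
  best <- NULL; any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(stats::nlminb(pmin(pmax(starts[i, ], lo), hi), obj,
                                  lower = lo, upper = hi),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  theta <- exp(best$par)
  se <- NULL
  if (settings$compute_se) {
    H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0))
        se <- theta * sqrt(diag(V))  # delta method from the log scale
    }
    if (!is.null(se)) names(se) <- c("alpha", "lam", "gamma", "delta")
  }
  structure(list(
    subject_id = subject_id %||% records$subject_id[1] %||% NA_character_,
    params = cpt_params(theta[1], theta[2], theta[3], theta[4],
                        k = settings$k),
    neg_log_lik = best$objective,
    n_trials_used = dat$n,
    converged = any_conv && best$convergence == 0,
    n_restarts_used = nrow(starts),
    std_errors = se,
    records = records, task = task, settings = settings
  ), class = "cpt_fit")
}

#' @export
print.cpt_fit <- function(x, digits = 4, ...) {
  cat("CPT maximum-likelihood fit",
      if (!is.na(x$subject_id)) paste0(" (subject ", x$subject_id, ")"),
      "\n", sep = "")
  print(round(unclass(x$params)[c("alpha", "lam", "gamma", "delta")], digits))
  cat("negative log-likelihood: ", format(round(x$neg_log_lik, digits)),
      " on ", x$n_trials_used, " trials; converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.cpt_fit <- function(object, ...) {
  unclass(object$params)[c("alpha", "lam", "gamma", "delta")]
}

#' @export
logLik.cpt_fit <- function(object, ...) {
  structure(-object$neg_log_lik, df = 4L, nobs = object$n_trials_used,
            class = "logLik")
}

#' @export
summary.cpt_fit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est, row.names = names(est))
  if (!is.null(object$std_errors)) tab$std_error <- object$std_errors[names(est)]
  out <- list(subject_id = object$subject_id, table = tab,
              neg_log_lik = object$neg_log_lik,
              n_trials_used = object$n_trials_used,
              converged = object$converged)
  class(out) <- "summary.cpt_fit"
  out
}

#' @export
print.summary.cpt_fit <- function(x, digits = 4, ...) {
  cat("CPT fit summary",
      if (!is.na(x$subject_id)) paste0(" (subject ", x$subject_id, ")"),
      "\n", sep = "")
  print(round(x$table, digits))
  cat("NLL ", format(round(x$neg_log_lik, digits)), " on ", x$n_trials_used,
      " trials; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Predicted choice probabilities from a CPT fit
#'
#' @param object a `cpt_fit`.
#' @param newdata a task table; defaults to the task the fit used.
#' @param ... unused.
#' @return Numeric vector: P(choose A) for each trial of `newdata`.
#' @export
predict.cpt_fit <- function(object, newdata = NULL, ...) {
  task <- newdata %||% object$task
  u <- task_utilities(task, object$params)
  choice_probability(u[, "a"], u[, "b"], object$params)
}

#' @export
residuals.cpt_fit <- function(object, ...) {
  rec <- object$records
  if (is.null(rec$timeout)) rec$timeout <- FALSE
  rec <- rec[!is.na(rec$choice) & !(rec$timeout %in% TRUE), , drop = FALSE]
  rec <- rec[order(rec$trial_id), , drop = FALSE]
  p <- predict(object)[match(rec$trial_id, object$task$trial_id)]
  as.numeric(rec$choice == "A") - p
}

#' Simulate choices from a fitted CPT model
#'
#' @param object a `cpt_fit`.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of `choice_dataset`s of length `nsim` (a single dataset if
#'   `nsim = 1`).
#' @export
simulate.cpt_fit <- function(object, nsim = 1, seed = 0L, ...) {
  pars <- data.frame(subject_id = object$subject_id %||% "S1",
                     t(coef(object)))
  sims <- lapply(seq_len(nsim), function(i)
    simulate_choices(object$task, pars, seed = derive_seed(seed, paste0("sim", i))))
  if (nsim == 1) sims[[1]] else sims
}

#' Fit a cohort subject by subject (two-stage, stage one)
#'
#' Runs [cpt_fit()] for every subject in a choice dataset; subjects with
#' fewer usable trials than `settings$min_trials` are skipped and listed.
#' The per-subject estimates are the input to the second-stage group
#' statistics ([cpt_group_tests()], [one_sample_test_vs_one()], ...).
#'
#' @param dataset a `choice_dataset`.
#' @param task the task; defaults to `attr(dataset, "task")`.
#' @param settings a [fit_settings()].
#' @return An object of class `cpt_cohort`: list with `fits` (named list of
#'   `cpt_fit`), `table` (one row per subject: `subject_id`, `group`,
#'   `alpha`, `lam`, `gamma`, `delta`, `nll`, `n_trials`, `converged`) and
#'   `skipped`.
#' @export
cpt_fit_cohort <- function(dataset, task = NULL, settings = fit_settings()) {
  task <- task %||% attr(dataset, "task")
  if (is.null(task)) stop("no task supplied or attached", call. = FALSE)
  ids <- unique(dataset$subject_id)
  fits <- list(); skipped <- character()
  for (id in ids) {
    rec <- dataset[dataset$subject_id == id, , drop = FALSE]
    usable <- sum(!is.na(rec$choice) & !(rec$timeout %in% TRUE))
    if (usable < settings$min_trials) {
      skipped <- c(skipped, id)
      next
    }
    fits[[id]] <- cpt_fit(rec, task, settings, subject_id = id)
  }
  grp <- dataset$group[match(names(fits), dataset$subject_id)]
  tab <- data.frame(
    subject_id = names(fits),
    group = grp,
    t(vapply(fits, coef, numeric(4L))),
    nll = vapply(fits, function(f) f$neg_log_lik, numeric(1L)),
    n_trials = vapply(fits, function(f) f$n_trials_used, numeric(1L)),
    converged = vapply(fits, function(f) f$converged, logical(1L)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, skipped = skipped,
                 settings = settings, task = task),
            class = "cpt_cohort")
}

#' @export
print.cpt_cohort <- function(x, ...) {
  cat("Two-stage CPT cohort fit: ", nrow(x$table), " subjects fitted",
      if (length(x$skipped)) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  print(utils::head(x$table, 6))
  if (nrow(x$table) > 6) cat("...\n")
  invisible(x)
}

#' @export
coef.cpt_cohort <- function(object, ...) object$table

#' @export
summary.cpt_cohort <- function(object, ...) {
  tab <- object$table
  agg <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               alpha = mean(d$alpha), lam = mean(d$lam),
               gamma = mean(d$gamma), delta = mean(d$delta))
  }))
  rownames(agg) <- NULL
  structure(list(group_means = agg, n_skipped = length(object$skipped)),
            class = "summary.cpt_cohort")
}

#' @export
print.summary.cpt_cohort <- function(x, digits = 4, ...) {
  cat("Group means of per-subject CPT estimates:\n")
  agg <- x$group_means
  agg[, -(1:2)] <- round(agg[, -(1:2)], digits)
  print(agg)
  if (x$n_skipped) cat(x$n_skipped, "subjects skipped (too few trials)\n")
  invisible(x)
}

#' Write per-subject fits as CSV plus a JSON run manifest
#'
#' @param cohort a `cpt_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fits <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "fits.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  manifest <- list(settings = unclass(cohort$settings),
                   n_subjects = nrow(cohort$table),
                   skipped = cohort$skipped,
                   package_version = as.character(utils::packageVersion("mdmcpt")))
  jsonlite::write_json(manifest, file.path(dir, "fit_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
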