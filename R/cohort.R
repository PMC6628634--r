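# Synthetic cohort simulation: group specifications, per-subject parameter
# draws, Bernoulli choice simulation under the logistic CPT choice rule, and
# dataset (de)serialization.

#' Group specification for cohort simulation
#'
#' Describes one participant group: its size, the group-level location of each
#' CPT parameter, log-scale dispersions for the per-subject random effects,
#' and (optionally) clinical-scale distributions with a requested correlation
#' between one parameter and one scale.
#'
#' @param label group name, e.g. `"HC"`, `"GAD"`, `"SAD"`, `"OCD"`.
#' @param n_subjects number of subjects, >= 1.
#' @param param_means [cpt_params()]-shaped group locations (natural scale).
#' @param param_sds named numeric; log-scale SD of each of `alpha`, `lam`,
#'   `gamma`, `delta` (0 collapses every subject onto the group mean).
#' @param clinical_means,clinical_sds optional named numerics over clinical
#'   scales (e.g. `PHQ9`, `GAD7`, `BDI`, `WSAS`); scores are drawn normal,
#'   truncated at 0.
#' @param param_clinical_corr optional list `list(param =, scale =, r =)`
#'   requesting correlation `r` between a parameter's log-deviation and a
#'   clinical scale.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(label, n_subjects,
                       param_means = cpt_params(alpha = 0.85, lam = 1.3,
                                                gamma = 0.7, delta = 0.9),
                       param_sds = c(alpha = 0.15, lam = 0.15,
                                     gamma = 0.15, delta = 0.15),
                       clinical_means = NULL, clinical_sds = NULL,
                       param_clinical_corr = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(param_sds < 0)) stop("param_sds must be >= 0", call. = FALSE)
  if (!is.null(param_clinical_corr)) {
    r <- param_clinical_corr$r
    if (abs(r) > 1) stop("correlation must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 param_means = as_cpt_params(param_means),
                 param_sds = param_sds[c("alpha", "lam", "gamma", "delta")],
                 clinical_means = clinical_means, clinical_sds = clinical_sds,
                 param_clinical_corr = param_clinical_corr),
            class = "group_spec")
}

#' Default four-group cohort specification
#'
#' The cohort shape the analysis was designed around: healthy controls
#' (HC, n = 20), generalized anxiety disorder (GAD, n = 15), social anxiety
#' disorder (SAD, n = 14) and obsessive-compulsive disorder (OCD, n = 10).
#' Group parameter means are identical (alpha 0.85, lambda 1.3, gamma 0.7,
#' delta 0.9 — conventional CPT magnitudes) except that the OCD group's value
#' discrimination is lowered to `ocd_alpha`, mirroring the qualitative
#' group difference the model is meant to detect. Clinical-scale means/SDs
#' (PHQ-9, GAD-7, BDI, WSAS) default to the published per-group summary
#' statistics.
#'
#' @param ocd_alpha value-discrimination mean for the OCD group.
#' @param hc_alpha value-discrimination mean for the other groups.
#' @param log_sd common log-scale random-effect SD for all four parameters.
#' @return List of four [group_spec()] objects.
#' @export
default_groups <- function(ocd_alpha = 0.55, hc_alpha = 0.85, log_sd = 0.15) {
  sds <- c(alpha = log_sd, lam = log_sd, gamma = log_sd, delta = log_sd)
  clin <- list(
    HC  = list(m = c(PHQ9 = 1.3, GAD7 = 0.9, BDI = 2.7, WSAS = 0.1),
               s = c(PHQ9 = 2.2, GAD7 = 1.4, BDI = 4.9, WSAS = 0.7)),
    GAD = list(m = c(PHQ9 = 10.2, GAD7 = 14.5, BDI = 22.1, WSAS = 19.1),
               s = c(PHQ9 = 6.6, GAD7 = 6.0, BDI = 13.5, WSAS = 11.0)),
    SAD = list(m = c(PHQ9 = 10.1, GAD7 = 11.8, BDI = 16.4, WSAS = 20.4),
               s = c(PHQ9 = 6.2, GAD7 = 5.1, BDI = 8.5, WSAS = 8.1)),
    OCD = list(m = c(PHQ9 = 11.6, GAD7 = 11.5, BDI = 22.8, WSAS = 22.1),
               s = c(PHQ9 = 8.7, GAD7 = 6.6, BDI = 13.9, WSAS = 9.4))
  )
  mk <- function(label, n, alpha) {
    group_spec(label, n,
               param_means = cpt_params(alpha = alpha, lam = 1.3,
                                        gamma = 0.7, delta = 0.9),
               param_sds = sds,
               clinical_means = clin[[label]]$m,
               clinical_sds = clin[[label]]$s)
  }
  list(mk("HC", 20L, hc_alpha), mk("GAD", 15L, hc_alpha),
       mk("SAD", 14L, hc_alpha), mk("OCD", 10L, ocd_alpha))
}

#' Draw per-subject CPT parameters for a group
#'
#' Each parameter is drawn log-normally: `log(theta_ik) ~ N(log(mean_k),
#' sd_k)`, which guarantees positivity; with dispersion 0 every subject
#' equals the group mean. The standardized log-deviations are kept (attribute
#' `"z"`) so clinical scores can be drawn with a requested correlation.
#'
#' @param group a [group_spec()].
#' @param seed RNG seed.
#' @return data.frame with columns `subject_id`, `group`, `alpha`, `lam`,
#'   `gamma`, `delta`.
#' @export
draw_subject_params <- function(group, seed = 0L) {
  with_seed(seed, {
    n <- group$n_subjects
    mu <- log(unclass(group$param_means)[c("alpha", "lam", "gamma", "delta")])
    z <- matrix(stats::rnorm(n * 4L), n, 4L,
                dimnames = list(NULL, names(mu)))
    th <- exp(sweep(sweep(z, 2L, group$param_sds[names(mu)], `*`),
                    2L, mu, `+`))
    out <- data.frame(subject_id = sprintf("%s%02d", group$label, seq_len(n)),
                      group = group$label, th,
                      stringsAsFactors = FALSE)
    attr(out, "z") <- z
    out
  })
}

# Clinical scores for one group given its drawn parameters: normal, truncated
# at 0; one (param, scale) pair may share variance with the parameter's
# standardized log-deviation at the requested correlation.
draw_clinical_scores <- function(group, params, seed = 0L) {
  if (is.null(group$clinical_means)) return(NULL)
  with_seed(seed, {
    n <- nrow(params)
    scales <- names(group$clinical_means)
    z <- attr(params, "z")
    out <- data.frame(subject_id = params$subject_id, group = group$label,
                      stringsAsFactors = FALSE)
    for (sc in scales) {
      eps <- stats::rnorm(n)
      cc <- group$param_clinical_corr
      if (!is.null(cc) && identical(cc$scale, sc) && !is.null(z)) {
        zp <- z[, cc$param]
        eps <- cc$r * zp + sqrt(1 - cc$r^2) * eps
      }
      out[[sc]] <- pmax(0, group$clinical_means[[sc]] +
                           group$clinical_sds[[sc]] * eps)
    }
    out
  })
}

#' Simulate choices on a task
#'
#' For each subject, every non-timeout choice is a Bernoulli draw: gamble A
#' is chosen with the logistic choice probability computed from the CPT
#' utilities of the trial's two gambles under that subject's parameters.
#' Timeouts occur independently at `timeout_rate` and carry no choice.
#' Deterministic benchmark policies are available for optimality analyses:
#' `"ev_max"` always picks the gamble with the higher expected value,
#' `"random"` picks uniformly.
#'
#' @param task an `mdm_task` table.
#' @param params_by_subject data.frame with columns `subject_id`, `alpha`,
#'   `lam`, `gamma`, `delta` (and optionally `group`), one row per subject,
#'   as from [draw_subject_params()].
#' @param seed RNG seed.
#' @param timeout_rate per-trial timeout probability in `[0, 1)`.
#' @param policy `"cpt"` (default), `"ev_max"` or `"random"`.
#' @return A `choice_dataset`: data.frame with columns `subject_id`, `group`,
#'   `trial_id`, `choice` (`"A"`/`"B"`, `NA` on timeout), `timeout`;
#'   attributes `task`, `true_params`.
#' @export
simulate_choices <- function(task, params_by_subject, seed = 0L,
                             timeout_rate = 0, policy = c("cpt", "ev_max",
                                                          "random")) {
  policy <- match.arg(policy)
  stopifnot(timeout_rate >= 0, timeout_rate < 1)
  ev_a <- gamble_ev(task$ax, task$ay, task$ap)
  ev_b <- gamble_ev(task$bx, task$by, task$bp)
  nt <- nrow(task)
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(params_by_subject)), function(i) {
      row <- params_by_subject[i, ]
      p_a <- switch(policy,
        cpt = {
          u <- task_utilities(task, cpt_params(row$alpha, row$lam,
                                               row$gamma, row$delta))
          choice_probability(u[, "a"], u[, "b"])
        },
        ev_max = as.numeric(ev_a > ev_b),
        random = rep(0.5, nt))
      choice <- ifelse(stats::runif(nt) < p_a, "A", "B")
      timeout <- stats::runif(nt) < timeout_rate
      choice[timeout] <- NA_character_
      data.frame(subject_id = row$subject_id,
                 group = if ("group" %in% names(row)) row$group else NA_character_,
                 trial_id = task$trial_id, choice = choice, timeout = timeout,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    class(out) <- c("choice_dataset", "data.frame")
    attr(out, "task") <- task
    attr(out, "true_params") <- as.data.frame(params_by_subject)
    out
  })
}

#' Simulate a full multi-group cohort
#'
#' Draws per-subject parameters for each group, simulates all choices on the
#' task, and (when the group specs carry clinical distributions) draws
#' per-subject clinical scores. Subject ids are disjoint across groups;
#' per-group seeds are derived deterministically from `seed`.
#'
#' @param groups list of [group_spec()]s; defaults to [default_groups()].
#' @param task an `mdm_task`; defaults to `generate_task(seed)`.
#' @param seed master RNG seed.
#' @param timeout_rate per-trial timeout probability.
#' @return A `choice_dataset` with attributes `task`, `true_params`,
#'   `clinical_scores`.
#' @examples
#' \donttest{
#' ds <- simulate_cohort(seed = 1)
#' nrow(ds)  # 59 subjects x 126 trials
#' }
#' @export
simulate_cohort <- function(groups = default_groups(), task = NULL,
                            seed = 0L, timeout_rate = 0) {
  if (is.null(task)) task <- generate_task(seed)
  parts <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    s_par <- derive_seed(seed, paste0("params:", g$label, gi))
    s_cho <- derive_seed(seed, paste0("choices:", g$label, gi))
    s_cli <- derive_seed(seed, paste0("clinical:", g$label, gi))
    pars <- draw_subject_params(g, s_par)
    ds <- simulate_choices(task, pars, s_cho, timeout_rate)
    list(ds = ds, pars = pars,
         clin = draw_clinical_scores(g, pars, s_cli))
  })
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$ds)))
  rownames(out) <- NULL
  class(out) <- c("choice_dataset", "data.frame")
  attr(out, "task") <- task
  tp <- do.call(rbind, lapply(parts, function(p) {
    df <- p$pars; attr(df, "z") <- NULL; df
  }))
  rownames(tp) <- NULL
  attr(out, "true_params") <- tp
  clin <- do.call(rbind, Filter(Negate(is.null),
                                lapply(parts, function(p) p$clin)))
  if (!is.null(clin)) rownames(clin) <- NULL
  attr(out, "clinical_scores") <- clin
  out
}

#' Read / write a choice dataset
#'
#' The choice table goes to `choices.csv` (columns `subject_id`, `group`,
#' `trial_id`, `choice`, `timeout`), the task to `task.csv`, and the
#' simulation sidecar (ground-truth parameters and clinical scores, when
#' present) to `sidecar.json` with full numeric precision, so ground truth
#' round-trips losslessly.
#'
#' @param dataset a `choice_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `choice_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset), file.path(dir, "choices.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  task <- attr(dataset, "task")
  if (!is.null(task)) write_task(task, file.path(dir, "task.csv"))
  side <- list(true_params = attr(dataset, "true_params"),
               clinical_scores = attr(dataset, "clinical_scores"))
  side <- Filter(Negate(is.null), side)
  if (length(side))
    jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                         dataframe = "columns", digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ds <- utils::read.csv(file.path(dir, "choices.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  ds$timeout <- as.logical(ds$timeout)
  ds$choice[ds$timeout] <- NA_character_
  class(ds) <- c("choice_dataset", "data.frame")
  task_path <- file.path(dir, "task.csv")
  if (file.exists(task_path)) attr(ds, "task") <- read_task(task_path)
  side_path <- file.path(dir, "sidecar.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$true_params))
      attr(ds, "true_params") <- as.data.frame(side$true_params)
    if (!is.null(side$clinical_scores))
      attr(ds, "clinical_scores") <- as.data.frame(side$clinical_scores)
  }
  ds
}
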