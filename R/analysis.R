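# Second-stage group statistics on fitted parameters and raw choices:
# pooled-variance t-tests with Bonferroni correction, one-sample tests of
# loss aversion against 1, Delta-EV optimality with mixed ANOVA, and
# parameter-clinical correlations.

#' Independent-samples t-test with Cohen's d
#'
#' Two-tailed pooled-variance (Student) t-test — the equal-variance form, so
#' degrees of freedom are `n1 + n2 - 2` — plus Cohen's d on the pooled SD and
#' a 95% CI on the mean difference.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param family_size Bonferroni family size used to report the corrected
#'   alpha (default 1, i.e. uncorrected).
#' @return A one-row data.frame of class `cpt_ttest`: `statistic`, `dof`,
#'   `p_value`, `mean_diff`, `ci_low`, `ci_high`, `cohens_d`,
#'   `corrected_alpha`, `significant`.
#' @export
independent_t_test <- function(sample_a, sample_b, family_size = 1L) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs >= 2 observations", call. = FALSE)
  n1 <- length(sample_a); n2 <- length(sample_b)
  sp2 <- ((n1 - 1) * stats::var(sample_a) + (n2 - 1) * stats::var(sample_b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  alpha_c <- 0.05 / family_size
  out <- data.frame(
    statistic = unname(tt$statistic), dof = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = unname(diff(rev(tt$estimate))),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    cohens_d = unname(diff(rev(tt$estimate))) / sqrt(sp2),
    corrected_alpha = alpha_c, significant = tt$p.value < alpha_c
  )
  class(out) <- c("cpt_ttest", "data.frame")
  out
}

#' One-sample t-test against 1 (loss-aversion null)
#'
#' Tests whether a sample's mean differs from 1 — the natural null for the
#' loss-aversion coefficient, where `lambda = 1` means losses and equivalent
#' gains weigh equally. Cohen's d is `(mean - 1) / sd`.
#'
#' @param sample numeric vector of length >= 2.
#' @param family_size Bonferroni family size for the corrected alpha.
#' @return A one-row data.frame of class `cpt_ttest` (`mean_diff` holds the
#'   sample mean; the CI is on the mean).
#' @examples
#' # reproduces printed-summary arithmetic: t = (m - 1) / (sd / sqrt(n))
#' x <- 1 + 0.437 * scale(rnorm(20))[, 1] + 0.255
#' one_sample_test_vs_one(x)
#' @export
one_sample_test_vs_one <- function(sample, family_size = 1L) {
  if (length(sample) < 2) stop("sample needs >= 2 observations", call. = FALSE)
  s <- stats::sd(sample)
  if (s <= 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(sample, mu = 1)
  alpha_c <- 0.05 / family_size
  out <- data.frame(
    statistic = unname(tt$statistic), dof = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = unname(tt$estimate),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    cohens_d = (mean(sample) - 1) / s,
    corrected_alpha = alpha_c, significant = tt$p.value < alpha_c
  )
  class(out) <- c("cpt_ttest", "data.frame")
  out
}

#' Bonferroni correction
#'
#' Family-wise decisions at corrected threshold `0.05 / family_size`. The
#' family size is always an explicit argument; no threshold is hard-coded.
#'
#' @param p_values numeric vector of p-values.
#' @param family_size number of tests in the family, >= 1.
#' @return List with `corrected_alpha` and logical `significant`.
#' @examples
#' bonferroni(c(0.001, 0.02), family_size = 12)  # threshold 0.05/12
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (family_size < 1) stop("family_size must be >= 1", call. = FALSE)
  alpha_c <- 0.05 / family_size
  list(corrected_alpha = alpha_c, significant = p_values < alpha_c)
}

#' The parameter-wise group comparison battery
#'
#' Compares each patient group against the reference group on each of the
#' four CPT parameters with pooled-variance t-tests — with three patient
#' groups this is the 12-test battery — Bonferroni-corrected at
#' `0.05 / family_size`.
#'
#' @param fit_table per-subject estimates, as `coef()` of a
#'   [cpt_fit_cohort()] result (columns `group`, `alpha`, `lam`, `gamma`,
#'   `delta`).
#' @param ref reference group label (default `"HC"`).
#' @param family_size Bonferroni family size; defaults to the number of tests
#'   performed.
#' @return data.frame, one row per (group, parameter) comparison.
#' @export
cpt_group_tests <- function(fit_table, ref = "HC", family_size = NULL) {
  groups <- setdiff(unique(fit_table$group), ref)
  pn <- c("alpha", "lam", "gamma", "delta")
  family_size <- family_size %||% (length(groups) * length(pn))
  rows <- list()
  for (g in groups) for (p in pn) {
    tt <- independent_t_test(fit_table[[p]][fit_table$group == g],
                             fit_table[[p]][fit_table$group == ref],
                             family_size = family_size)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(comparison = paste(g, "vs", ref), parameter = p),
            as.data.frame(tt))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected-value optimality (Delta-EV) analysis
#'
#' On the equal-probability single-domain trials — where probability
#' weighting is held constant and loss aversion cannot differentiate the
#' gambles — computes each trial's `Delta-EV = EV(chosen) - EV(non-chosen)`
#' and per-subject means by trial type. Higher Delta-EV is more optimal; the
#' ceiling (always choosing the higher-EV gamble) is
#' `max_attainable / n_trials` per trial. Timeout trials are excluded;
#' subjects with no usable subset trials are dropped with a warning.
#'
#' @param dataset a `choice_dataset`.
#' @param task the task; defaults to `attr(dataset, "task")`.
#' @return List of class `delta_ev_summary`: `per_trial` (subject x trial
#'   Delta-EV, long), `per_subject` (mean Delta-EV overall and by type),
#'   `max_attainable` (summed optimal Delta-EV over the subset),
#'   `n_subset_trials`.
#' @export
delta_ev_analysis <- function(dataset, task = NULL) {
  task <- task %||% attr(dataset, "task")
  if (is.null(task)) stop("no task supplied or attached", call. = FALSE)
  sub <- equal_probability_trials(task, single_domain_only = TRUE)
  ev_a <- gamble_ev(sub$ax, sub$ay, sub$ap)
  ev_b <- gamble_ev(sub$bx, sub$by, sub$bp)
  rec <- dataset[dataset$trial_id %in% sub$trial_id &
                   !is.na(dataset$choice) &
                   !(dataset$timeout %in% TRUE), , drop = FALSE]
  idx <- match(rec$trial_id, sub$trial_id)
  rec$delta_ev <- ifelse(rec$choice == "A", ev_a[idx] - ev_b[idx],
                         ev_b[idx] - ev_a[idx])
  rec$trial_type <- sub$trial_type[idx]
  all_ids <- unique(dataset$subject_id)
  missing <- setdiff(all_ids, unique(rec$subject_id))
  if (length(missing))
    warning(length(missing), " subject(s) with no usable subset trials ",
            "excluded: ", paste(missing, collapse = ", "), call. = FALSE)
  per_subject <- do.call(rbind, lapply(split(rec, rec$subject_id), function(d) {
    by_type <- tapply(d$delta_ev, d$trial_type, mean)
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               mean_delta_ev = mean(d$delta_ev),
               mean_gain = unname(by_type["GAIN_ONLY"]),
               mean_loss = unname(by_type["LOSS_ONLY"]),
               n_trials = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_subject) <- NULL
  structure(list(
    per_trial = rec[, c("subject_id", "group", "trial_id", "trial_type",
                        "delta_ev")],
    per_subject = per_subject,
    max_attainable = sum(abs(ev_a - ev_b)),
    n_subset_trials = nrow(sub)
  ), class = "delta_ev_summary")
}

#' @export
print.delta_ev_summary <- function(x, digits = 3, ...) {
  cat("Delta-EV optimality on ", x$n_subset_trials,
      " equal-probability single-domain trials\n", sep = "")
  cat("optimal per-trial Delta-EV (ceiling): ",
      round(x$max_attainable / x$n_subset_trials, digits), "\n", sep = "")
  gm <- tapply(x$per_subject$mean_delta_ev, x$per_subject$group, mean)
  print(round(gm, digits))
  invisible(x)
}

#' Two-way mixed ANOVA (group x trial)
#'
#' Standard between-within decomposition for one between-subject factor
#' (group, two levels) and one within-subject factor (trial): the group main
#' effect is tested against subjects-within-groups, the trial effect and the
#' group x trial interaction against the subject x trial residual. Subjects
#' missing any included trial are dropped listwise. Cohen's d is computed on
#' the per-subject means of the two groups.
#'
#' @param per_trial long data.frame with columns `subject_id`, `group`,
#'   `trial_id` and `value` (e.g. per-trial Delta-EV).
#' @param groups character vector of exactly two group labels to include.
#' @return data.frame of class `mixed_anova`: one row per effect (`group`,
#'   `trial`, `group:trial`) with `F`, `dof1`, `dof2`, `p_value`, plus
#'   attribute `cohens_d`.
#' @export
mixed_anova <- function(per_trial, groups) {
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  d <- per_trial[per_trial$group %in% groups, , drop = FALSE]
  trials <- sort(unique(d$trial_id))
  # listwise deletion: keep subjects with a value for every included trial
  counts <- table(d$subject_id)
  complete <- names(counts)[counts == length(trials)]
  dropped <- setdiff(unique(d$subject_id), complete)
  if (length(dropped))
    warning(length(dropped), " subject(s) dropped listwise (missing trials)",
            call. = FALSE)
  d <- d[d$subject_id %in% complete, , drop = FALSE]
  subj <- factor(d$subject_id); grp <- factor(d$group, levels = groups)
  tri <- factor(d$trial_id)
  y <- d$value
  n_s <- nlevels(subj); n_t <- nlevels(tri)
  if (n_s < 3 || n_t < 2) stop("too few subjects or trials", call. = FALSE)
  grand <- mean(y)
  subj_means <- tapply(y, subj, mean)
  grp_of_subj <- tapply(as.character(grp), subj, `[`, 1L)
  grp_means <- tapply(y, grp, mean)
  tri_means <- tapply(y, tri, mean)
  n_per_grp <- table(grp_of_subj)[levels(grp)]
  # sums of squares for the balanced between-within design
  ss_between_subj <- n_t * sum((subj_means - grand)^2)
  ss_group <- n_t * sum(n_per_grp * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_trial <- n_s * sum((tri_means - grand)^2)
  cell <- tapply(y, list(grp, tri), mean)
  ss_cells <- sum(outer(as.numeric(n_per_grp), rep(1, n_t)) *
                    (cell - grand)^2)
  ss_gt <- ss_cells - ss_group - ss_trial
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_trial - ss_gt
  df_group <- 1L
  df_sw <- n_s - 2L
  df_trial <- n_t - 1L
  df_gt <- df_trial
  df_resid <- df_sw * df_trial
  f_group <- (ss_group / df_group) / (ss_subj_within / df_sw)
  f_trial <- (ss_trial / df_trial) / (ss_resid / df_resid)
  f_gt <- (ss_gt / df_gt) / (ss_resid / df_resid)
  out <- data.frame(
    effect = c("group", "trial", "group:trial"),
    F = c(f_group, f_trial, f_gt),
    dof1 = c(df_group, df_trial, df_gt),
    dof2 = c(df_sw, df_resid, df_resid),
    p_value = c(stats::pf(f_group, df_group, df_sw, lower.tail = FALSE),
                stats::pf(f_trial, df_trial, df_resid, lower.tail = FALSE),
                stats::pf(f_gt, df_gt, df_resid, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  m1 <- subj_means[grp_of_subj == levels(grp)[1]]
  m2 <- subj_means[grp_of_subj == levels(grp)[2]]
  sp <- sqrt(((length(m1) - 1) * stats::var(m1) +
                (length(m2) - 1) * stats::var(m2)) /
               (length(m1) + length(m2) - 2))
  attr(out, "cohens_d") <- (mean(m1) - mean(m2)) / sp
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' Parameter-clinical correlations
#'
#' Pearson correlation between each fitted CPT parameter and each clinical
#' scale across patients, with Bonferroni decisions at `0.05 / family_size`.
#' Constant columns are skipped with a warning.
#'
#' @param fit_table per-subject estimates (columns `subject_id`, `alpha`,
#'   `lam`, `gamma`, `delta`).
#' @param clinical_scores data.frame with `subject_id` plus one column per
#'   scale.
#' @param family_size Bonferroni family size; defaults to the number of
#'   (parameter, scale) pairs.
#' @return data.frame: `parameter`, `scale`, `r`, `dof`, `p_value`,
#'   `corrected_alpha`, `significant`.
#' @export
parameter_clinical_correlations <- function(fit_table, clinical_scores,
                                            family_size = NULL) {
  pn <- c("alpha", "lam", "gamma", "delta")
  scales <- setdiff(names(clinical_scores), c("subject_id", "group"))
  merged <- merge(fit_table[, c("subject_id", pn)],
                  clinical_scores[, c("subject_id", scales)],
                  by = "subject_id")
  if (nrow(merged) < 3) stop("need >= 3 paired observations", call. = FALSE)
  family_size <- family_size %||% (length(pn) * length(scales))
  alpha_c <- 0.05 / family_size
  rows <- list(); skipped <- character()
  for (p in pn) for (sc in scales) {
    x <- merged[[p]]; yv <- merged[[sc]]
    if (stats::sd(x) == 0 || stats::sd(yv) == 0) {
      skipped <- c(skipped, paste(p, "vs", sc))
      next
    }
    ct <- stats::cor.test(x, yv)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, scale = sc, r = unname(ct$estimate),
      dof = unname(ct$parameter), p_value = ct$p.value,
      corrected_alpha = alpha_c, significant = ct$p.value < alpha_c,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("constant column(s); skipped: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate the CPT value and weighting curves
#'
#' Evaluates `v(x)` over `[-value_max, value_max]` and `w(p)` over `[0, 1]`
#' for a set of (group) parameter vectors — the curves conventionally plotted
#' from the group-level fixed effects.
#'
#' @param params_list named list of [cpt_params()] (one per group).
#' @param value_max outcome range half-width (points).
#' @param n_points grid points per curve.
#' @return List of two data.frames: `value` (`group`, `x`, `v`) and
#'   `weight` (`group`, `p`, `w`).
#' @export
cpt_curve_table <- function(params_list, value_max = 200, n_points = 201L) {
  xs <- seq(-value_max, value_max, length.out = n_points)
  ps <- seq(0, 1, length.out = n_points)
  value <- do.call(rbind, lapply(names(params_list), function(g)
    data.frame(group = g, x = xs,
               v = cpt_value(xs, params_list[[g]]),
               stringsAsFactors = FALSE)))
  weight <- do.call(rbind, lapply(names(params_list), function(g)
    data.frame(group = g, p = ps,
               w = cpt_weight(ps, params_list[[g]]),
               stringsAsFactors = FALSE)))
  list(value = value, weight = weight)
}

#' Plot group-level value and weighting functions to files
#'
#' Renders `v(x)` and `w(p)` per group (base graphics) and writes the
#' underlying curve tables as CSV alongside.
#'
#' @param params_list named list of [cpt_params()] (one per group).
#' @param dir output directory.
#' @param value_max outcome range half-width.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the paths written.
#' @export
plot_cpt_functions <- function(params_list, dir, value_max = 200,
                               format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- cpt_curve_table(params_list, value_max = value_max)
  vpath <- file.path(dir, "value_curves.csv")
  wpath <- file.path(dir, "weight_curves.csv")
  utils::write.csv(curves$value, vpath, row.names = FALSE, quote = FALSE)
  utils::write.csv(curves$weight, wpath, row.names = FALSE, quote = FALSE)
  dev <- switch(format, png = grDevices::png, svg = grDevices::svg)
  cols <- stats::setNames(seq_along(params_list) + 1L, names(params_list))
  fig_v <- file.path(dir, paste0("value_function.", format))
  if (format == "png") dev(fig_v, width = 600, height = 600) else dev(fig_v)
  plot(NULL, xlim = c(-value_max, value_max),
       ylim = range(curves$value$v), xlab = "outcome x (points)",
       ylab = "subjective value v(x)", main = "CPT value function")
  abline(h = 0, v = 0, col = "grey80")
  for (g in names(params_list))
    lines(curves$value$x[curves$value$group == g],
          curves$value$v[curves$value$group == g], col = cols[[g]], lwd = 2)
  legend("topleft", legend = names(params_list), col = cols, lwd = 2,
         bty = "n")
  grDevices::dev.off()
  fig_w <- file.path(dir, paste0("weight_function.", format))
  if (format == "png") dev(fig_w, width = 600, height = 600) else dev(fig_w)
  plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "probability p",
       ylab = "decision weight w(p)", main = "CPT weighting function")
  abline(0, 1, col = "grey80")
  for (g in names(params_list))
    lines(curves$weight$p[curves$weight$group == g],
          curves$weight$w[curves$weight$group == g], col = cols[[g]], lwd = 2)
  legend("topleft", legend = names(params_list), col = cols, lwd = 2,
         bty = "n")
  grDevices::dev.off()
  invisible(c(vpath, wpath, fig_v, fig_w))
}

#' Plot a fitted subject's value and weighting functions
#'
#' @param x a `cpt_fit`.
#' @param value_max outcome range half-width.
#' @param ... passed to `plot`.
#' @export
plot.cpt_fit <- function(x, value_max = 200, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  xs <- seq(-value_max, value_max, length.out = 201)
  plot(xs, cpt_value(xs, x$params), type = "l", lwd = 2,
       xlab = "outcome x (points)", ylab = "v(x)",
       main = "value function", ...)
  abline(h = 0, v = 0, col = "grey80")
  ps <- seq(0, 1, length.out = 201)
  plot(ps, cpt_weight(ps, x$params), type = "l", lwd = 2,
       xlab = "p", ylab = "w(p)", main = "weighting function", ...)
  abline(0, 1, col = "grey80")
  invisible(x)
}
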