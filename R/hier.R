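# Penalized hierarchical estimation: a joint fit of all subjects in which
# per-subject log-parameters are shrunk toward their group's fixed effect by
# Gaussian penalties, with random-effect SDs profiled on a coarse grid. This
# approximates a nonlinear mixed-effects fit with group dummy offsets; it is
# a documented approximation to marginal maximum likelihood, not a
# re-implementation of nlme.

#' Settings for the hierarchical CPT fit
#'
#' @param min_trials minimum usable trials per subject.
#' @param max_iter maximum block-coordinate-descent sweeps.
#' @param tol relative convergence tolerance on the profiled objective.
#' @param sd_grid coarse grid on which each parameter's random-effect SD
#'   (log scale) is profiled; the smallest grid point is also the floor used
#'   when the between-subject dispersion degenerates.
#' @param ref_group label of the reference group for dummy offsets; defaults
#'   to `"HC"` when present, else the first group.
#' @param lower,upper box bounds on each parameter (natural scale).
#' @param k choice sensitivity (fixed at 1).
#' @return List of class `hier_settings`.
#' @export
hier_settings <- function(min_trials = 50L, max_iter = 15L, tol = 1e-3,
                          sd_grid = c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8),
                          ref_group = NULL, lower = 0.05, upper = 20, k = 1) {
  structure(list(min_trials = as.integer(min_trials),
                 max_iter = as.integer(max_iter), tol = tol,
                 sd_grid = sort(sd_grid), ref_group = ref_group,
                 lower = lower, upper = upper, k = k),
            class = "hier_settings")
}

#' Hierarchical CPT fit with group dummy offsets
#'
#' Maximizes a penalized joint likelihood: the sum over subjects of the
#' choice negative log-likelihood plus a Gaussian penalty pulling each
#' subject's log-parameters toward their group's fixed effect, with the
#' per-parameter random-effect SDs profiled on a coarse grid. Group fixed
#' effects are parameterized as a reference group plus additive offsets on
#' the log-parameter scale ("dummy" offsets); Wald-type tests on the offsets
#' use the pooled within-group variance of the per-subject conditional
#' estimates.
#'
#' @param dataset a `choice_dataset` with >= 2 subjects in every group.
#' @param task the task; defaults to `attr(dataset, "task")`.
#' @param settings a [hier_settings()].
#' @return Object of class `cpt_hier`: `fixed_effects` (per-group natural
#'   scale), `offsets` (log scale, non-reference groups), `wald` (data.frame
#'   of offset tests), `random_effect_sds`, `subject_blups`,
#'   `total_neg_log_lik` (unpenalized, at the conditional estimates),
#'   `dof_residual`, `converged`.
#' @export
cpt_fit_hierarchical <- function(dataset, task = NULL,
                                 settings = hier_settings()) {
  task <- task %||% attr(dataset, "task")
  if (is.null(task)) stop("no task supplied or attached", call. = FALSE)
  ids <- unique(dataset$subject_id)
  grp <- dataset$group[match(ids, dataset$subject_id)]
  dats <- lapply(ids, function(id)
    make_subject_data(dataset[dataset$subject_id == id, , drop = FALSE], task))
  usable <- vapply(dats, function(d) d$n, integer(1L)) >= settings$min_trials
  ids <- ids[usable]; grp <- grp[usable]; dats <- dats[usable]
  counts <- table(grp)
  if (any(counts < 2L))
    stop("every group needs >= 2 fittable subjects", call. = FALSE)
  groups <- names(counts)
  n <- length(ids)
  pn <- c("alpha", "lam", "gamma", "delta")
  lo <- rep(log(settings$lower), 4L); hi <- rep(log(settings$upper), 4L)

  theta <- matrix(rep(log(c(0.85, 1.3, 0.7, 0.9)), each = n), n, 4L,
                  dimnames = list(ids, pn))
  mu <- do.call(rbind, lapply(groups, function(g)
    colMeans(theta[grp == g, , drop = FALSE])))
  rownames(mu) <- groups
  sigma <- stats::setNames(rep(0.2, 4L), pn)
  floored <- FALSE
  obj_old <- Inf; converged <- FALSE
  for (iter in seq_len(settings$max_iter)) {
    for (i in seq_len(n)) {
      m <- mu[grp[i], ]
      pen_obj <- function(eta)
        nll_eta(eta, dats[[i]], k = settings$k) +
          sum((eta - m)^2 / (2 * sigma^2))
      res <- stats::nlminb(pmin(pmax(theta[i, ], lo), hi), pen_obj,
                           lower = lo, upper = hi)
      theta[i, ] <- res$par
    }
    for (g in groups) mu[g, ] <- colMeans(theta[grp == g, , drop = FALSE])
    dev <- theta - mu[grp, , drop = FALSE]
    raw_sd <- sqrt(colMeans(dev^2))
    if (any(raw_sd < min(settings$sd_grid))) floored <- TRUE
    sigma <- vapply(raw_sd, function(s)
      settings$sd_grid[which.min(abs(settings$sd_grid - max(s, min(settings$sd_grid))))],
      numeric(1L))
    names(sigma) <- pn
    nll_tot <- sum(vapply(seq_len(n), function(i)
      nll_eta(theta[i, ], dats[[i]], k = settings$k), numeric(1L)))
    obj <- nll_tot + sum(dev^2 / (2 * rep(sigma^2, each = n))) +
      n * sum(log(sigma))
    if (abs(obj_old - obj) < settings$tol * (abs(obj) + 1)) {
      converged <- TRUE; break
    }
    obj_old <- obj
  }
  if (floored)
    warning("between-subject dispersion degenerate for at least one ",
            "parameter; random-effect SD floored at ", min(settings$sd_grid),
            call. = FALSE)

  ref <- settings$ref_group %||% if ("HC" %in% groups) "HC" else groups[1]
  others <- setdiff(groups, ref)
  # Wald tests on log-scale offsets, using pooled within-group variance of
  # the conditional (shrunken) estimates; an approximation, documented as such.
  dev <- theta - mu[grp, , drop = FALSE]
  s2 <- colSums(dev^2) / (n - length(groups))
  wald <- NULL
  if (length(others)) {
    wald <- do.call(rbind, lapply(others, function(g) {
      off <- mu[g, ] - mu[ref, ]
      se <- sqrt(s2 * (1 / counts[[g]] + 1 / counts[[ref]]))
      tval <- off / se
      df <- n - length(groups)
      data.frame(group = g, parameter = pn, offset = unname(off),
                 std_error = unname(se), t = unname(tval), dof = df,
                 p_value = unname(2 * stats::pt(-abs(tval), df)),
                 stringsAsFactors = FALSE)
    }))
    rownames(wald) <- NULL
  }
  blups <- data.frame(subject_id = ids, group = grp, exp(theta),
                      stringsAsFactors = FALSE)
  rownames(blups) <- NULL
  nll_tot <- sum(vapply(seq_len(n), function(i)
    nll_eta(theta[i, ], dats[[i]], k = settings$k), numeric(1L)))
  structure(list(
    fixed_effects = exp(mu), reference_group = ref,
    offsets = if (length(others)) mu[others, , drop = FALSE] -
      matrix(mu[ref, ], length(others), 4L, byrow = TRUE,
             dimnames = list(others, pn)) else NULL,
    wald = wald, random_effect_sds = sigma, subject_blups = blups,
    total_neg_log_lik = nll_tot, dof_residual = n - length(groups),
    converged = converged, settings = settings
  ), class = "cpt_hier")
}

#' @export
print.cpt_hier <- function(x, digits = 4, ...) {
  cat("Penalized hierarchical CPT fit (reference group: ",
      x$reference_group, ")\n", sep = "")
  cat("Group fixed effects (natural scale):\n")
  print(round(x$fixed_effects, digits))
  cat("Random-effect SDs (log scale):\n")
  print(round(x$random_effect_sds, digits))
  if (!is.null(x$wald)) {
    cat("Wald tests on group dummy offsets (log scale):\n")
    w <- x$wald
    w[, c("offset", "std_error", "t", "p_value")] <-
      round(w[, c("offset", "std_error", "t", "p_value")], digits)
    print(w)
  }
  invisible(x)
}

#' @export
coef.cpt_hier <- function(object, ...) object$fixed_effects
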