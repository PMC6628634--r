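# MDM task generation, validation, subsetting and (de)serialization.
#
# A task is a data.frame with one row per trial and columns
#   trial_id, trial_type, ax, ay, ap, bx, by, bp
# where (ax, ay, ap) is gamble A -- outcome ax with probability ap, ay with
# 1 - ap -- and likewise for gamble B. Class "mdm_task"; generation settings
# and derived quantities live in attr(task, "metadata").

#' Task generation settings
#'
#' Structural constraints for [generate_task()]. Defaults reproduce the
#' published structure of the 126-trial MDM task: 42 trials per type
#' (gain-only, loss-only, mixed-outcome), 17 trials in which both gambles
#' carry identical probabilities, 14 of them single-domain (7 gain-only,
#' 7 loss-only) and 3 mixed. Outcome values are drawn from a grid of
#' multiples of `value_step` within `[-value_max, value_max]` and
#' probabilities from the five task levels.
#'
#' @param n_per_type trials per trial type.
#' @param eq_gain,eq_loss,eq_mixed number of equal-probability trials of each
#'   type; their sum is the equal-probability census.
#' @param prob_levels admissible probability levels for the `x` outcome.
#' @param value_step grid step for outcome values (points).
#' @param value_max largest absolute outcome value (points).
#' @param ev_gap_min,ev_gap_max band for the absolute expected-value
#'   difference between a trial's two gambles. The lower bound keeps the
#'   EV-optimal choice well defined on every trial; the upper bound keeps a
#'   substantial share of trials near indifference, which is what makes the
#'   stimulus set informative about the subjective value and weighting
#'   functions (a task of one-sidedly dominated pairs identifies none of
#'   them). The default band's mean gap matches the magnitude of the
#'   published per-trial optimality ceiling on the equal-probability subset.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_per_type = 42L, eq_gain = 7L, eq_loss = 7L,
                        eq_mixed = 3L,
                        prob_levels = c(0.05, 0.30, 0.50, 0.70, 0.95),
                        value_step = 5L, value_max = 200L,
                        ev_gap_min = 2.5, ev_gap_max = 40) {
  cfg <- list(n_per_type = as.integer(n_per_type),
              eq_gain = as.integer(eq_gain), eq_loss = as.integer(eq_loss),
              eq_mixed = as.integer(eq_mixed),
              prob_levels = as.numeric(prob_levels),
              value_step = as.integer(value_step),
              value_max = as.integer(value_max),
              ev_gap_min = as.numeric(ev_gap_min),
              ev_gap_max = as.numeric(ev_gap_max))
  if (cfg$n_per_type < 1L)
    stop("task_config: n_per_type must be >= 1", call. = FALSE)
  if (cfg$eq_gain < 0L || cfg$eq_loss < 0L || cfg$eq_mixed < 0L)
    stop("task_config: equal-probability counts must be non-negative",
         call. = FALSE)
  if (max(cfg$eq_gain, cfg$eq_loss, cfg$eq_mixed) > cfg$n_per_type)
    stop("task_config: equal-probability count exceeds trials per type",
         call. = FALSE)
  if (any(cfg$prob_levels <= 0 | cfg$prob_levels >= 1))
    stop("task_config: probability levels must lie strictly inside (0, 1)",
         call. = FALSE)
  if (cfg$value_step < 1L || cfg$value_max < cfg$value_step)
    stop("task_config: invalid value grid", call. = FALSE)
  if (cfg$ev_gap_min <= 0 || cfg$ev_gap_max <= cfg$ev_gap_min)
    stop("task_config: need 0 < ev_gap_min < ev_gap_max", call. = FALSE)
  structure(cfg, class = "task_config")
}

# Draw one gamble of the requested type on the value grid. By convention the
# x outcome (probability p) is the extreme outcome in single-domain gambles
# and the gain in mixed gambles.
sample_gamble <- function(type, p, cfg) {
  pick <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 grids
  grid <- seq(cfg$value_step, cfg$value_max, by = cfg$value_step)
  if (type == "GAIN_ONLY") {
    x <- pick(grid)
    y <- pick(seq(0L, x - cfg$value_step, by = cfg$value_step))
  } else if (type == "LOSS_ONLY") {
    x <- -pick(grid)
    y <- -pick(seq(0L, -x - cfg$value_step, by = cfg$value_step))
  } else {
    x <- pick(grid)
    y <- -pick(grid)
  }
  c(x = x, y = y, p = p)
}

# One trial row: two distinct gambles of one type whose EVs differ by an
# amount inside the configured band.
sample_trial <- function(type, equal_prob, cfg) {
  repeat {
    pa <- sample(cfg$prob_levels, 1L)
    pb <- if (equal_prob) pa else sample(setdiff(cfg$prob_levels, pa), 1L)
    a <- sample_gamble(type, pa, cfg)
    b <- sample_gamble(type, pb, cfg)
    if (all(a == b)) next
    gap <- abs(gamble_ev(a["x"], a["y"], a["p"]) -
               gamble_ev(b["x"], b["y"], b["p"]))
    if (gap < cfg$ev_gap_min || gap > cfg$ev_gap_max) next
    return(data.frame(trial_type = type, ax = a[["x"]], ay = a[["y"]],
                      ap = a[["p"]], bx = b[["x"]], by = b[["y"]],
                      bp = b[["p"]]))
  }
}

#' Generate an MDM task specification
#'
#' Synthesizes a trial table satisfying the published structural constraints
#' of the MDM task (the concrete gamble pairs of the original instrument were
#' never published, so each seed yields one admissible instantiation). Every
#' trial's two gambles differ in expected value by a strictly positive margin,
#' so the EV-optimal choice is always well defined; trial order is a seeded
#' uniform shuffle.
#'
#' The summed optimal Delta-EV over the equal-probability single-domain
#' trials — the ceiling an always-EV-maximizing agent attains on the subset
#' used in the optimality analysis — is recorded in
#' `attr(task, "metadata")$optimal_delta_ev_sum`.
#'
#' @param seed non-negative integer seed; identical seed and config give an
#'   identical task, field for field.
#' @param config a [task_config()].
#' @return A data.frame of class `mdm_task` with columns `trial_id`,
#'   `trial_type`, `ax`, `ay`, `ap`, `bx`, `by`, `bp`.
#' @examples
#' task <- generate_task(seed = 0)
#' nrow(task)                      # 126
#' table(task$trial_type)          # 42 per type
#' @export
generate_task <- function(seed = 0L, config = task_config()) {
  if (!inherits(config, "task_config")) config <- do.call(task_config, config)
  with_seed(seed, {
    types <- c("GAIN_ONLY", "LOSS_ONLY", "MIXED")
    eq_counts <- c(GAIN_ONLY = config$eq_gain, LOSS_ONLY = config$eq_loss,
                   MIXED = config$eq_mixed)
    rows <- list()
    for (ty in types) {
      n_eq <- eq_counts[[ty]]
      for (i in seq_len(n_eq))
        rows[[length(rows) + 1L]] <- sample_trial(ty, TRUE, config)
      for (i in seq_len(config$n_per_type - n_eq))
        rows[[length(rows) + 1L]] <- sample_trial(ty, FALSE, config)
    }
    task <- do.call(rbind, rows)
    task <- task[sample.int(nrow(task)), , drop = FALSE]
    task <- cbind(trial_id = seq_len(nrow(task)), task)
    rownames(task) <- NULL
    class(task) <- c("mdm_task", "data.frame")
    attr(task, "metadata") <- list(
      seed = as.integer(seed),
      config = unclass(config),
      optimal_delta_ev_sum = optimal_delta_ev_sum(task)
    )
    task
  })
}

# Summed |EV(A) - EV(B)| over the equal-probability single-domain trials.
optimal_delta_ev_sum <- function(task) {
  sub <- equal_probability_trials(task, single_domain_only = TRUE)
  sum(abs(gamble_ev(sub$ax, sub$ay, sub$ap) - gamble_ev(sub$bx, sub$by, sub$bp)))
}

#' Validate an MDM task table
#'
#' Checks every structural invariant of the task and returns a report listing
#' each violation (empty when the task conforms). Malformed rows are reported,
#' never raised as errors.
#'
#' @param task a task table (class `mdm_task` or plain data.frame with the
#'   task columns).
#' @param config the [task_config()] the counts are checked against; defaults
#'   to the config the task was generated with, else the standard one.
#' @return Character vector of violation messages, class `task_validation`;
#'   `length(.) == 0` iff the task is valid.
#' @export
validate_task <- function(task, config = NULL) {
  problems <- character()
  need <- c("trial_id", "trial_type", "ax", "ay", "ap", "bx", "by", "bp")
  if (!all(need %in% names(task)))
    return(structure(paste("missing columns:",
                           paste(setdiff(need, names(task)), collapse = ", ")),
                     class = "task_validation"))
  config <- config %||% attr(task, "metadata")$config %||% task_config()
  n_expected <- 3L * config$n_per_type
  if (nrow(task) != n_expected)
    problems <- c(problems, sprintf("expected %d trials, found %d",
                                    n_expected, nrow(task)))
  for (ty in c("GAIN_ONLY", "LOSS_ONLY", "MIXED")) {
    n <- sum(task$trial_type == ty)
    if (n != config$n_per_type)
      problems <- c(problems, sprintf("expected %d %s trials, found %d",
                                      config$n_per_type, ty, n))
  }
  unknown <- setdiff(unique(task$trial_type),
                     c("GAIN_ONLY", "LOSS_ONLY", "MIXED"))
  if (length(unknown))
    problems <- c(problems, paste("unknown trial_type:",
                                  paste(unknown, collapse = ", ")))
  eq <- task$ap == task$bp
  n_eq_expected <- config$eq_gain + config$eq_loss + config$eq_mixed
  n_sd_expected <- config$eq_gain + config$eq_loss
  if (sum(eq) != n_eq_expected)
    problems <- c(problems, sprintf(
      "expected %d equal-probability trials, found %d", n_eq_expected, sum(eq)))
  n_sd <- sum(eq & task$trial_type != "MIXED")
  if (n_sd != n_sd_expected)
    problems <- c(problems, sprintf(
      "expected %d single-domain equal-probability trials, found %d",
      n_sd_expected, n_sd))
  # per-gamble invariants
  for (side in c("a", "b")) {
    x <- task[[paste0(side, "x")]]; y <- task[[paste0(side, "y")]]
    p <- task[[paste0(side, "p")]]
    bad_p <- !p %in% config$prob_levels
    if (any(bad_p))
      problems <- c(problems, sprintf(
        "gamble %s: %d trials with probability outside the task levels",
        toupper(side), sum(bad_p)))
    out <- abs(x) > config$value_max | abs(y) > config$value_max
    if (any(out))
      problems <- c(problems, sprintf(
        "gamble %s: %d trials with outcomes outside [-%d, %d]",
        toupper(side), sum(out), config$value_max, config$value_max))
    ok <- ifelse(task$trial_type == "GAIN_ONLY", x > y & y >= 0,
          ifelse(task$trial_type == "LOSS_ONLY", x < y & y <= 0,
                 x > 0 & y < 0))
    ok[!task$trial_type %in% c("GAIN_ONLY", "LOSS_ONLY", "MIXED")] <- TRUE
    if (any(!ok))
      problems <- c(problems, sprintf(
        "gamble %s: %d trials whose outcome pattern violates the trial type (trial_id %s)",
        toupper(side), sum(!ok),
        paste(utils::head(task$trial_id[!ok], 5L), collapse = ", ")))
  }
  same <- task$ax == task$bx & task$ay == task$by & task$ap == task$bp
  if (any(same))
    problems <- c(problems, sprintf("%d trials with identical gambles A and B",
                                    sum(same)))
  gap <- abs(gamble_ev(task$ax, task$ay, task$ap) -
             gamble_ev(task$bx, task$by, task$bp))
  if (any(gap < 1e-9 & !same))
    problems <- c(problems, sprintf("%d trials with equal expected values",
                                    sum(gap < 1e-9 & !same)))
  if (!is.null(config$ev_gap_min)) {
    off <- gap < config$ev_gap_min - 1e-9 | gap > config$ev_gap_max + 1e-9
    if (any(off))
      problems <- c(problems, sprintf(
        "%d trials with EV gap outside [%g, %g]", sum(off),
        config$ev_gap_min, config$ev_gap_max))
  }
  structure(problems, class = "task_validation")
}

#' @export
print.task_validation <- function(x, ...) {
  if (length(x) == 0) cat("Task conforms to all structural invariants.\n")
  else cat("Task violations:\n", paste0("  - ", x, collapse = "\n"), "\n",
           sep = "")
  invisible(x)
}

#' Equal-probability trial subset
#'
#' Trials in which both gambles carry identical probabilities — the subset
#' that holds probability weighting constant so choices reflect outcome
#' values alone. With `single_domain_only = TRUE`, mixed-outcome trials
#' (where loss aversion can still drive choice) are excluded; this is the
#' subset used in the Delta-EV optimality analysis.
#'
#' @param task a task table.
#' @param single_domain_only drop mixed-outcome trials?
#' @return The matching rows of `task`.
#' @examples
#' task <- generate_task(0)
#' nrow(equal_probability_trials(task))                            # 17
#' nrow(equal_probability_trials(task, single_domain_only = TRUE)) # 14
#' @export
equal_probability_trials <- function(task, single_domain_only = FALSE) {
  keep <- task$ap == task$bp
  if (single_domain_only) keep <- keep & task$trial_type != "MIXED"
  task[keep, , drop = FALSE]
}

#' Read / write a task table as CSV
#'
#' One row per trial, columns `trial_id, trial_type, ax, ay, ap, bx, by, bp`,
#' probabilities as decimals, header row, UTF-8. `write_task` then
#' `read_task` then `write_task` reproduces the file byte for byte.
#'
#' @param task a task table.
#' @param path CSV file path.
#' @return `write_task` returns `path` invisibly; `read_task` returns an
#'   `mdm_task` data.frame (generation metadata is recomputed where possible).
#' @export
write_task <- function(task, path) {
  cols <- c("trial_id", "trial_type", "ax", "ay", "ap", "bx", "by", "bp")
  utils::write.csv(as.data.frame(task)[, cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  task <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  class(task) <- c("mdm_task", "data.frame")
  attr(task, "metadata") <- list(
    optimal_delta_ev_sum = optimal_delta_ev_sum(task))
  task
}
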