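# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# A reduced task (42 trials: 14 per type, 5 equal-probability of which 4
# single-domain) for tests where the full 126-trial task would be slow.
small_task <- function(seed = 0L) {
  generate_task(seed, task_config(n_per_type = 14L, eq_gain = 2L,
                                  eq_loss = 2L, eq_mixed = 1L))
}

# Concatenate `times` copies of a task with fresh trial_ids, emulating a
# longer session on the same stimuli.
repeat_task <- function(task, times) {
  n <- nrow(task)
  big <- do.call(rbind, lapply(seq_len(times), function(i) {
    t2 <- as.data.frame(task)
    t2$trial_id <- t2$trial_id + (i - 1L) * n
    t2
  }))
  class(big) <- c("mdm_task", "data.frame")
  big
}

quick_settings <- fit_settings(min_trials = 10L, n_starts = 3L)

# log-scale vector -> cpt_params
as_pars <- function(eta) {
  eta <- exp(eta)
  cpt_params(eta[1], eta[2], eta[3], eta[4])
}

# Independent brute-force negative log-likelihood: one trial at a time,
# straight from the model formulas, no vectorization shared with the
# implementation under test.
nll_brute <- function(records, task, params) {
  records <- records[!is.na(records$choice) &
                       !(records$timeout %in% TRUE), , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(records))) {
    tr <- task[task$trial_id == records$trial_id[i], ]
    fa <- cpt_utility(tr$ax, tr$ay, tr$ap, tr$trial_type, params)
    fb <- cpt_utility(tr$bx, tr$by, tr$bp, tr$trial_type, params)
    # P(observed) straight from the logistic rule; evaluating the chosen
    # side directly (rather than 1 - P(other)) avoids cancellation in the
    # saturated tail
    p_obs <- if (records$choice[i] == "A")
      1 / (1 + exp(params[["k"]] * (fb - fa)))
    else
      1 / (1 + exp(params[["k"]] * (fa - fb)))
    p_obs <- min(max(p_obs, 1e-12), 1 - 1e-12)
    total <- total - log(p_obs)
  }
  total
}

# Random gambles with a consistent trial type, for property sweeps.
random_gamble_rows <- function(n, seed = 1L) {
  set.seed(seed)
  type <- sample(c("GAIN_ONLY", "LOSS_ONLY", "MIXED"), n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    if (type[i] == "GAIN_ONLY") {
      x[i] <- runif(1, 1, 200); y[i] <- runif(1, 0, x[i] - 0.5)
    } else if (type[i] == "LOSS_ONLY") {
      x[i] <- -runif(1, 1, 200); y[i] <- -runif(1, 0, -x[i] - 0.5)
    } else {
      x[i] <- runif(1, 1, 200); y[i] <- -runif(1, 1, 200)
    }
  }
  data.frame(x = x, y = y, p = runif(n, 0.01, 0.99), trial_type = type)
}
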