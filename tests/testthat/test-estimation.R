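test_that("vectorized likelihood equals the brute-force per-trial oracle", {
  task <- small_task(1)
  set.seed(21)
  for (i in 1:10) {
    pars <- cpt_params(alpha = runif(1, 0.3, 1.5), lam = runif(1, 0.3, 3),
                       gamma = runif(1, 0.3, 1.5), delta = runif(1, 0.3, 2))
    truth <- data.frame(subject_id = "S1", alpha = 0.8, lam = 1.3,
                        gamma = 0.7, delta = 0.9)
    ds <- simulate_choices(task, truth, seed = 100 + i)
    expect_equal(cpt_nll(ds, task, pars), nll_brute(ds, task, pars),
                 tolerance = 1e-9)
  }
})

test_that("likelihood hand cases: maximum-entropy and single-trial values", {
  # all-equal-utility trials give n * ln 2 at any parameters
  task <- data.frame(trial_id = 1:4, trial_type = "GAIN_ONLY",
                     ax = c(100, 80, 60, 40), ay = 0, ap = 0.5,
                     bx = c(100, 80, 60, 40), by = 1e-9, bp = 0.5)
  recs <- data.frame(trial_id = 1:4, choice = c("A", "B", "A", "B"),
                     timeout = FALSE)
  expect_equal(cpt_nll(recs, task, cpt_params()), 4 * log(2),
               tolerance = 1e-6)
  # one trial whose model probability is 1/(1+e): NLL = -log(0.2689) = 1.3133
  task1 <- data.frame(trial_id = 1L, trial_type = "GAIN_ONLY",
                      ax = 2, ay = 0, ap = 0.5, bx = 4, by = 0, bp = 0.5)
  rec1 <- data.frame(trial_id = 1L, choice = "A", timeout = FALSE)
  expect_equal(cpt_nll(rec1, task1, cpt_params()), -log(1 / (1 + exp(1))),
               tolerance = 1e-9)
  expect_error(cpt_nll(data.frame(trial_id = 1L, choice = NA_character_,
                                  timeout = TRUE), task1, cpt_params()),
               "usable")
})

test_that("fits are deterministic and invariant to trial order", {
  task <- small_task(2)
  truth <- data.frame(subject_id = "S1", alpha = 0.8, lam = 1.3,
                      gamma = 0.7, delta = 0.9)
  ds <- simulate_choices(repeat_task(task, 4), truth, seed = 5)
  f1 <- cpt_fit(ds, repeat_task(task, 4), quick_settings)
  f2 <- cpt_fit(ds, repeat_task(task, 4), quick_settings)
  expect_identical(coef(f1), coef(f2))
  set.seed(1)
  shuffled <- ds[sample.int(nrow(ds)), ]
  f3 <- cpt_fit(shuffled, repeat_task(task, 4), quick_settings)
  expect_identical(coef(f1), coef(f3))
})

test_that("the optimum beats every start point and random probes", {
  task <- generate_task(1)
  truth <- data.frame(subject_id = "S1", alpha = 0.8, lam = 1.3,
                      gamma = 0.7, delta = 0.9)
  ds <- simulate_choices(task, truth, seed = 6)
  fit <- cpt_fit(ds, task)
  nll_at <- function(p) cpt_nll(ds, task, p)
  starts <- mdmcpt:::start_points(fit$settings)
  for (i in seq_len(nrow(starts)))
    expect_lte(fit$neg_log_lik, nll_at(as_pars(starts[i, ])) + 1e-6)
  set.seed(33)
  for (i in 1:100) {
    probe <- exp(runif(4, log(0.1), log(8)))
    expect_lte(fit$neg_log_lik, nll_at(as_pars(log(probe))) + 1e-6)
  }
})

test_that("estimator error shrinks as trials grow", {
  task <- generate_task(2)
  truth <- c(alpha = 0.8, lam = 1.3, gamma = 0.7, delta = 0.9)
  err_at <- function(times, seeds) {
    big <- repeat_task(task, times)
    median(vapply(seeds, function(s) {
      ds <- simulate_choices(big, data.frame(subject_id = "S1", t(truth)),
                             seed = s)
      sum(abs(log(coef(cpt_fit(ds, big, fit_settings(n_starts = 4))) / truth)))
    }, numeric(1)))
  }
  seeds <- 301:306
  e1 <- err_at(1, seeds)    # 126 trials
  e4 <- err_at(4, seeds)    # 504
  e16 <- err_at(16, seeds)  # 2016
  expect_gt(e1, e4)
  expect_gt(e4, e16)
})

test_that("subjects below the usable-trial minimum are skipped, others fitted", {
  task <- small_task(3)
  groups <- list(group_spec("HC", 3), group_spec("OCD", 2))
  ds <- simulate_cohort(groups, task, seed = 9)
  # knock one subject out with all-timeout records
  ds$timeout[ds$subject_id == "HC01"] <- TRUE
  ds$choice[ds$subject_id == "HC01"] <- NA_character_
  co <- cpt_fit_cohort(ds, task, quick_settings)
  expect_equal(nrow(coef(co)), 4L)
  expect_equal(co$skipped, "HC01")
  expect_true(all(coef(co)$converged))
  expect_true(all(c("subject_id", "group", "alpha", "lam", "gamma", "delta",
                    "nll", "n_trials", "converged") %in% names(coef(co))))
  expect_error(cpt_fit(ds[ds$subject_id == "HC01", ], task, quick_settings),
               "usable trials")
})

test_that("fit methods expose coefficients, likelihood, predictions and residuals", {
  task <- small_task(4)
  truth <- data.frame(subject_id = "S1", alpha = 0.8, lam = 1.3,
                      gamma = 0.7, delta = 0.9)
  ds <- simulate_choices(task, truth, seed = 12)
  fit <- cpt_fit(ds, task, fit_settings(min_trials = 10, compute_se = TRUE))
  expect_named(coef(fit), c("alpha", "lam", "gamma", "delta"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$neg_log_lik)
  expect_equal(attr(ll, "nobs"), nrow(task))
  pr <- predict(fit)
  expect_length(pr, nrow(task))
  expect_true(all(pr > 0 & pr < 1))
  r <- residuals(fit)
  expect_length(r, nrow(task))
  expect_true(all(abs(r) < 1))
  expect_true(is.numeric(fit$std_errors) && all(fit$std_errors > 0))
  sim <- simulate(fit, seed = 1)
  expect_s3_class(sim, "choice_dataset")
  expect_equal(nrow(sim), nrow(task))
  expect_output(print(fit), "CPT maximum-likelihood fit")
  expect_output(print(summary(fit)), "converged")
})

test_that("fits serialize to CSV with a JSON manifest", {
  task <- small_task(5)
  ds <- simulate_cohort(list(group_spec("HC", 2), group_spec("OCD", 2)),
                        task, seed = 10)
  co <- cpt_fit_cohort(ds, task, quick_settings)
  dir <- tempfile()
  write_fits(co, dir)
  tab <- read.csv(file.path(dir, "fits.csv"))
  expect_equal(nrow(tab), 4L)
  man <- jsonlite::read_json(file.path(dir, "fit_manifest.json"))
  expect_equal(man$n_subjects, 4L)
})
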