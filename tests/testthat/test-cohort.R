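test_that("subject parameter draws are log-normal, seeded, and collapse at zero dispersion", {
  g0 <- group_spec("HC", 6, param_means = cpt_params(alpha = 0.8),
                   param_sds = c(alpha = 0, lam = 0, gamma = 0, delta = 0))
  pars <- draw_subject_params(g0, seed = 1)
  expect_equal(pars$alpha, rep(0.8, 6))
  expect_equal(pars$lam, rep(1, 6))
  expect_identical(draw_subject_params(g0, 1), draw_subject_params(g0, 1))
  # law of large numbers on the log scale
  gbig <- group_spec("HC", 10000,
                     param_means = cpt_params(alpha = 0.8, lam = 1.3,
                                              gamma = 0.7, delta = 0.9),
                     param_sds = c(alpha = 0.2, lam = 0.2, gamma = 0.2,
                                   delta = 0.2))
  pb <- draw_subject_params(gbig, seed = 2)
  se <- 0.2 / sqrt(10000)
  expect_lt(abs(mean(log(pb$alpha)) - log(0.8)), 3 * se)
  expect_lt(abs(mean(log(pb$lam)) - log(1.3)), 3 * se)
  expect_true(all(pb$alpha > 0 & pb$lam > 0 & pb$gamma > 0 & pb$delta > 0))
})

test_that("simulated choice frequencies follow the logistic choice rule", {
  # a synthetic one-trial task with equal expected values: P(A) = 0.5 at
  # identity parameters
  task <- data.frame(trial_id = 1L, trial_type = "GAIN_ONLY",
                     ax = 100, ay = 0, ap = 0.5, bx = 50, by = 50, bp = 0.5)
  class(task) <- c("mdm_task", "data.frame")
  pars <- data.frame(subject_id = sprintf("S%05d", 1:10000),
                     alpha = 1, lam = 1, gamma = 1, delta = 1)
  ds <- simulate_choices(task, pars, seed = 9)
  p_hat <- mean(ds$choice == "A")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  # large utility gap: essentially always the better gamble
  task2 <- task; task2$bx <- 5; task2$by <- 0
  ds2 <- simulate_choices(task2, pars, seed = 10)
  expect_gt(mean(ds2$choice == "A"), 0.999)
})

test_that("timeouts occur at the requested rate and only without a choice", {
  task <- small_task(1)
  pars <- data.frame(subject_id = sprintf("S%03d", 1:50),
                     alpha = 0.85, lam = 1.3, gamma = 0.7, delta = 0.9)
  ds0 <- simulate_choices(task, pars, seed = 4, timeout_rate = 0)
  expect_false(any(ds0$timeout))
  expect_false(anyNA(ds0$choice))
  ds <- simulate_choices(task, pars, seed = 4, timeout_rate = 0.1)
  expect_true(all(is.na(ds$choice[ds$timeout])))
  expect_false(anyNA(ds$choice[!ds$timeout]))
  rate <- mean(ds$timeout)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(ds)))
  # record-count conservation: timeouts still occupy their trial rows
  expect_equal(as.integer(table(ds$subject_id)), rep(nrow(task), 50))
})

test_that("default cohort has the study's group structure", {
  ds <- simulate_cohort(seed = 3)
  ids <- unique(ds$subject_id)
  expect_length(ids, 59L)
  counts <- table(attr(ds, "true_params")$group)
  expect_equal(as.integer(counts[c("HC", "GAD", "SAD", "OCD")]),
               c(20L, 15L, 14L, 10L))
  expect_equal(as.integer(table(ds$subject_id)), rep(126L, 59L))
  expect_false(any(duplicated(paste(ds$subject_id, ds$trial_id))))
  clin <- attr(ds, "clinical_scores")
  expect_setequal(setdiff(names(clin), c("subject_id", "group")),
                  c("PHQ9", "GAD7", "BDI", "WSAS"))
  # different seeds differ; same seed reproduces
  ds2 <- simulate_cohort(seed = 4)
  expect_false(identical(as.data.frame(ds), as.data.frame(ds2)))
  expect_identical(as.data.frame(simulate_cohort(seed = 3)),
                   as.data.frame(ds))
})

test_that("requested parameter-clinical correlation is realized", {
  g <- group_spec("GAD", 2000,
                  param_means = cpt_params(alpha = 0.85, lam = 1.3,
                                           gamma = 0.7, delta = 0.9),
                  param_sds = c(alpha = 0.15, lam = 0.15, gamma = 0.15,
                                delta = 0.15),
                  clinical_means = c(WSAS = 20), clinical_sds = c(WSAS = 9),
                  param_clinical_corr = list(param = "lam", scale = "WSAS",
                                             r = 0.9))
  task <- small_task(2)
  ds <- simulate_cohort(list(g), task, seed = 8)
  m <- merge(attr(ds, "true_params"), attr(ds, "clinical_scores"),
             by = "subject_id")
  expect_lt(abs(cor(m$lam, m$WSAS) - 0.9), 0.05)
})

test_that("dataset serialization round-trips records and ground truth", {
  ds <- simulate_cohort(list(group_spec("HC", 3), group_spec("OCD", 3)),
                        small_task(1), seed = 2, timeout_rate = 0.05)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back), as.data.frame(ds), ignore_attr = TRUE)
  expect_equal(attr(back, "true_params"), attr(ds, "true_params"),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(attr(back, "task"))[, 1:8],
               as.data.frame(attr(ds, "task"))[, 1:8], ignore_attr = TRUE)
})
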