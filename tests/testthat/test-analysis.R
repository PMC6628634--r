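test_that("pooled t-test matches the textbook formula and df convention", {
  # {1,2,3} vs {4,5,6}: pooled sd = 1, t = -3 / sqrt(2/3)
  tt <- independent_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(tt$dof, 4)
  expect_equal(tt$cohens_d, -3)
  # df shape n1 + n2 - 2 for a 20-vs-10 comparison
  set.seed(1)
  tt2 <- independent_t_test(rnorm(20), rnorm(10))
  expect_equal(tt2$dof, 28)
  # identical samples: zero pooled variance is a domain error; equal means
  # with variance give t = 0, p = 1
  expect_error(independent_t_test(c(1, 1), c(1, 1)), "variance")
  tt3 <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt3$statistic, 0)
  expect_equal(tt3$p_value, 1)
})

test_that("one-sample test against 1 reproduces printed-summary arithmetic", {
  # exact mean/sd construction
  make_sample <- function(m, s, n) {
    z <- seq_len(n); z <- (z - mean(z)) / sd(z)
    m + s * z
  }
  hc <- make_sample(1.255, 0.437, 20)
  t_hc <- one_sample_test_vs_one(hc)
  expect_equal(t_hc$statistic, (1.255 - 1) / (0.437 / sqrt(20)),
               tolerance = 1e-9)
  expect_equal(t_hc$cohens_d, (1.255 - 1) / 0.437, tolerance = 1e-9)
  expect_equal(t_hc$dof, 19)
  jitter_one <- 1 + make_sample(0, 1e-8, 10)
  expect_lt(abs(one_sample_test_vs_one(jitter_one)$statistic), 1e-6)
  expect_error(one_sample_test_vs_one(rep(1, 5)), "variance")
})

test_that("Bonferroni thresholds follow the family size", {
  b12 <- bonferroni(c(0.001, 0.0045, 0.2), family_size = 12)
  expect_equal(b12$corrected_alpha, 0.05 / 12)
  expect_equal(b12$significant, c(TRUE, FALSE, FALSE))
  expect_equal(bonferroni(0.5, 6)$corrected_alpha, 0.05 / 6)
  expect_true(bonferroni(0, 1000)$significant)
  expect_error(bonferroni(0.5, 0), "family_size")
})

test_that("the group battery runs 12 corrected comparisons against the reference", {
  set.seed(2)
  tab <- data.frame(
    subject_id = sprintf("S%02d", 1:45),
    group = rep(c("HC", "GAD", "OCD"), each = 15),
    alpha = rnorm(45, 0.8, 0.1), lam = rnorm(45, 1.3, 0.2),
    gamma = rnorm(45, 0.7, 0.1), delta = rnorm(45, 0.9, 0.1))
  gt <- cpt_group_tests(tab, ref = "HC", family_size = 12)
  expect_equal(nrow(gt), 8L)  # two patient groups x four parameters
  expect_true(all(gt$corrected_alpha == 0.05 / 12))
  expect_true(all(gt$dof == 28))
})

test_that("Delta-EV: optimal agent attains the ceiling, random agent centers on zero", {
  task <- generate_task(0)
  n_sub <- 200
  pars <- data.frame(subject_id = sprintf("S%04d", 1:n_sub),
                     alpha = 1, lam = 1, gamma = 1, delta = 1)
  opt <- simulate_choices(task, pars[1:5, ], seed = 1, policy = "ev_max")
  dev_opt <- delta_ev_analysis(opt, task)
  ceiling <- dev_opt$max_attainable / dev_opt$n_subset_trials
  expect_equal(dev_opt$per_subject$mean_delta_ev, rep(ceiling, 5))
  expect_equal(dev_opt$n_subset_trials, 14L)
  rnd <- simulate_choices(task, pars, seed = 2, policy = "random")
  dev_rnd <- delta_ev_analysis(rnd, task)
  means <- dev_rnd$per_subject$mean_delta_ev
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(n_sub))
  expect_true(all(abs(dev_rnd$per_trial$delta_ev) <= ceiling * 14))
  expect_true(all(means <= ceiling + 1e-12))
})

test_that("low value discrimination degrades gain-trial optimality", {
  task <- generate_task(1)
  n <- 150
  low <- data.frame(subject_id = sprintf("L%04d", 1:n), alpha = 0.3,
                    lam = 1, gamma = 1, delta = 1)
  idn <- data.frame(subject_id = sprintf("I%04d", 1:n), alpha = 1,
                    lam = 1, gamma = 1, delta = 1)
  dev_low <- delta_ev_analysis(simulate_choices(task, low, seed = 3), task)
  dev_idn <- delta_ev_analysis(simulate_choices(task, idn, seed = 4), task)
  expect_lt(mean(dev_low$per_subject$mean_gain),
            mean(dev_idn$per_subject$mean_gain))
})

test_that("mixed ANOVA matches a hand-computed decomposition and stats::aov", {
  # 2 groups x 3 trials, 6 subjects
  toy <- expand.grid(subject_id = sprintf("S%d", 1:6), trial_id = 1:3)
  toy$group <- ifelse(toy$subject_id %in% c("S1", "S2", "S3"), "A", "B")
  set.seed(5)
  toy$value <- c(2, 4, 3, 7, 6, 8,
                 3, 5, 4, 8, 7, 10,
                 1, 3, 2, 6, 5, 7)
  an <- mixed_anova(toy, c("A", "B"))
  # independent oracle: aov with a subject error stratum
  fit <- stats::aov(value ~ group * factor(trial_id) +
                      Error(factor(subject_id)),
                    data = toy)
  s <- summary(fit)
  between <- s[["Error: factor(subject_id)"]][[1]]
  within <- s[["Error: Within"]][[1]]
  expect_equal(an$F[an$effect == "group"], between["group", "F value"],
               tolerance = 1e-9)
  expect_equal(an$F[an$effect == "trial"],
               within["factor(trial_id)", "F value"], tolerance = 1e-9)
  expect_equal(an$F[an$effect == "group:trial"],
               within["group:factor(trial_id)", "F value"], tolerance = 1e-9)
  expect_equal(an$dof2[an$effect == "group"], 4)
  # matched subject profiles across groups: group F = 0 exactly
  toy0 <- toy
  offs <- c(S1 = 0, S2 = 1, S3 = 2, S4 = 0, S5 = 1, S6 = 2)
  toy0$value <- rep(c(2, 4, 6), each = 6) + offs[as.character(toy0$subject_id)]
  an0 <- mixed_anova(toy0, c("A", "B"))
  expect_lt(an0$F[an0$effect == "group"], 1e-9)
  expect_error(mixed_anova(toy, c("A", "B", "C")), "two groups")
})

test_that("mixed ANOVA detects lower optimality in a low-alpha group", {
  task <- generate_task(2)
  nls <- 40
  grp <- rbind(
    data.frame(subject_id = sprintf("H%03d", 1:nls), group = "HC",
               alpha = 0.85, lam = 1.3, gamma = 0.7, delta = 0.9),
    data.frame(subject_id = sprintf("O%03d", 1:nls), group = "OCD",
               alpha = 0.4, lam = 1.3, gamma = 0.7, delta = 0.9))
  ds <- simulate_choices(task, grp, seed = 6)
  dev <- delta_ev_analysis(ds, task)
  pt <- dev$per_trial
  names(pt)[names(pt) == "delta_ev"] <- "value"
  an <- mixed_anova(pt, c("OCD", "HC"))
  hc_mean <- mean(dev$per_subject$mean_delta_ev[dev$per_subject$group == "HC"])
  ocd_mean <- mean(dev$per_subject$mean_delta_ev[dev$per_subject$group == "OCD"])
  expect_lt(ocd_mean, hc_mean)
  expect_lt(an$p_value[an$effect == "group"], 0.05)
})

test_that("parameter-clinical correlations report r, p and corrected decisions", {
  set.seed(7)
  n <- 60
  tab <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    alpha = rnorm(n, 0.8, 0.1), lam = rnorm(n, 1.3, 0.2),
                    gamma = rnorm(n, 0.7, 0.1), delta = rnorm(n, 0.9, 0.1))
  clin <- data.frame(subject_id = tab$subject_id,
                     WSAS = tab$gamma,             # perfect correlation
                     BDI = rnorm(n, 20, 8))
  ct <- parameter_clinical_correlations(tab, clin, family_size = 16)
  expect_equal(ct$r[ct$parameter == "gamma" & ct$scale == "WSAS"], 1)
  expect_true(all(ct$corrected_alpha == 0.05 / 16))
  # independent columns at large n stay near zero
  set.seed(8)
  n2 <- 5000
  tab2 <- data.frame(subject_id = seq_len(n2), alpha = rnorm(n2),
                     lam = rnorm(n2), gamma = rnorm(n2), delta = rnorm(n2))
  clin2 <- data.frame(subject_id = seq_len(n2), WSAS = rnorm(n2))
  ct2 <- parameter_clinical_correlations(tab2, clin2)
  expect_true(all(abs(ct2$r) < 0.05))
  # constant column skipped with a warning
  clin3 <- data.frame(subject_id = tab$subject_id, WSAS = 1)
  expect_warning(parameter_clinical_correlations(tab, clin3), "constant")
})

test_that("curve tables are self-consistent with the model functions", {
  groups <- list(HC = cpt_params(0.85, 1.26, 0.68, 0.88),
                 OCD = cpt_params(0.55, 1.32, 0.68, 0.88))
  curves <- cpt_curve_table(groups)
  for (g in names(groups)) {
    v <- curves$value[curves$value$group == g, ]
    expect_equal(v$v, cpt_value(v$x, groups[[g]]))
    w <- curves$weight[curves$weight$group == g, ]
    expect_equal(w$w, cpt_weight(w$p, groups[[g]]))
  }
  # identity parameters give straight lines
  ident <- cpt_curve_table(list(I = cpt_params()))
  expect_equal(ident$value$v, ident$value$x)
  expect_equal(ident$weight$w, ident$weight$p)
  # equal weighting parameters give identical weight curves row for row
  expect_equal(curves$weight$w[curves$weight$group == "HC"],
               curves$weight$w[curves$weight$group == "OCD"])
  dir <- tempfile()
  paths <- plot_cpt_functions(groups, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "value_curves.csv"))
  expect_equal(back$v, curves$value$v, tolerance = 1e-12)
})
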