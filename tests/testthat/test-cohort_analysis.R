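test_that("spearman_gaussian matches the rank formula and handles signs", {
  expect_equal(spearman_gaussian(1:4, c(10, 20, 30, 40))$r, 1)
  expect_equal(spearman_gaussian(1:4, c(40, 30, 20, 10))$r, -1)
  ## no-ties example: d^2 = (1,1,1,1,0), r = 1 - 6*4/(5*24) = 0.8
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  sp <- spearman_gaussian(x, y)
  expect_equal(sp$r, oracle_spearman_rank_formula(x, y), tolerance = 1e-12)
  expect_equal(sp$r, 0.8, tolerance = 1e-12)
  ## Gaussian approximation: z = r * sqrt(n - 1), two-sided
  expect_equal(sp$p, 2 * pnorm(-0.8 * sqrt(4)))
  ## agrees with stats::cor spearman
  set.seed(801)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_gaussian(a, b)$r, cor(a, b, method = "spearman"))
  expect_error(spearman_gaussian(rep(1, 5), 1:5), "constant")
  expect_error(spearman_gaussian(1:3, c(2, 1, 3)), ">= 4")
})

test_that("spearman r is invariant to strictly monotone transforms", {
  set.seed(802)
  for (i in 1:20) {
    x <- runif(25); y <- runif(25)
    r0 <- spearman_gaussian(x, y)$r
    expect_equal(spearman_gaussian(exp(x), y)$r, r0)
    expect_equal(spearman_gaussian(x, y^3 + 2)$r, r0)
    expect_equal(spearman_gaussian(-1 / (x + 1), y)$r, r0)
  }
})

test_that("dichotomize_aei splits at the cutoff with a documented tie rule", {
  rec <- data.table(aei = c(10, 49.9, 50, 50.1, 90))
  d <- dichotomize_aei(rec)
  expect_equal(d$low$aei, c(10, 49.9))
  expect_equal(d$high$aei, c(50, 50.1, 90))    # tie goes high by default
  d2 <- dichotomize_aei(rec, equal_to_cutoff = "low")
  expect_equal(d2$low$aei, c(10, 49.9, 50))
  all_low <- dichotomize_aei(data.table(aei = c(1, 2)))
  expect_equal(nrow(all_low$high), 0L)
  expect_error(dichotomize_aei(rec[0L]), "no records")
})

test_that("kaplan_meier reproduces hand product-limit computations", {
  km <- kaplan_meier(c(5, 10), c(1L, 1L))
  expect_equal(km$survival, c(0.5, 0))

  ## all censored: flat at 1
  flat <- kaplan_meier(c(3, 6, 9), c(0L, 0L, 0L))
  expect_equal(flat$survival, c(1, 1, 1))
  expect_true(is.na(median_survival(flat)))

  ## 5-observation hand example: (2,4,4,7,9), events (1,1,0,1,1)
  ## S: 4/5 = .8 -> .8*3/4 = .6 -> (censor) -> .6*1/2 = .3 -> 0
  km5 <- kaplan_meier(c(2, 4, 4, 7, 9), c(1L, 1L, 0L, 1L, 1L))
  expect_equal(km5$time, c(2, 4, 7, 9))
  expect_equal(km5$survival, c(0.8, 0.6, 0.3, 0))
  expect_equal(km5$n_risk, c(5L, 4L, 2L, 1L))
  expect_equal(median_survival(km5), 7)
  expect_equal(km_survival_at(km5, c(0, 2, 6.9, 100)), c(1, 0.8, 0.6, 0))
})

test_that("kaplan_meier matches survival::survfit and the ECDF identity", {
  skip_if_not_installed("survival")
  set.seed(803)
  for (i in 1:5) {
    t <- round(rexp(20, 1 / 50), 1)
    ev <- rbinom(20, 1, 0.8)
    km <- kaplan_meier(t, ev)
    sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
    expect_equal(km_survival_at(km, sf$time), sf$surv, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))   # non-increasing
  }
  ## no censoring: S = 1 - ECDF
  t <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- kaplan_meier(t)
  expect_equal(km$survival, 1 - ecdf(t)(km$time))
})

test_that("logrank_test matches the hypergeometric oracle and survdiff", {
  ## two-group toy: brute-force O/E/Var gives chisq = 49/17
  lr <- logrank_test(c(1, 2), c(1L, 1L), c(3, 4), c(1L, 1L))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$chisq,
               oracle_logrank_chisq(c(1, 2), c(1, 1), c(3, 4), c(1, 1)),
               tolerance = 1e-12)

  ## identical groups: chisq 0, p 1
  same <- logrank_test(c(5, 8, 12), rep(1L, 3), c(5, 8, 12), rep(1L, 3))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  ## label-swap invariance and agreement with survival::survdiff
  set.seed(804)
  for (i in 1:5) {
    ta <- round(rexp(12, 1 / 40), 1); ea <- rbinom(12, 1, 0.9)
    tb <- round(rexp(15, 1 / 60), 1); eb <- rbinom(15, 1, 0.9)
    if (sum(ea) + sum(eb) == 0) next
    l1 <- logrank_test(ta, ea, tb, eb)
    l2 <- logrank_test(tb, eb, ta, ea)
    expect_equal(l1$chisq, l2$chisq, tolerance = 1e-12)
    expect_equal(l1$chisq,
                 oracle_logrank_chisq(ta, ea, tb, eb), tolerance = 1e-12)
    if (requireNamespace("survival", quietly = TRUE)) {
      sd <- survival::survdiff(
        survival::Surv(c(ta, tb), c(ea, eb)) ~
          rep(1:2, c(length(ta), length(tb))))
      expect_equal(l1$chisq, sd$chisq, tolerance = 1e-8)
    }
  }
})

test_that("phase_comparison: Welch + paired t with zero-variance rules", {
  pre <- data.table(patient_id = sprintf("P%d", 1:3), aei = c(1, 2, 3))
  on <- data.table(patient_id = sprintf("P%d", 1:3), aei = c(2, 3, 4))
  pc <- phase_comparison(pre, on)
  expect_equal(pc$mean_paired_diff, 1)
  expect_equal(pc$paired_p, 0)              # constant nonzero shift
  expect_equal(pc$n_pairs, 3L)

  same <- phase_comparison(pre, copy(pre))
  expect_equal(same$paired_p, 1)
  expect_equal(same$unpaired_p, 1)

  ## simulated phases vs the direct t formula
  set.seed(805)
  a <- rnorm(23, 48, 27)
  b <- a + rnorm(23, 10, 27)
  pre2 <- data.table(patient_id = sprintf("P%d", 1:23), aei = a)
  on2 <- data.table(patient_id = sprintf("P%d", 1:23), aei = b)
  pc2 <- phase_comparison(pre2, on2)
  d <- b - a
  t_stat <- mean(d) / (sd(d) / sqrt(23))
  expect_equal(pc2$paired_p, 2 * pt(-abs(t_stat), df = 22))
  expect_equal(pc2$unpaired_p, t.test(a, b)$p.value)
  expect_equal(pc2$mean_pre, mean(a))
  expect_equal(pc2$sd_on, sd(b))
})

test_that("covariate_panel flags degenerate rows and finds self-correlation", {
  set.seed(806)
  rec <- data.table(aei = rgamma(22, 3, scale = 16))
  rec$mutation_load <- rec$aei                  # r = 1 by construction
  rec$neoantigen_load <- rlnorm(22, 5, 1)
  rec$neopeptide_load <- NA_real_               # all missing
  rec$cytolytic_score <- 7                      # constant
  panel <- covariate_panel(rec)
  corr <- panel$correlations
  expect_equal(corr[covariate == "mutation_load", spearman_r], 1)
  expect_equal(corr[covariate == "neopeptide_load", note],
               "insufficient_data")
  expect_equal(corr[covariate == "cytolytic_score", note],
               "insufficient_data")
  expect_true(is.finite(corr[covariate == "neoantigen_load", p]))
  contrast <- panel$group_contrast
  expect_equal(contrast[covariate == "neopeptide_load", note],
               "insufficient_data")
})

test_that("type-I control: independent covariate rejects ~5% of the time", {
  set.seed(807)
  n <- 22L; reps <- 400L
  crit <- qnorm(0.975) / sqrt(n - 1)    # |r| threshold under the Gaussian p
  hits <- 0L
  for (i in seq_len(reps)) {
    r <- spearman_gaussian(rnorm(n), rnorm(n))$r
    hits <- hits + (abs(r) > crit)
  }
  rate <- hits / reps
  ## binomial 99.9% band around 0.05 for 400 reps: ~ +/- 0.036
  expect_gt(rate, 0.014)
  expect_lt(rate, 0.086)
})

test_that("cohort_report assembles all components on a synthetic cohort", {
  cfg <- simulation_config(99L)
  co <- simulate_cohort(cfg)$cohort
  rep <- cohort_report(co)
  expect_true(rep$aei_survival_pre$r < 0)    # hazard increases with AEI
  expect_true(rep$adar_aei$r > 0)            # ADAR tracks AEI
  expect_equal(rep$dichotomy$n_low + rep$dichotomy$n_high, cfg$cohort_n)
  expect_s3_class(rep$km_low, "km_curve")
  expect_true(is.finite(rep$logrank$p))
  expect_equal(rep$phase$n_pairs, cfg$cohort_n)
  expect_equal(nrow(rep$covariate_panel$correlations), 4L)
})
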