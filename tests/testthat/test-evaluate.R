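test_that("harrell_c handles perfect order, total ties, and matches pair enumeration", {
  n <- 20
  withr::local_seed(90)
  time <- sort(rexp(n) + 0.01)
  surv <- survival_data(paste0("s", 1:n), time, rep(1, n))
  expect_equal(harrell_c(-time, surv), 1.0)       # reverse order, no censoring
  expect_equal(harrell_c(rep(2, n), surv), 0.5)   # all risks tied

  # 5-sample toy with one censored observation vs exhaustive enumeration
  surv5 <- survival_data(letters[1:5], c(2, 4, 3, 6, 5), c(1, 1, 0, 1, 1))
  risk5 <- c(3.0, 1.0, 2.0, 0.5, 1.0)
  expect_equal(harrell_c(risk5, surv5),
               oracle_harrell_c(risk5, surv5$time, surv5$event))
  # larger random instances against the same oracle
  for (i in 1:10) {
    s <- random_surv_instance(12, ties = i %% 2 == 0)
    r <- sample(1:6, 12, replace = TRUE)  # deliberate risk ties
    expect_equal(harrell_c(r, s), oracle_harrell_c(r, s$time, s$event))
  }
})

test_that("harrell_c of a flipped risk is the complement when no risk ties exist", {
  withr::local_seed(91)
  for (i in 1:10) {
    s <- random_surv_instance(15)
    r <- rnorm(15)
    expect_equal(harrell_c(r, s) + harrell_c(-r, s), 1)
  }
})

test_that("the likelihood ratio behaves like chi-squared(1) under the null", {
  withr::local_seed(92)
  n <- 50
  reps <- 1000
  lr <- numeric(reps)
  for (r in seq_len(reps)) {
    surv <- survival_data(paste0("s", 1:n), rexp(n) + 0.01, rbinom(n, 1, 0.8))
    lr[r] <- likelihood_ratio(rnorm(n), surv)
  }
  expect_equal(mean(lr), 1, tolerance = 0.15)
  expect_equal(unname(quantile(lr, 0.95)), qchisq(0.95, 1), tolerance = 0.15)
})

test_that("an informative risk yields a large likelihood ratio; degenerate input errors", {
  withr::local_seed(93)
  for (r in 1:5) {
    n <- 100
    x <- rnorm(n)
    surv <- survival_data(paste0("s", 1:n), rexp(n, 0.1 * exp(1.5 * x)) + 1e-6,
                          rep(1, n))
    expect_gt(likelihood_ratio(x, surv), 20)
  }
  surv <- random_surv_instance(10)
  expect_error(likelihood_ratio(rep(1, 10), surv), "constant")
})

test_that("likelihood ratio and R2 are affine-invariant; C and log-rank rank-invariant", {
  withr::local_seed(94)
  n <- 60
  x <- rnorm(n)
  surv <- survival_data(paste0("s", 1:n), rexp(n, 0.2 * exp(0.8 * x)) + 1e-6,
                        rbinom(n, 1, 0.8))
  expect_equal(likelihood_ratio(5 * x + 3, surv), likelihood_ratio(x, surv),
               tolerance = 1e-6)
  expect_equal(r_squared(5 * x + 3, surv), r_squared(x, surv), tolerance = 1e-6)
  mono <- exp(x)  # strictly increasing, non-affine
  expect_equal(harrell_c(mono, surv), harrell_c(x, surv))
  expect_equal(logrank_median_split(mono, surv)$p_value,
               logrank_median_split(x, surv)$p_value)
})

test_that("r_squared follows its closed form and stays in [0, 1)", {
  # LR = n * ln 2 forces R2 = 1/2; LR = 0 forces 0
  expect_equal(1 - exp(-0 / 10), 0)
  withr::local_seed(95)
  n <- 40
  x <- rnorm(n)
  surv <- survival_data(paste0("s", 1:n), rexp(n, 0.2 * exp(x)) + 1e-6, rep(1, n))
  lr <- likelihood_ratio(x, surv)
  r2 <- r_squared(x, surv)
  expect_equal(r2, 1 - exp(-lr / n), tolerance = 1e-12)
  expect_gte(r2, 0)
  expect_lt(r2, 1)
})

test_that("the median-split log-rank statistic matches a hand-computed case", {
  # 4 samples, all events at times 1 < 2 < 3 < 4; risk puts samples (1,2)
  # in the high group. Observed high-group deaths: 2.
  # Expected under the null, summing n1k/nk over the four event times:
  #   t=1: 2/4, t=2: 1/3, t=3: 0, t=4: 0  => E = 5/6
  # Variances n1k*n2k*(nk-dk)/(nk^2*(nk-1)): 1/4*2/3=... summed V = 17/36
  # chi2 = (O - E)^2 / V = (2 - 5/6)^2 / (17/36)
  surv <- survival_data(c("a", "b", "c", "d"), c(1, 2, 3, 4), rep(1, 4))
  risk <- c(10, 9, 1, 2)
  ls <- logrank_median_split(risk, surv)
  o_minus_e <- 2 - (2 / 4 + 1 / 3)
  v <- (2 * 2 * 3) / (16 * 3) + (1 * 2 * 2) / (9 * 2)
  expect_equal(ls$statistic, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(ls$n_high, 2)
  expect_equal(ls$n_low, 2)
  # ties at the median go to the low-risk group
  ls2 <- logrank_median_split(c(5, 5, 1, 9), surv)
  expect_equal(ls2$n_high, 1)
  expect_error(logrank_median_split(rep(1, 4), surv), "empty")
})

test_that("median-split log-rank is calibrated under the null and powered under signal", {
  withr::local_seed(96)
  reps <- 500
  p_null <- numeric(reps)
  n <- 60
  for (r in seq_len(reps)) {
    surv <- survival_data(paste0("s", 1:n), rexp(n) + 0.01, rbinom(n, 1, 0.8))
    p_null[r] <- logrank_median_split(rnorm(n), surv)$p_value
  }
  expect_gte(mean(p_null < 0.05), 0.02)
  expect_lte(mean(p_null < 0.05), 0.08)

  hits <- 0
  for (r in 1:40) {
    grp <- rep(c(0, 1), each = 100)
    t_ev <- rexp(200, 0.1 * 3^grp)
    surv <- survival_data(paste0("s", 1:200), t_ev, rep(1, 200))
    if (logrank_median_split(grp + rnorm(200, sd = 1e-3), surv)$p_value < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gt(hits / 40, 0.9)
})

test_that("evaluate_risk assembles a consistent report and KM export", {
  withr::local_seed(97)
  n <- 80
  x <- rnorm(n)
  surv <- survival_data(paste0("s", 1:n), rexp(n, 0.1 * exp(0.7 * x)) + 1e-6,
                        rbinom(n, 1, 0.9))
  rep_ <- evaluate_risk(x, surv)
  expect_equal(rep_$n_low + rep_$n_high, n)
  expect_equal(rep_$r_squared, 1 - exp(-rep_$likelihood_ratio / n),
               tolerance = 1e-12)
  expect_true(rep_$logrank_p > 0 && rep_$logrank_p <= 1)
  km <- km_curve_data(x, surv)
  expect_setequal(unique(km$group), c("low", "high"))
  expect_true(all(diff(km$survival[km$group == "high"]) <= 1e-12))
})
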