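test_that("feeder proportions sum to one and zero totals are undefined", {
  cs <- count_series(1:4, c(10, 8, 0, 0), c(10, 0, 5, 0))
  pr <- feeder_proportions(cs)
  expect_equal(pr$p1, c(0.5, 1, 0, NA))
  expect_equal(pr$p2, c(0.5, 0, 1, NA))
  ok <- !is.na(pr$p1)
  expect_true(all(abs(pr$p1[ok] + pr$p2[ok] - 1) < 1e-12))
})

test_that("count series constructor validates its invariants", {
  expect_error(count_series(c(1, 1), c(0, 0), c(0, 0)), "increasing")
  expect_error(count_series(1:2, c(-1, 0), c(0, 0)), "non-negative")
  expect_error(count_series(1:3, 1:2, 1:3), "equal length")
})

test_that("majority patch uses the documented tie-breaks", {
  expect_equal(majority_patch(count_series(1:3, c(1, 2, 5), c(9, 9, 3)), 3), 1L)
  expect_equal(majority_patch(count_series(1:3, c(1, 2, 3), c(9, 9, 5)), 3), 2L)
  # tie at the reference time -> cumulative count decides
  expect_equal(majority_patch(count_series(1:3, c(1, 2, 4), c(9, 9, 4)), 3), 2L)
  # still tied -> patch 1
  expect_equal(majority_patch(count_series(1:3, c(4, 2, 4), c(2, 4, 4)), 3), 1L)
  expect_error(majority_patch(count_series(1:3, 1:3, 1:3), 10), "time point")
})

test_that("symmetry index matches direct arithmetic", {
  even <- count_series(1:10, rep(5, 10), rep(5, 10))
  expect_equal(symmetry_index(even), 0)
  onesided <- count_series(1:10, rep(7, 10), rep(0, 10))
  expect_equal(symmetry_index(onesided), 1)
  # p1 = 0.75 at half the points and 0.25 at the other half -> mean |diff| 0.5
  half <- count_series(1:10, c(rep(15, 5), rep(5, 5)), c(rep(5, 5), rep(15, 5)))
  expect_equal(symmetry_index(half), 0.5)
  expect_error(symmetry_index(count_series(1:3, rep(0, 3), rep(0, 3))),
               "undefined")
})

test_that("crossing time finds the earliest sustained exceedance", {
  s1 <- rep(10, 2000)
  s2 <- c(rep(0, 999), rep(12, 1001))
  expect_equal(crossing_time(s1, s2, persistence = 60), 1000)
  expect_true(is.na(crossing_time(s1, rep(5, 2000), persistence = 60)))
  # spurious 5-step blips before a true sustained crossing are ignored
  s3 <- rep(10, 2000)
  s3[c(300:304, 700:704)] <- 15
  s3[1500:2000] <- 20
  expect_equal(crossing_time(s1, s3, persistence = 60), 1500)
  expect_equal(crossing_time(s1, s3, persistence = 5), 300)
})

test_that("crossing time is monotone in the persistence window", {
  set.seed(8)
  for (k in 1:25) {
    a <- stats::rpois(300, 6)
    b <- stats::rpois(300, 6) + c(rep(0, 150), rep(3, 150))
    times <- sapply(c(1, 5, 20, 60), function(p) crossing_time(a, b, p))
    times[is.na(times)] <- 1e9 # no crossing sorts after any real crossing
    expect_true(all(diff(times) >= 0))
  }
})

test_that("bias chi-square reproduces the printed 8.33 and is symmetric", {
  ct <- chisq_equal_bias(12, 11)
  expect_equal(round(ct$statistic, 2), 8.33)
  expect_equal(ct$df, 1)
  expect_lt(ct$p_value, 0.005)
  expect_equal(chisq_equal_bias(12, 6)$statistic, 0)
  expect_equal(chisq_equal_bias(12, 12)$statistic, 12)
  # invariant to swapping the two categories
  expect_equal(chisq_equal_bias(12, 11)$statistic,
               chisq_equal_bias(12, 1)$statistic)
  expect_error(chisq_equal_bias(0, 0), "n_trials")
})

test_that("one-sample t matches the closed-form oracle", {
  expect_equal(one_sample_t(rep(0.5, 10))$t, 0)
  # n = 23, mean 0.51, sd 0.04: t = 0.01 * sqrt(23) / 0.04
  x <- sample_with_moments(23, 0.51, 0.04)
  res <- one_sample_t(x)
  expect_equal(res$t, 0.01 * sqrt(23) / 0.04, tolerance = 1e-10)
  expect_equal(res$df, 22)
  y <- sample_with_moments(23, 0.59, 0.04)
  expect_equal(one_sample_t(y)$t, 0.09 * sqrt(23) / 0.04, tolerance = 1e-10)
  # zero-variance sample away from the null is flagged infinite
  expect_equal(one_sample_t(rep(0.7, 5))$t, Inf)
})

test_that("switch-time regression recovers planted relationships", {
  rates <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 2.0)
  exact <- 1000 - 150 * log(rates)
  # lm warns that a perfect fit makes the t-statistics unreliable; only the
  # coefficients and R^2 are asserted here
  fit <- suppressWarnings(regress_switch_logdecay(rates, exact))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -150, tolerance = 1e-9)
  # planted slope with noise, recovered within 2 standard errors
  set.seed(12)
  noisy <- 1500 - 200 * log(rates) + stats::rnorm(8)[seq_along(rates)] * 20
  f2 <- regress_switch_logdecay(rates, noisy)
  se <- abs(f2$slope / f2$t_value)
  expect_lt(abs(f2$slope - (-200)), 2 * se)
  expect_error(regress_switch_logdecay(c(0, 0.4, 1), c(1, 2, 3)), "> 0")
  expect_error(regress_switch_logdecay(c(0.4, 1), c(1, 2)), "at least 3")
})

test_that("Holm step-down matches the by-hand example", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.30)), c(TRUE, TRUE, FALSE))
  expect_equal(holm_adjust(0.04), TRUE)
  expect_equal(holm_adjust(rep(1, 4)), rep(FALSE, 4))
  expect_equal(holm_adjust(numeric(0)), logical(0))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm rejects a superset of plain Bonferroni", {
  set.seed(13)
  for (k in 1:50) {
    p <- stats::runif(8)^2
    holm <- holm_adjust(p)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(holm[bonf]))
  }
})
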