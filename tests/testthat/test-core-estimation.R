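# Core estimation: point estimate, sample-size formulas, finite-population
# correction, delta-method variance, confidence intervals.

test_that("multiplier point estimate is the count divided by the proportion", {
  expect_identical(estimate_pse(750, 0.05), 15000)
  expect_identical(estimate_pse(6000, 0.4), 15000)
  expect_identical(estimate_pse(0, 0.5), 0)
  expect_identical(estimate_pse(100, 1.0), 100)
  expect_identical(estimate_pse(count_estimate(952), 0.063), 952 / 0.063)
})

test_that("point estimate rejects out-of-range inputs by name", {
  expect_error(estimate_pse(100, 0), "'p'.*0")
  expect_error(estimate_pse(100, -0.1), "'p'")
  expect_error(estimate_pse(100, 1.2), "'p'.*1\\.2")
  expect_error(count_estimate(-5), "'m'.*-5")
})

test_that("ratio identity holds across random valid inputs", {
  set.seed(401)
  for (i in 1:200) {
    m <- rpois(1, runif(1, 1, 5000))
    p <- runif(1, 1e-4, 1)
    est <- estimate_pse(m, p)
    expect_equal(est * p, m, tolerance = 1e-12)
    expect_gte(est, m) # p <= 1 so the estimate is never below the count
  }
})

test_that("required sample size follows deff * p(1-p) / se^2, rounded up", {
  expect_identical(required_n_srs(0.5, 0.05, deff = 1), 100L)
  expect_identical(required_n_srs(0.5, 0.05, deff = 4), 400L)
  # ceil(3 * 0.063 * 0.937 / 0.01^2) = ceil(1770.93)
  expect_identical(required_n_srs(0.063, 0.01, deff = 3), 1771L)
  # monotone: increasing in deff, decreasing in target_se
  n_by_deff <- vapply(1:4, function(d) required_n_srs(0.3, 0.02, d), 1L)
  expect_true(all(diff(n_by_deff) > 0))
  n_by_se <- vapply(c(0.05, 0.02, 0.01), function(s)
    required_n_srs(0.3, s), 1L)
  expect_true(all(diff(n_by_se) > 0))
  expect_error(required_n_srs(0, 0.05), "0 < p < 1")
  expect_error(required_n_srs(1, 0.05), "0 < p < 1")
  expect_error(required_n_srs(0.5, 0.05, deff = 0.5), "deff")
  expect_error(required_n_srs(0.5, 0), "target_se")
})

test_that("finite-population adjustment shrinks n and vanishes at N = Inf", {
  expect_identical(fpc_adjust_n(100, Inf), 100)
  expect_identical(fpc_adjust_n(1, 50), 1)
  expect_equal(fpc_adjust_n(100, 100), 100 / 1.99, tolerance = 1e-12)
  set.seed(402)
  for (i in 1:50) {
    n0 <- runif(1, 1, 5000)
    N <- runif(1, n0, 1e6)
    adj <- fpc_adjust_n(n0, N)
    expect_lte(adj, min(n0, N))
    expect_gt(adj, 0)
  }
  # large-N limit recovers the unadjusted size
  expect_equal(fpc_adjust_n(1500, 1e12), 1500, tolerance = 1e-6)
  expect_error(fpc_adjust_n(0, 100), "n0")
  expect_error(fpc_adjust_n(100, -1), "pop_n")
})

test_that("se of the proportion matches the design formula with FPC", {
  expect_equal(se_p_achieved(0.5, 100), 0.05)
  # census: the FPC factor is exactly zero
  expect_equal(se_p_achieved(0.5, 5000, deff = 1, pop_n = 5000), 0)
  # sqrt(3 * .063 * .937 / 1500) * sqrt(13500 / 14999)
  expect_equal(se_p_achieved(0.063, 1500, deff = 3, pop_n = 15000),
               0.010308389020213, tolerance = 1e-10)
  # correction can only shrink the standard error
  set.seed(403)
  for (i in 1:50) {
    p <- runif(1, 0.01, 0.99)
    n <- sample(10:2000, 1)
    deff <- runif(1, 1, 5)
    N <- n + sample(1:50000, 1)
    expect_lte(se_p_achieved(p, n, deff, N), se_p_achieved(p, n, deff, Inf))
  }
  # works on a proportion_spec too
  spec <- proportion_spec(0.063, n = 1500, deff = 3, pop_n = 15000)
  expect_equal(se_p_achieved(spec), spec$se_p)
  expect_error(se_p_achieved(0.5, 200, pop_n = 100), "exceeds")
  expect_error(se_p_achieved(0.5, 1, pop_n = 100), "n >= 2")
})

test_that("delta-method variance decomposes into count and proportion parts", {
  v <- var_pse(100, 1, 0)
  expect_equal(v$variance, 100)
  expect_equal(v$var_from_p, 0)
  # se_p = 0 leaves only the Poisson term mu / p^2
  set.seed(404)
  for (i in 1:20) {
    mu <- runif(1, 10, 5000)
    p <- runif(1, 0.01, 1)
    v <- var_pse(count_estimate(round(mu), mu_m = mu), p, 0)
    expect_equal(v$variance, mu / p^2, tolerance = 1e-12)
  }
  # decomposition: components non-negative and summing to the total
  for (i in 1:20) {
    mu <- runif(1, 10, 5000)
    p <- runif(1, 0.01, 1)
    se <- runif(1, 0, p / 4)
    v <- var_pse(count_estimate(round(mu), mu_m = mu), p, se)
    expect_gte(v$var_from_m, 0)
    expect_gte(v$var_from_p, 0)
    expect_equal(v$variance, v$var_from_m + v$var_from_p)
  }
  expect_error(var_pse(100, 0, 0.01), "'p'")
  expect_error(var_pse(100, 0.5, -0.01), "se_p")
})

test_that("delta variance tracks a brute-force ratio simulation", {
  # brute force: M ~ Poisson(952), P ~ Normal(0.063, se^2) truncated to
  # (0, 1]; empirical var(M/P) vs the first-order analytic value. A
  # first-order approximation of a ratio omits O((se/p)^2) terms; at this
  # design se/p is about 0.16 and the heavy right tail of 1/P puts the
  # brute-force sd roughly 10-15% above the analytic value, so the check
  # is that the analytic value sits just below, at the right scale.
  se <- se_p_achieved(0.063, 1500, deff = 3, pop_n = 15000)
  set.seed(405)
  reps <- 2e5
  m <- rpois(reps, 952)
  p <- rnorm(reps, 0.063, se)
  keep <- p > 0 & p <= 1
  ratio_draws <- m[keep] / p[keep]
  analytic <- var_pse(count_estimate(952), 0.063, se)$variance
  expect_gt(sqrt(analytic) / sd(ratio_draws), 0.8)
  expect_lte(sqrt(analytic) / sd(ratio_draws), 1.005)
  # at a small coefficient of variation of P the first-order value matches
  # the brute force tightly
  se2 <- se_p_achieved(0.4, 3000, deff = 1, pop_n = Inf)
  m2 <- rpois(reps, 6000)
  p2 <- rnorm(reps, 0.4, se2)
  analytic2 <- var_pse(count_estimate(6000), 0.4, se2)$variance
  expect_equal(sqrt(analytic2) / sd(m2 / p2), 1, tolerance = 0.02)
})

test_that("confidence interval is estimate +/- z * sqrt(variance)", {
  r <- ci_pse(list(estimate = 15000, variance = 0))
  expect_equal(c(r$ci_lower, r$ci_upper), c(15000, 15000))
  r <- ci_pse(list(estimate = 5000, variance = 2.5e6), level = 0.95)
  expect_equal(r$z, qnorm(0.975))
  expect_equal(r$ci_width, 2 * qnorm(0.975) * sqrt(2.5e6))
  expect_equal(r$ci_upper - r$ci_lower, r$ci_width)
  # lower bound may be negative by default; opt-in floor at the count
  res <- pse(85, 0.006, n = 500, deff = 3, pop_n = 15000)
  expect_lt(res$ci_lower, 0)
  res_tr <- pse(85, 0.006, n = 500, deff = 3, pop_n = 15000,
                truncate_lower = TRUE)
  expect_equal(res_tr$ci_lower, 85)
  expect_equal(res_tr$ci_upper, res$ci_upper)
  expect_error(ci_pse(list(estimate = 1)), "variance")
  expect_error(ci_pse(list(estimate = 1, variance = 1), level = 1), "level")
})

test_that("full pse() wrapper composes the pieces coherently", {
  res <- pse(952, 0.063, n = 1500, deff = 3, pop_n = 15000)
  expect_s3_class(res, "pse_result")
  expect_equal(res$estimate, 952 / 0.063)
  expect_equal(res$se_p, se_p_achieved(0.063, 1500, 3, 15000))
  expect_equal(res$variance, res$var_from_m + res$var_from_p)
  expect_equal(res$ci_upper - res$ci_lower,
               2 * qnorm(0.975) * sqrt(res$variance))
  # supplying se_p directly bypasses the design derivation
  res2 <- pse(952, 0.063, se_p = res$se_p)
  expect_equal(res2$variance, res$variance)
  expect_error(pse(952, 0.063), "se_p|'n'")
  expect_output(print(res), "PSE = M/P")
})
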