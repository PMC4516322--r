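test_that("mw parameterization satisfies its defining constraints", {
  for (m in c(2, 10, 50)) {
    for (w in c(0.5, 8, 40)) {
      expect_equal(gumbel_cdf(m, m, w), 0.5)
      expect_equal(gumbel_qf(0.9, m, w) - gumbel_qf(0.1, m, w), w)
      expect_equal(gumbel_qf(0.5, m, w), m)
    }
  }
  expect_error(gumbel_cdf(1, 10, -1), "w must be")
})

test_that("gumbel CDF matches an independent constraint-solver evaluation", {
  # a, b solved numerically from F(m) = 0.5 and qf(0.9) - qf(0.1) = w by an
  # external root-finder for m = 10, w = 10; frozen value of F(5)
  expect_equal(gumbel_cdf(5, 10, 10), 0.13780267843042415, tolerance = 1e-7)
  # and via an in-suite brute-force inversion: recover w from the curve
  qf_num <- function(p) uniroot(function(x) gumbel_cdf(x, 10, 10) - p,
                                c(-1e3, 1e3), tol = 1e-12)$root
  expect_equal(qf_num(0.9) - qf_num(0.1), 10, tolerance = 1e-6)
})

test_that("gumbel core is strictly increasing with asymptotes 0 and 1", {
  x <- seq(-50, 400, by = 0.5)
  F <- gumbel_cdf(x, 12, 10)
  expect_true(all(diff(F) >= 0))
  # strictly increasing wherever F is representable below 1 in double
  core <- gumbel_cdf(seq(-20, 22, by = 0.5), 12, 10)
  expect_true(all(diff(core) > 0))
  expect_lt(gumbel_cdf(-1e6, 12, 10), 1e-12)
  expect_equal(gumbel_cdf(1e6, 12, 10), 1)
})

test_that("percent-gap counts match a hand tally and anchor FA at x = 0", {
  s <- make_session(c(0, 0, 5, 5), c("gap", "nogap", "gap", "nogap"))
  pgf <- build_percent_gap(s)
  expect_equal(pgf$x, c(0, 5))
  expect_equal(pgf$n, c(2L, 2L))
  expect_equal(pgf$k, c(1L, 1L))   # one FA, one hit

  s2 <- make_counts_session(c(0, 10, 20), c(100, 50, 50), c(23, 50, 0))
  pgf2 <- build_percent_gap(s2)
  expect_equal(pgf2$k[1] / pgf2$n[1], 0.23)
  expect_equal(pgf2$k / pgf2$n, c(0.23, 1, 0))
})

test_that("deviance matches direct formula evaluation and the loglik identity", {
  # single level n = 10, k = 5 against fitted probability 0.4:
  # curve with zero amplitude (gamma = 0.4, lam = 0.6) is constant at 0.4
  pgf <- structure(list(x = 5, n = 10L, k = 5L), class = "percent_gap")
  flat <- fake_fit(10, 10, 0.4, 0.6)
  expect_equal(deviance_pgf(flat, pgf), 0.40821994520255167)
  # D = -2 (loglik_model - loglik_saturated) on a multi-level table
  pgf <- structure(list(x = c(0, 3, 5, 10, 20), n = rep(50L, 5),
                        k = c(12L, 13L, 20L, 30L, 47L)),
                   class = "percent_gap")
  fit <- fit_psychometric(pgf)
  ll_sat <- sum(dbinom(pgf$k, pgf$n, pgf$k / pgf$n, log = TRUE))
  ll_mod <- sum(dbinom(pgf$k, pgf$n,
                       psi_fun(pgf$x, fit$m, fit$w, fit$gamma, fit$lam),
                       log = TRUE))
  expect_equal(fit$deviance, -2 * (ll_mod - ll_sat), tolerance = 1e-8)
  expect_gte(fit$deviance, 0)
  # zero when the fitted curve reproduces the empirical rates exactly
  pgf0 <- structure(list(x = c(3, 5, 10), n = rep(10L, 3), k = rep(4L, 3)),
                    class = "percent_gap")
  expect_equal(deviance_pgf(fake_fit(10, 10, 0.4, 0.6), pgf0), 0)
})

test_that("MLE recovers parameters from data generated on a known curve", {
  truth <- list(m = 12, w = 10, gamma = 0.2, lam = 0.05)
  x <- c(0, 3, 5, 10, 20, 50, 100, 270)
  n <- rep(20000L, length(x))
  psi <- psi_fun(x, truth$m, truth$w, truth$gamma, truth$lam)
  k <- as.integer(round(n * psi))
  pgf <- structure(list(x = x, n = n, k = k), class = "percent_gap")
  fit <- fit_psychometric(pgf)
  expect_lt(abs(fit$m - truth$m), 0.1)
  expect_lt(abs(fit$w - truth$w), 0.2)
  expect_lt(abs(fit$gamma - truth$gamma), 0.01)
  expect_lt(abs(fit$lam - truth$lam), 0.01)
})

test_that("fitted curve respects its asymptote band and monotonicity", {
  set.seed(11)
  obs <- observer_model()
  sch <- schedule_spec("ferret", n_trials = 400)
  for (i in 1:5) {
    s <- simulate_session(obs, sch, seed = 40 + i)
    fit <- fit_psychometric(build_percent_gap(s))
    xs <- seq(0, 300, by = 1)
    psi <- psi_fun(xs, fit$m, fit$w, fit$gamma, fit$lam)
    expect_true(all(diff(psi) >= 0))
    expect_true(all(psi >= fit$gamma - 1e-12))
    expect_true(all(psi <= 1 - fit$lam + 1e-12))
  }
})

test_that("fit is invariant to duplicating counts; deviance scales", {
  pgf <- structure(list(x = c(0, 3, 5, 10, 20, 50), n = rep(60L, 6),
                        k = c(14L, 16L, 24L, 37L, 52L, 57L)),
                   class = "percent_gap")
  fit1 <- fit_psychometric(pgf)
  pgf4 <- structure(list(x = pgf$x, n = 4L * pgf$n, k = 4L * pgf$k),
                    class = "percent_gap")
  fit4 <- fit_psychometric(pgf4)
  expect_equal(fit4$m, fit1$m, tolerance = 1e-3)
  expect_equal(fit4$w, fit1$w, tolerance = 1e-3)
  expect_equal(fit4$gamma, fit1$gamma, tolerance = 1e-3)
  expect_equal(fit4$lam, fit1$lam, tolerance = 1e-3)
  expect_equal(fit4$deviance, 4 * fit1$deviance, tolerance = 0.02)
})

test_that("bootstrap GOF accepts well-specified data and rejects a step function", {
  obs <- observer_model()
  s <- simulate_session(obs, schedule_spec("ferret", n_trials = 800), seed = 9)
  pgf <- build_percent_gap(s)
  fit <- bootstrap_gof(fit_psychometric(pgf), pgf, n_boot = 200, seed = 2)
  expect_true(fit$accepted)
  expect_equal(attr(fit, "n_refit_failures"), 0L)

  # two-step staircase with a plateau at 0.5: outside the sigmoid family,
  # and at large n the deviance gives it away
  x <- c(0, 3, 5, 10, 20, 50, 100, 270)
  n <- rep(2000L, 8)
  p_step <- c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5, 0.95, 0.95)
  k <- as.integer(n * p_step)
  pgf_step <- structure(list(x = x, n = n, k = k), class = "percent_gap")
  fit_step <- fit_psychometric(pgf_step)
  fit_step <- bootstrap_gof(fit_step, pgf_step, n_boot = 200, seed = 3)
  expect_false(fit_step$accepted)
})

test_that("monotone-decreasing data is rejected by the GOF gate", {
  x <- c(0, 3, 5, 10, 20, 50, 100, 270)
  n <- rep(500L, 8)
  k <- as.integer(n * c(0.9, 0.85, 0.8, 0.6, 0.4, 0.25, 0.15, 0.1))
  pgf <- structure(list(x = x, n = n, k = k), class = "percent_gap")
  fit <- fit_psychometric(pgf)
  fit <- bootstrap_gof(fit, pgf, n_boot = 200, seed = 4)
  expect_false(fit$accepted)
})
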