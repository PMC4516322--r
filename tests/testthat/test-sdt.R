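test_that("d-prime matches the inverse-normal oracle and its symmetries", {
  # independent oracle: invert the normal CDF by root-finding, not qnorm
  z_num <- function(p) uniroot(function(q) pnorm(q) - p, c(-10, 10),
                               tol = 1e-12)$root
  expect_equal(dprime(0.9, 0.1), z_num(0.9) - z_num(0.1), tolerance = 1e-8)
  expect_equal(dprime(0.9, 0.1), 2.5631031310892007, tolerance = 1e-9)
  for (p in c(0.1, 0.23, 0.5, 0.77)) expect_equal(dprime(p, p), 0)
  expect_equal(dprime(0.61, 0.23), -dprime(0.23, 0.61))
})

test_that("corrected performance follows the guessing correction", {
  expect_equal(corrected_performance(0.61, 0.23), (0.61 - 0.23) / 0.77)
  expect_equal(corrected_performance(0.4, 0), 0.4)
  expect_equal(corrected_performance(0.23, 0.23), 0)
  expect_error(corrected_performance(0.5, 1), "fa must be")
})

test_that("threshold at d' = 1 matches a dense-grid search on the curve", {
  fit <- fake_fit(12, 10, 0.23, 0)
  fa <- 0.23
  thr <- threshold_at_dprime(fit, fa)
  expect_true(attr(thr, "defined"))
  # grid oracle at 1e-3 ms resolution
  xs <- seq(0.001, 300, by = 0.001)
  sens <- qnorm(psi_fun(xs, fit$m, fit$w, fit$gamma, fit$lam)) - qnorm(fa)
  grid_thr <- xs[which.min(abs(sens - 1))]
  expect_equal(as.numeric(thr), grid_thr, tolerance = 1e-3)
  # the hit rate at threshold is the d' = 1 equivalent ~0.603 for FA = 0.23
  expect_equal(psi_fun(as.numeric(thr), fit$m, fit$w, fit$gamma, fit$lam),
               pnorm(1 + qnorm(0.23)), tolerance = 1e-8)
})

test_that("threshold is undefined when the asymptote cannot reach the target", {
  low_asymptote <- fake_fit(12, 10, 0.23, 0.5)   # Psi(Inf) = 0.5 < 0.603
  thr <- threshold_at_dprime(low_asymptote, 0.23)
  expect_true(is.na(thr))
  expect_false(attr(thr, "defined"))
  expect_true(is.na(slope_at_threshold(low_asymptote, 0.23)))
  # degenerate target 0 with gamma = fa: curve starts at the target
  thr0 <- threshold_at_dprime(fake_fit(12, 10, 0.23, 0), 0.23, target = 0)
  expect_false(attr(thr0, "defined"))
})

test_that("threshold grows with midpoint and width", {
  fa <- 0.23
  thr_m <- vapply(c(8, 12, 16, 24), function(m)
    as.numeric(threshold_at_dprime(fake_fit(m, 10, 0.23, 0.05), fa)),
    numeric(1))
  expect_true(all(diff(thr_m) > 0))
  thr_w <- vapply(c(5, 10, 20, 40), function(w)
    as.numeric(threshold_at_dprime(fake_fit(12, w, 0.23, 0.05), fa)),
    numeric(1))
  expect_true(all(diff(thr_w) > 0))
})

test_that("slope at threshold matches the analytic chain rule", {
  fit <- fake_fit(12, 10, 0.2, 0.05)
  fa <- 0.23
  thr <- as.numeric(threshold_at_dprime(fit, fa))
  slp <- as.numeric(slope_at_threshold(fit, fa))
  # d/dx z(Psi) = Psi'(x) / phi(z(Psi(x))), Psi' via the Gumbel density
  b <- (log(-log(0.1)) - log(-log(0.9))) / fit$w
  eta <- log(log(2)) + b * (thr - fit$m)
  psi_prime <- (1 - fit$gamma - fit$lam) * b * exp(eta - exp(eta))
  analytic <- psi_prime / dnorm(qnorm(psi_fun(thr, fit$m, fit$w,
                                              fit$gamma, fit$lam)))
  expect_equal(slp, analytic, tolerance = 1e-6)
  expect_gt(slp, 0)
  # doubling the width halves the slope at threshold
  slp2 <- as.numeric(slope_at_threshold(fake_fit(12, 20, 0.2, 0.05), fa))
  expect_equal(slp2, slp / 2, tolerance = 1e-4)
  # near-flat curve: slope collapses toward zero
  expect_lt(as.numeric(slope_at_threshold(fake_fit(12, 4000, 0.2, 0.05), fa)),
            0.002)
})

test_that("empirical lapse rate is the error rate at the longest gap", {
  s <- make_counts_session(c(10, 270), c(10, 20), c(10, 19))
  expect_equal(empirical_lapse_rate(s), 0.05)   # 1 miss in 20 at 270 ms
  s_all <- make_counts_session(c(10, 270), c(10, 20), c(10, 20))
  expect_equal(empirical_lapse_rate(s_all), 0)
  # manual tally with excluded trials filtered
  s_mix <- make_session(c(270, 270, 270, 50), c("gap", "nogap", "gap", "gap"),
                        excluded_reason = c("none", "none", "correction",
                                            "none"))
  expect_equal(empirical_lapse_rate(s_mix), 0.5)
})

test_that("asymptotic sensitivity dominates d' at any finite gap", {
  fit <- fake_fit(12, 10, 0.23, 0.05)
  fa <- 0.23
  ms <- max_sensitivity(fit, fa)
  expect_equal(ms, qnorm(0.95) - qnorm(0.23), tolerance = 1e-9)
  expect_equal(ms, 2.383700476136686, tolerance = 1e-9)
  xs <- c(1, 5, 12, 50, 270, 1000)
  d_at <- qnorm(psi_fun(xs, fit$m, fit$w, fit$gamma, fit$lam)) - qnorm(fa)
  expect_true(all(ms >= d_at))
  # zero fitted lapse: clipping keeps the value large but finite
  big <- max_sensitivity(fake_fit(12, 10, 0.2, 0), 0.23, n_clip = 100L)
  expect_true(is.finite(big))
  expect_equal(big, qnorm(1 - 1 / 200) - qnorm(0.23))
})

test_that("per-session summary extracts all five measures coherently", {
  obs <- observer_model()
  s <- simulate_session(obs, schedule_spec("ferret", n_trials = 1500),
                        seed = 21)
  row <- sdt_summary(s)
  expect_equal(row$fa_rate, with(build_percent_gap(s), k[1] / n[1]))
  expect_gt(row$threshold_ms, 0)
  expect_gt(row$slope_dprime_per_ms, 0)
  expect_gte(row$max_sensitivity,
             dprime(clip_rate(row$hit_rate_at_threshold, 100),
                    clip_rate(row$fa_rate, row$n_nogap)) - 1e-6)
  expect_equal(row$hit_rate_at_threshold,
               pnorm(1 + qnorm(clip_rate(row$fa_rate, row$n_nogap))),
               tolerance = 1e-6)
})
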