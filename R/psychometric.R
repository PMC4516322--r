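#' Right-weighted Gumbel (log-Weibull) CDF in the midpoint/width parameterization
#'
#' Sigmoid core used for gap-detection psychometric functions:
#' `F(x) = 1 - exp(-exp(a + b * x))` on a linear gap-length axis, with the
#' intercept `a` and slope `b` solved so that `F(m) = 0.5` and the distance
#' between the `F = 0.1` and `F = 0.9` points equals `w` (the "mw0.1"
#' convention: `m` is the midpoint, `w` the width between the 10% and 90%
#' points of the core sigmoid). This core approaches its upper asymptote more
#' slowly than its lower one, matching the right-weighted shape of gap
#' detection data on a linear ms axis.
#'
#' @param x gap length(s), ms.
#' @param m midpoint, ms (the gap length at which `F = 0.5`).
#' @param w width, ms; distance between the `F = 0.1` and `F = 0.9` points.
#'   Must be positive.
#' @return `F(x)`, a probability in (0, 1).
#' @examples
#' gumbel_cdf(10, m = 10, w = 8)          # exactly 0.5
#' gumbel_qf(0.9, 10, 8) - gumbel_qf(0.1, 10, 8)  # exactly 8
#' @export
gumbel_cdf <- function(x, m, w) {
  ab <- gumbel_coefs(m, w)
  1 - exp(-exp(ab[1] + ab[2] * x))
}

#' @rdname gumbel_cdf
#' @param p probability in (0, 1).
#' @return `gumbel_qf`: the gap length at which `F(x) = p`.
#' @export
gumbel_qf <- function(p, m, w) {
  ab <- gumbel_coefs(m, w)
  (log(-log(1 - p)) - ab[1]) / ab[2]
}

# a, b of F(x) = 1 - exp(-exp(a + b x)) under the mw0.1 constraints
gumbel_coefs <- function(m, w) {
  if (!is.numeric(w) || any(w <= 0)) stop("width w must be > 0")
  b <- (log(-log(0.1)) - log(-log(0.9))) / w
  a <- log(log(2)) - b * m
  c(a, b)
}

#' Psychometric response probability with guess and lapse processes
#'
#' `Psi(x) = gamma + (1 - gamma - lam) * F(x; m, w)`: the probability of a
#' "gap" report at gap length `x` for an observer with guess (false-alarm)
#' rate `gamma` and lapse probability `lam` riding on the Gumbel core.
#'
#' @inheritParams gumbel_cdf
#' @param gamma lower asymptote (guess / false-alarm probability).
#' @param lam lapse probability; upper asymptote is `1 - lam`.
#' @export
psi_fun <- function(x, m, w, gamma, lam) {
  gamma + (1 - gamma - lam) * gumbel_cdf(x, m, w)
}

#' Build a per-session percent-gap function
#'
#' Tabulates "gap" responses against gap length from the analyzable trials of
#' one session. Levels at `x > 0` carry hit counts; the `x = 0` level carries
#' the no-gap *incorrect* ("gap") count, anchoring the function at the
#' empirical false-alarm rate.
#'
#' @param session a session trial table (see [read_trials()]); excluded
#'   trials (correction, center-reward) are dropped first.
#' @return an object of class `percent_gap` with fields `x` (gap lengths, ms,
#'   sorted, 0 first when no-gap trials exist), `n` (trials per level) and
#'   `k` ("gap" responses per level).
#' @export
build_percent_gap <- function(session) {
  tr <- session[!session$excluded, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no analyzable trials in session")
  x <- sort(unique(tr$gap_ms))
  n <- k <- integer(length(x))
  for (i in seq_along(x)) {
    at <- tr[tr$gap_ms == x[i], , drop = FALSE]
    n[i] <- nrow(at)
    k[i] <- sum(at$response == "gap")
  }
  structure(list(x = x, n = n, k = k), class = "percent_gap")
}

#' @export
print.percent_gap <- function(x, ...) {
  cat("percent-gap function (", length(x$x), " levels)\n", sep = "")
  print(data.frame(gap_ms = x$x, n = x$n, k = x$k, p = round(x$k / x$n, 3)))
  invisible(x)
}

# negative binomial log-likelihood of (m, w, gamma, lam) for a percent-gap
# function; Psi clipped away from {0,1} so the objective stays finite
nll_pgf <- function(par, pgf, eps = 1e-9) {
  psi <- psi_fun(pgf$x, par[1], par[2], par[3], par[4])
  psi <- pmin(pmax(psi, eps), 1 - eps)
  -sum(pgf$k * log(psi) + (pgf$n - pgf$k) * log(1 - psi))
}

# analytic gradient of nll_pgf; clipped levels contribute ~0 anyway
nll_grad_pgf <- function(par, pgf, eps = 1e-9) {
  m <- par[1]; w <- par[2]; g <- par[3]; l <- par[4]
  b <- (log(-log(0.1)) - log(-log(0.9))) / w
  eta <- log(log(2)) + b * (pgf$x - m)
  ee <- exp(eta)
  F <- 1 - exp(-ee)
  dF_deta <- exp(eta - ee)   # = ee * exp(-ee), stable for large eta
  psi <- pmin(pmax(g + (1 - g - l) * F, eps), 1 - eps)
  # d(nll)/d(psi) per level
  dpsi <- -(pgf$k / psi - (pgf$n - pgf$k) / (1 - psi))
  amp <- (1 - g - l)
  c(sum(dpsi * amp * dF_deta * (-b)),
    sum(dpsi * amp * dF_deta * (-b * (pgf$x - m) / w)),
    sum(dpsi * (1 - F)),
    sum(dpsi * (-F)))
}

#' Fit the psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of
#' `Psi(x) = gamma + (1 - gamma - lam) * F(x; m, w)` over the four parameters
#' with box constraints (`m` within twice the tested range, `w` up to four
#' times the range, `gamma <= 0.5`, `lam <= 0.3`) from a deterministic
#' multi-start grid over (m, w) seeded with empirical guess/lapse anchors.
#' Ties between converged starts are broken by higher log-likelihood, then
#' smaller width.
#'
#' @param pgf a [build_percent_gap()] object with at least 4 levels.
#' @param n_starts_per_axis grid resolution over m and w (default 5 x 5).
#' @return an object of class `psychometric_fit`: `m`, `w`, `gamma`, `lam`,
#'   `loglik`, `deviance`, plus `gof_percentile`/`accepted` slots filled in by
#'   [bootstrap_gof()].
#' @seealso [deviance_pgf()], [bootstrap_gof()]
#' @export
fit_psychometric <- function(pgf, n_starts_per_axis = 5L) {
  stopifnot(inherits(pgf, "percent_gap"))
  xpos <- pgf$x[pgf$x > 0]
  if (length(pgf$x) < 4L) stop("need at least 4 stimulus levels to fit")
  rng <- max(xpos) - min(xpos)
  lower <- c(min(xpos), 1e-3, 0, 0)
  upper <- c(2 * max(xpos), 4 * rng, 0.5, 0.3)

  # empirical anchors: gamma from the x = 0 level, lambda from the top level
  p_emp <- pgf$k / pgf$n
  g0 <- if (pgf$x[1] == 0) min(p_emp[1], 0.49) else 0.1
  l0 <- min(max(1 - p_emp[length(p_emp)], 0.001), 0.29)

  ms <- seq(min(xpos), max(xpos), length.out = n_starts_per_axis)
  ws <- seq(rng / 10, 2 * rng, length.out = n_starts_per_axis)
  starts <- as.matrix(expand.grid(m = ms, w = ws, KEEP.OUT.ATTRS = FALSE))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- c(starts[i, 1], starts[i, 2], g0, l0)
    fit <- try(stats::optim(st, nll_pgf, gr = nll_grad_pgf, pgf = pgf,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed from every start")
  par <- best$par
  out <- structure(
    list(m = par[1], w = par[2], gamma = par[3], lam = par[4],
         loglik = -best$value, deviance = NA_real_,
         gof_percentile = NA_real_, accepted = NA),
    class = "psychometric_fit")
  out$deviance <- deviance_pgf(out, pgf)
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: m = %.3f ms, w = %.3f ms, gamma = %.3f, lam = %.3f\n",
    x$m, x$w, x$gamma, x$lam))
  cat(sprintf("  loglik = %.3f, deviance = %.3f", x$loglik, x$deviance))
  if (!is.na(x$gof_percentile)) {
    cat(sprintf(", GOF percentile = %.1f (%s)", x$gof_percentile,
                if (isTRUE(x$accepted)) "accepted" else "discarded"))
  }
  cat("\n")
  invisible(x)
}

#' Binomial deviance of a fitted psychometric function
#'
#' `D = 2 * sum(k log(k / (n Psi)) + (n - k) log((n - k) / (n (1 - Psi))))`
#' with the convention `0 * log(0) = 0`: twice the log-likelihood gap between
#' the fitted and saturated binomial models. Always nonnegative.
#'
#' @param fit a `psychometric_fit`.
#' @param pgf the percent-gap function it was fitted to.
#' @export
deviance_pgf <- function(fit, pgf) {
  psi <- psi_fun(pgf$x, fit$m, fit$w, fit$gamma, fit$lam)
  psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
  xlogy <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  2 * sum(xlogy(pgf$k, pgf$n * psi) + xlogy(pgf$n - pgf$k, pgf$n * (1 - psi)))
}

#' Parametric deviance bootstrap goodness-of-fit test
#'
#' Simulates `n_boot` replicate datasets `k* ~ Binomial(n, Psi_hat)` at the
#' observed levels, refits each (starting from the original fit), and collects
#' the refit deviances. The fit is accepted when the observed deviance does
#' not exceed the 95th percentile of the bootstrap deviance distribution;
#' fits above it are flagged for discard.
#'
#' @param fit a `psychometric_fit`.
#' @param pgf the percent-gap function it was fitted to.
#' @param n_boot bootstrap replicates (1000 in the canonical analysis).
#' @param seed integer seed for reproducibility.
#' @param refit_starts extra multi-start grid resolution for refits; the
#'   default refits from the original parameters only, which is fast and
#'   adequate because replicates are drawn from the fitted model.
#' @return the fit with `gof_percentile` (percentile rank of the observed
#'   deviance within the bootstrap distribution, 0-100) and `accepted` filled
#'   in, plus attributes `boot_deviances` and `n_refit_failures`.
#' @export
bootstrap_gof <- function(fit, pgf, n_boot = 1000L, seed = 1L,
                          refit_starts = 0L) {
  stopifnot(inherits(fit, "psychometric_fit"), inherits(pgf, "percent_gap"))
  set.seed(seed)
  psi <- psi_fun(pgf$x, fit$m, fit$w, fit$gamma, fit$lam)
  psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
  xpos <- pgf$x[pgf$x > 0]
  rng <- max(xpos) - min(xpos)
  lower <- c(min(xpos), 1e-3, 0, 0)
  upper <- c(2 * max(xpos), 4 * rng, 0.5, 0.3)
  par0 <- c(fit$m, fit$w, fit$gamma, fit$lam)

  dev_star <- rep(NA_real_, n_boot)
  failures <- 0L
  for (b in seq_len(n_boot)) {
    kb <- stats::rbinom(length(pgf$x), pgf$n, psi)
    pgb <- structure(list(x = pgf$x, n = pgf$n, k = kb), class = "percent_gap")
    ref <- try(stats::optim(par0, nll_pgf, gr = nll_grad_pgf, pgf = pgb,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 300)), silent = TRUE)
    if (refit_starts > 0L) {
      ref2 <- try(fit_psychometric(pgb, n_starts_per_axis = refit_starts),
                  silent = TRUE)
      if (!inherits(ref2, "try-error") &&
          (inherits(ref, "try-error") || -ref2$loglik < ref$value)) {
        ref <- list(par = c(ref2$m, ref2$w, ref2$gamma, ref2$lam),
                    value = -ref2$loglik)
      }
    }
    if (inherits(ref, "try-error")) {
      failures <- failures + 1L
      next
    }
    fb <- list(m = ref$par[1], w = ref$par[2],
               gamma = ref$par[3], lam = ref$par[4])
    dev_star[b] <- deviance_pgf(fb, pgb)
  }
  if (failures > 0.05 * n_boot) {
    warning(sprintf("bootstrap refit failed on %d of %d replicates",
                    failures, n_boot))
  }
  dev_star <- dev_star[!is.na(dev_star)]
  cut95 <- stats::quantile(dev_star, 0.95, names = FALSE, type = 7)
  fit$gof_percentile <- 100 * mean(dev_star < fit$deviance)
  fit$accepted <- fit$deviance <= cut95
  attr(fit, "boot_deviances") <- dev_star
  attr(fit, "n_refit_failures") <- failures
  fit
}
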