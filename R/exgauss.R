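#' Ex-Gaussian log-density
#'
#' Log-density of the ex-Gaussian (Normal(mu, sigma) + Exponential(tau))
#' latency model:
#' `log f(t) = -log(tau) + sigma^2/(2 tau^2) - (t - mu)/tau +
#'  log Phi((t - mu)/sigma - sigma/tau)`,
#' with the Gaussian tail term computed through `pnorm(log.p = TRUE)` so the
#' asymptotic branch is numerically stable for small `tau` and extreme `t`.
#'
#' @param t latency value(s), s.
#' @param mu,sigma,tau parameters, s; `sigma`, `tau` > 0.
#' @return log-density (may be `-Inf`).
#' @export
exgauss_logpdf <- function(t, mu, sigma, tau) {
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be positive")
  z <- (t - mu) / sigma - sigma / tau
  -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    stats::pnorm(z, log.p = TRUE)
}

#' Fit an ex-Gaussian distribution by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of the ex-Gaussian
#' log-likelihood from a moment-based start: the exponential component is
#' initialized from the sample skewness (`tau0 = sd * (skew/2)^(1/3)`), the
#' Gaussian mean from `mean - tau0` and the Gaussian SD from the residual
#' variance. `sigma` and `tau` are bounded below at 1e-4 s.
#'
#' @param samples latency sample, s; at least 20 values with nonzero spread.
#' @return an `exgauss_fit` list: `mu`, `sigma`, `tau` (s), `loglik`, `n`,
#'   `converged`.
#' @export
fit_exgauss <- function(samples) {
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples")
  sd0 <- stats::sd(samples)
  if (!is.finite(sd0) || sd0 == 0) stop("degenerate sample: zero variance")
  m1 <- mean(samples)
  skew <- mean((samples - m1)^3) / sd0^3
  tau0 <- max(sd0 * (max(skew, 0.01) / 2)^(1 / 3), 1e-3)
  tau0 <- min(tau0, 0.95 * sd0 + 1e-3)
  mu0 <- m1 - tau0
  sig0 <- sqrt(max(sd0^2 - tau0^2, 1e-6))

  nll <- function(par) -sum(exgauss_logpdf(samples, par[1], par[2], par[3]))
  lower <- c(-Inf, 1e-4, 1e-4)
  fit <- stats::optim(c(mu0, sig0, tau0), nll, method = "L-BFGS-B",
                      lower = lower, control = list(maxit = 500))
  structure(list(mu = fit$par[1], sigma = fit$par[2], tau = fit$par[3],
                 loglik = -fit$value, n = n,
                 converged = fit$convergence == 0L),
            class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf(
    "ex-Gaussian fit (n = %d): mu = %.4f s, sigma = %.4f s, tau = %.4f s\n",
    x$n, x$mu, x$sigma, x$tau))
  cat(sprintf("  loglik = %.2f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Fit ex-Gaussian latency distributions by subgroup
#'
#' Splits trials by the requested grouping columns (e.g. stimulus band,
#' response side, correct x trial type) and fits each cell with at least
#' `min_n` analyzable latencies.
#'
#' @param trials a trial table (one or more sessions row-bound).
#' @param by character vector of grouping column names.
#' @param min_n minimum latencies per cell (cells below it are dropped).
#' @return data frame: one row per cell with `mu`, `sigma`, `tau`, `n`,
#'   `loglik`, `converged`.
#' @export
fit_exgauss_by <- function(trials, by = "stimulus_band", min_n = 20L) {
  tr <- trials[!trials$excluded & is.finite(trials$rt_s), , drop = FALSE]
  cells <- split(tr, tr[, by, drop = FALSE], drop = TRUE)
  rows <- lapply(cells, function(cell) {
    if (nrow(cell) < min_n) return(NULL)
    f <- fit_exgauss(cell$rt_s)
    cbind(unique(cell[, by, drop = FALSE])[1, , drop = FALSE],
          data.frame(mu = f$mu, sigma = f$sigma, tau = f$tau, n = f$n,
                     loglik = f$loglik, converged = f$converged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
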