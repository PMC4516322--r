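#' Clip a response rate away from 0 and 1 before z-transforming
#'
#' Standard correction for perfect rates: rates are confined to
#' `[1/(2N), 1 - 1/(2N)]`, `N` the number of trials behind the rate, so the
#' inverse-normal transform stays finite.
#'
#' @param p rate(s) in [0, 1].
#' @param n trial count(s) behind each rate.
#' @export
clip_rate <- function(p, n) {
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Sensitivity index d-prime
#'
#' `d' = z(Hit) - z(FA)`, `z` the inverse standard-normal CDF. Rates should
#' already be clipped into (0, 1) (see [clip_rate()]).
#'
#' @param hit,fa hit and false-alarm rates in (0, 1).
#' @examples
#' dprime(0.61, 0.23)   # ~ 1.02: threshold-level performance at FA = 0.23
#' @export
dprime <- function(hit, fa) {
  stats::qnorm(hit) - stats::qnorm(fa)
}

#' False-alarm-corrected proportion correct
#'
#' `(hit - fa) / (1 - fa)`: the classic guessing correction; 0.5 corresponds
#' to the d' = 1 threshold at the population false-alarm rate of 0.23.
#'
#' @inheritParams dprime
#' @export
corrected_performance <- function(hit, fa) {
  if (any(fa >= 1)) stop("fa must be < 1")
  (hit - fa) / (1 - fa)
}

#' Gap-detection threshold: gap length at a target d-prime
#'
#' Finds the gap length at which the fitted curve's sensitivity
#' `z(Psi(x)) - z(fa)` reaches `target` (default d' = 1), by bracketed
#' root-finding on the fitted psychometric function with the *empirical*
#' false-alarm rate in the z(FA) term. Undefined (returned as `NA` with
#' attribute `defined = FALSE`) when the curve's asymptotic sensitivity
#' never reaches the target.
#'
#' @param fit a `psychometric_fit`.
#' @param fa empirical false-alarm rate (clipped into (0, 1) beforehand).
#' @param target sensitivity criterion, d' units.
#' @param x_hi upper bracket, ms; defaults to far beyond the fitted midpoint.
#' @return threshold in ms, or `NA` when undefined.
#' @export
threshold_at_dprime <- function(fit, fa, target = 1, x_hi = NULL) {
  stopifnot(fa > 0, fa < 1)
  hit_target <- stats::pnorm(target + stats::qnorm(fa))
  psi_inf <- fit$gamma + (1 - fit$gamma - fit$lam)
  if (psi_inf <= hit_target || fit$gamma >= hit_target) {
    # asymptote below target, or already above it at x -> -Inf
    return(structure(NA_real_, defined = FALSE))
  }
  if (is.null(x_hi)) x_hi <- fit$m + 20 * fit$w
  g <- function(x) psi_fun(x, fit$m, fit$w, fit$gamma, fit$lam) - hit_target
  lo <- min(0, fit$m - 20 * fit$w)
  if (g(x_hi) < 0 || g(lo) > 0) return(structure(NA_real_, defined = FALSE))
  root <- stats::uniroot(g, c(lo, x_hi), tol = 1e-9)$root
  structure(root, defined = TRUE)
}

#' Psychometric slope at threshold, in d'/ms
#'
#' Central-difference derivative of `z(Psi(x)) - z(fa)` at the d' = 1
#' threshold (step `1e-3 * w`): the rate at which session performance
#' approaches asymptote.
#'
#' @inheritParams threshold_at_dprime
#' @return slope in d' per ms, or `NA` when the threshold is undefined.
#' @export
slope_at_threshold <- function(fit, fa, target = 1) {
  thr <- threshold_at_dprime(fit, fa, target)
  if (!isTRUE(attr(thr, "defined"))) return(structure(NA_real_, defined = FALSE))
  h <- 1e-3 * fit$w
  dsens <- function(x) stats::qnorm(psi_fun(x, fit$m, fit$w,
                                            fit$gamma, fit$lam))
  structure((dsens(thr + h) - dsens(thr - h)) / (2 * h), defined = TRUE)
}

#' Empirical lapse rate
#'
#' Proportion of incorrect responses among analyzable trials at the session's
#' longest tested gap length: errors on the easiest stimuli, reflecting
#' inattention rather than sensory limits.
#'
#' @param session a `gap_session`.
#' @export
empirical_lapse_rate <- function(session) {
  tr <- session[!session$excluded & session$gap_ms > 0, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no analyzable gap trials")
  at_max <- tr[tr$gap_ms == max(tr$gap_ms), , drop = FALSE]
  mean(!at_max$correct)
}

#' Asymptotic sensitivity of a fitted curve
#'
#' d' at the fitted function's upper asymptote:
#' `z(Psi(Inf)) - z(fa)` with `Psi(Inf) = gamma + (1 - gamma - lam) = 1 - lam`,
#' the asymptote clipped by [clip_rate()] with `n_clip` trials so that a
#' zero fitted lapse yields a large but finite d'.
#'
#' @inheritParams threshold_at_dprime
#' @param n_clip trial count used to clip the asymptote (default 100).
#' @export
max_sensitivity <- function(fit, fa, n_clip = 100L) {
  psi_inf <- clip_rate(fit$gamma + (1 - fit$gamma - fit$lam), n_clip)
  dprime(psi_inf, fa)
}

#' Full per-session SDT performance summary
#'
#' Extracts the five performance measures from one session's accepted
#' psychometric fit: empirical false-alarm rate, threshold (ms at d' = 1),
#' slope at threshold (d'/ms), lapse rate (both the empirical longest-gap
#' error rate and the fitted lapse parameter), and asymptote sensitivity.
#'
#' @param session a `gap_session`.
#' @param fit its `psychometric_fit` (fitted to [build_percent_gap()] of the
#'   same session); if `NULL`, fitted here.
#' @param target sensitivity criterion for the threshold, d' units.
#' @return one-row data frame: `subject`, `session`, `stimulus_band`,
#'   `fa_rate`, `n_nogap`, `threshold_ms`, `slope_dprime_per_ms`,
#'   `lapse_rate`, `fitted_lapse`, `max_sensitivity`,
#'   `hit_rate_at_threshold`, `gof_accepted`.
#' @export
sdt_summary <- function(session, fit = NULL, target = 1) {
  pgf <- build_percent_gap(session)
  if (is.null(fit)) fit <- fit_psychometric(pgf)
  if (pgf$x[1] != 0) stop("session has no no-gap trials: FA rate undefined")
  n0 <- pgf$n[1]
  fa <- clip_rate(pgf$k[1] / n0, n0)
  thr <- threshold_at_dprime(fit, fa, target)
  slp <- slope_at_threshold(fit, fa, target)
  hit_at_thr <- if (isTRUE(attr(thr, "defined"))) {
    psi_fun(as.numeric(thr), fit$m, fit$w, fit$gamma, fit$lam)
  } else NA_real_
  data.frame(
    subject = session$subject[1], session = session$session[1],
    stimulus_band = session$stimulus_band[1],
    fa_rate = pgf$k[1] / n0, n_nogap = n0,
    threshold_ms = as.numeric(thr),
    slope_dprime_per_ms = as.numeric(slp),
    lapse_rate = empirical_lapse_rate(session),
    fitted_lapse = fit$lam,
    max_sensitivity = max_sensitivity(fit, fa),
    hit_rate_at_threshold = hit_at_thr,
    gof_accepted = if (is.na(fit$accepted)) NA else fit$accepted,
    stringsAsFactors = FALSE)
}
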