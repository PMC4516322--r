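# build a minimal consistent gap_session from gap lengths and responses
make_session <- function(gap_ms, response,
                         subject = "F01", session = 1L,
                         stimulus_band = "BBN",
                         rt_s = NULL, excluded_reason = NULL) {
  n <- length(gap_ms)
  stopifnot(length(response) == n)
  if (is.null(rt_s)) rt_s <- rep(1.5, n)
  if (is.null(excluded_reason)) excluded_reason <- rep("none", n)
  is_gap <- gap_ms > 0
  says_gap <- response == "gap"
  s <- data.frame(
    subject = rep(subject, length.out = n),
    session = rep(session, length.out = n),
    stimulus_band = rep(stimulus_band, length.out = n),
    gap_ms = gap_ms, is_gap_trial = is_gap, response = response,
    correct = says_gap == is_gap, rt_s = rt_s,
    response_side = ifelse(says_gap, "left", "right"),
    excluded = excluded_reason != "none",
    excluded_reason = excluded_reason,
    stringsAsFactors = FALSE)
  class(s) <- c("gap_session", "data.frame")
  s
}

# session with exact per-level counts: k "gap" responses out of n at each gap
make_counts_session <- function(x, n, k, ...) {
  gap_ms <- rep(x, n)
  response <- unlist(mapply(function(ki, ni) {
    c(rep("gap", ki), rep("nogap", ni - ki))
  }, k, n, SIMPLIFY = FALSE))
  make_session(gap_ms, response, ...)
}

# a psychometric_fit-shaped object with chosen parameters (for measure tests)
fake_fit <- function(m, w, gamma, lam) {
  structure(list(m = m, w = w, gamma = gamma, lam = lam,
                 loglik = NA_real_, deviance = NA_real_,
                 gof_percentile = NA_real_, accepted = TRUE),
            class = "psychometric_fit")
}
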