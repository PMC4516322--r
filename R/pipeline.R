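#' Run the per-session analysis pipeline
#'
#' For each session: apply the inclusion rule, build the percent-gap
#' function, fit the psychometric curve, optionally gate it with the
#' parametric deviance bootstrap, and extract the SDT performance summary.
#'
#' @param sessions list of `gap_session` data frames (from [read_trials()]
#'   or [simulate_session()]).
#' @param n_boot bootstrap replicates for goodness-of-fit gating; 0 skips
#'   the gate (every fit keeps `gof_accepted = NA`).
#' @param seed base seed; session b uses `seed + b` for its bootstrap.
#' @param keep_rejected keep sessions whose fit failed the GOF gate
#'   (flagged) instead of dropping their rows.
#' @return data frame of per-session [sdt_summary()] rows; sessions failing
#'   the inclusion rule are absent, with their ids in
#'   `attr(, "excluded_sessions")`.
#' @export
analyze_sessions <- function(sessions, n_boot = 1000L, seed = 1L,
                             keep_rejected = TRUE) {
  if (inherits(sessions, "gap_session")) sessions <- list(sessions)
  excluded <- character(0)
  rows <- vector("list", length(sessions))
  for (b in seq_along(sessions)) {
    s <- sessions[[b]]
    inc <- session_is_includable(s)
    if (!inc) {
      excluded <- c(excluded,
                    sprintf("%s/%s (%s)", s$subject[1], s$session[1],
                            attr(inc, "reason")))
      next
    }
    pgf <- build_percent_gap(s)
    fit <- fit_psychometric(pgf)
    if (n_boot > 0L) fit <- bootstrap_gof(fit, pgf, n_boot = n_boot,
                                          seed = seed + b)
    row <- sdt_summary(s, fit)
    if (!keep_rejected && isFALSE(row$gof_accepted)) next
    rows[[b]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded_sessions") <- excluded
  out
}
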