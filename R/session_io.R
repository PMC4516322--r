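#' Canonical trial-table columns
#'
#' Trial tables are comma-separated UTF-8 CSV with a header. Gap lengths are
#' in ms (0 encodes a no-gap trial), response times in seconds
#' (stimulus onset to peripheral spout), and excluded trials carry the reason
#' (`correction` or `center_reward`).
#' @keywords internal
trial_columns <- c("subject", "session", "stimulus_band", "gap_ms",
                   "is_gap_trial", "response", "correct", "rt_s",
                   "response_side", "excluded", "excluded_reason")

valid_bands <- c("NBN1k", "NBN4k", "NBN16k", "BBN")

#' Read trial tables into validated sessions
#'
#' Parses a canonical trial-table CSV, validates every row (known stimulus
#' band, nonnegative gap, `is_gap_trial` consistent with `gap_ms > 0`,
#' `correct` consistent with response vs trial type, gap responses on the
#' left spout), and splits the table into per-(subject, session) sessions.
#' Malformed rows raise an error naming their line numbers.
#'
#' @param path CSV file path.
#' @return a list of `gap_session` data frames, one per subject x session.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols)) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df$is_gap_trial <- as.logical(df$is_gap_trial)
  df$correct <- as.logical(df$correct)
  df$excluded <- as.logical(df$excluded)

  line_no <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s at line(s) %s", what,
                   paste(utils::head(line_no[cond], 10L), collapse = ", ")))
    }
  }
  bad(!df$stimulus_band %in% valid_bands, "unknown stimulus_band")
  bad(!is.finite(df$gap_ms) | df$gap_ms < 0, "negative or missing gap_ms")
  bad(!df$response %in% c("gap", "nogap"), "unknown response")
  bad(df$is_gap_trial != (df$gap_ms > 0),
      "is_gap_trial inconsistent with gap_ms")
  bad(df$correct != ((df$response == "gap") == df$is_gap_trial),
      "correct flag inconsistent with response and trial type")

  sessions <- split(df, interaction(df$subject, df$session, drop = TRUE))
  lapply(unname(sessions), function(s) {
    if (length(unique(s$stimulus_band)) > 1L) {
      stop(sprintf("subject %s session %s mixes stimulus bands",
                   s$subject[1], s$session[1]))
    }
    rownames(s) <- NULL
    class(s) <- c("gap_session", "data.frame")
    s
  })
}

#' Write a trial table (and optional generating-parameter sidecar)
#'
#' @param sessions a `gap_session` or list of them.
#' @param path output CSV path.
#' @param ground_truth_path optional JSON path; writes the generating
#'   parameters stored by [simulate_session()] for each session that has them.
#' @export
write_trials <- function(sessions, path, ground_truth_path = NULL) {
  if (inherits(sessions, "gap_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, function(s) {
    as.data.frame(s)[, trial_columns]
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ground_truth_path)) {
    gt <- lapply(sessions, attr, "ground_truth")
    names(gt) <- vapply(sessions, function(s)
      paste(s$subject[1], s$session[1], sep = "_"), character(1))
    jsonlite::write_json(gt, ground_truth_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Session inclusion rule
#'
#' A session enters analysis only when at least five distinct (positive) gap
#' lengths were each tested at least five times among its analyzable trials;
#' otherwise the psychometric fit is under-constrained and the session is
#' excluded. Excluded (correction / center-reward) trials are filtered first;
#' the gap = 0 no-gap anchor does not count toward the five lengths.
#'
#' @param session a `gap_session`.
#' @param min_lengths,min_trials rule constants (5 and 5).
#' @return logical flag with a `reason` attribute
#'   (`"ok"`, `"empty"`, or `"too_few_gap_lengths_tested"`).
#' @export
session_is_includable <- function(session, min_lengths = 5L, min_trials = 5L) {
  tr <- session[!session$excluded, , drop = FALSE]
  if (nrow(tr) == 0L) {
    return(structure(FALSE, reason = "empty"))
  }
  counts <- table(tr$gap_ms[tr$gap_ms > 0])
  if (sum(counts >= min_trials) >= min_lengths) {
    structure(TRUE, reason = "ok")
  } else {
    structure(FALSE, reason = "too_few_gap_lengths_tested")
  }
}

#' Noise-burst duration implied by a gap length
#'
#' Gaps are interleaved with centers evenly spaced so that total stimulus
#' duration is constant across gap lengths; the carrier is therefore divided
#' into `n_gaps + 1` equal noise bursts of duration
#' `(total_ms - n_gaps * gap_ms) / (n_gaps + 1)`. With the ferret defaults
#' (2,080 ms carrier, 4 gaps) the tested gap set 3-270 ms maps to bursts
#' 413.6 down to 200 ms.
#'
#' @param gap_ms gap length, ms (0 allowed: the no-gap stimulus).
#' @param total_ms total stimulus duration, ms.
#' @param n_gaps gaps per stimulus.
#' @return burst duration, ms; strictly decreasing in `gap_ms`.
#' @export
burst_duration <- function(gap_ms, total_ms = 2080, n_gaps = 4L) {
  if (any(gap_ms < 0)) stop("gap_ms must be nonnegative")
  if (any(n_gaps * gap_ms >= total_ms)) {
    stop("total gap time exceeds stimulus duration")
  }
  (total_ms - n_gaps * gap_ms) / (n_gaps + 1)
}
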