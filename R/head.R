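#' Construct a head-bearing trajectory
#'
#' A 60 frames/s horizontal head-bearing trace (degrees, rightward positive)
#' with optional platform-departure frame. The initial head bearing — used by
#' the population outlier screen — is the mean of the three frames preceding
#' stimulus onset (frame 1 here) unless supplied.
#'
#' @param t frame times, s, uniformly spaced at 1/60 s.
#' @param bearing head bearing per frame, deg.
#' @param departure_frame index of the frame at which the animal left the
#'   platform, or `NULL`.
#' @param initial_bearing pre-stimulus bearing, deg; defaults to the mean of
#'   the first three frames.
#' @export
head_trajectory <- function(t, bearing, departure_frame = NULL,
                            initial_bearing = NULL) {
  stopifnot(length(t) == length(bearing), length(t) >= 5L,
            all(is.finite(bearing)))
  dt <- diff(t)
  if (any(abs(dt - 1 / 60) > 1e-6)) stop("frames must be uniform at 60 fps")
  if (is.null(initial_bearing)) initial_bearing <- mean(bearing[1:3])
  structure(list(t = t, bearing = bearing,
                 departure_frame = departure_frame,
                 initial_bearing = initial_bearing),
            class = "head_trajectory")
}

#' Detect the initial head-orienting turn
#'
#' A head-turning response is a period of more than three consecutive frames
#' over which the head moves in the same rotational direction: the first run
#' of more than three consecutive same-sign frame-to-frame bearing changes
#' (a zero change breaks the run — no motion, no turn). The initial
#' head-turning response time is the time of the run's first frame.
#'
#' @param traj a [head_trajectory()].
#' @return a `head_turn` list: `detected`, `onset_s`, `final_s` (time of the
#'   run's last frame), `final_bearing_deg` (mean of the run's last three
#'   frames), `direction` (`"left"`/`"right"`), and frame indices
#'   `run_start`, `run_end`.
#' @export
detect_head_turn <- function(traj) {
  stopifnot(inherits(traj, "head_trajectory"))
  s <- sign(diff(traj$bearing))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values != 0 & r$lengths > 3L)
  if (length(hit) == 0L) {
    return(structure(list(detected = FALSE, onset_s = NA_real_,
                          final_s = NA_real_, final_bearing_deg = NA_real_,
                          direction = NA_character_,
                          run_start = NA_integer_, run_end = NA_integer_),
                     class = "head_turn"))
  }
  i <- hit[1]
  run_start <- starts[i]            # frame index of the run's first frame
  run_end <- ends[i] + 1L           # diffs i..j span frames i..j+1
  structure(list(
    detected = TRUE,
    onset_s = traj$t[run_start],
    final_s = traj$t[run_end],
    final_bearing_deg = mean(traj$bearing[(run_end - 2L):run_end]),
    direction = if (r$values[i] > 0) "right" else "left",
    run_start = run_start, run_end = run_end),
    class = "head_turn")
}

#' Final head bearing of a trial
#'
#' Mean of the last three frames of the initial continuous head movement, or,
#' when no head movement was detected, the mean of the final three frames
#' recorded before the animal left the platform.
#'
#' @param traj a [head_trajectory()].
#' @param turn its [detect_head_turn()] result; computed here if missing.
#' @return final bearing, deg.
#' @export
final_bearing <- function(traj, turn = NULL) {
  if (is.null(turn)) turn <- detect_head_turn(traj)
  if (turn$detected) return(turn$final_bearing_deg)
  last <- if (!is.null(traj$departure_frame)) traj$departure_frame
          else length(traj$bearing)
  if (last < 3L) stop("fewer than 3 usable frames before departure")
  mean(traj$bearing[(last - 2L):last])
}

#' Screen out trials with atypical initial head bearing
#'
#' Single-pass population screen: removes trajectories whose initial bearing
#' lies more than 2 standard deviations from the population mean initial
#' bearing (mean and SD computed once over the input, not iteratively). A
#' zero-SD population removes nothing.
#'
#' @param trajs list of [head_trajectory()] objects (at least 3).
#' @param n_sd exclusion criterion in SD units.
#' @return the retained sublist, with attribute `excluded_idx`.
#' @export
exclude_bearing_outliers <- function(trajs, n_sd = 2) {
  stopifnot(length(trajs) >= 3L)
  ib <- vapply(trajs, function(tr) tr$initial_bearing, numeric(1))
  mu <- mean(ib)
  sd0 <- stats::sd(ib)
  drop <- abs(ib - mu) > n_sd * sd0   # sd0 = 0 => nothing exceeds 0
  structure(trajs[!drop], excluded_idx = which(drop))
}
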