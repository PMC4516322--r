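#' Synthetic gap-detection observer
#'
#' Parameter bundle for the simulated observer used to validate every stage of
#' the pipeline by parameter recovery. The observer reports "gap" with
#' probability `gamma + (1 - gamma - lam) * F(x; m, w)` at gap length `x`
#' (see [psi_fun()]), responds "gap" on no-gap trials with probability
#' `gamma`, draws approach-to-target latencies from an ex-Gaussian, and moves
#' its head with a constant-rate turn plus white per-frame bearing noise.
#'
#' Defaults describe a ferret-like broadband-noise observer: midpoint near the
#' behavioral threshold regime (~12 ms), width 10 ms, false-alarm rate 0.23,
#' lapse 0.05, and ex-Gaussian latencies with mu = 1.97 s, sigma = 0.3 s,
#' tau = 0.4 s.
#'
#' @param m midpoint of the internal psychometric function, ms.
#' @param w width (10-90% distance), ms; > 0.
#' @param gamma guess / false-alarm probability.
#' @param lam lapse probability; `gamma + lam < 1`.
#' @param rt_mu,rt_sigma,rt_tau ex-Gaussian latency parameters, s.
#' @param head_bias mean rightward drift rate of the head during a turn,
#'   deg/s (rightward positive).
#' @param head_noise per-frame bearing noise SD, deg.
#' @return an `observer_model` list.
#' @export
observer_model <- function(m = 12, w = 10, gamma = 0.23, lam = 0.05,
                           rt_mu = 1.97, rt_sigma = 0.3, rt_tau = 0.4,
                           head_bias = 50, head_noise = 0.5) {
  stopifnot(w > 0, gamma >= 0, lam >= 0, gamma + lam < 1,
            gamma <= 1, lam <= 1, rt_sigma > 0, rt_tau > 0,
            head_noise >= 0)
  structure(list(m = m, w = w, gamma = gamma, lam = lam,
                 rt_mu = rt_mu, rt_sigma = rt_sigma, rt_tau = rt_tau,
                 head_bias = head_bias, head_noise = head_noise),
            class = "observer_model")
}

#' Trial schedule specification
#'
#' Describes the pseudorandom stimulus schedule of one session. Ferret mode
#' uses the gap set {3, 5, 10, 20, 50, 100, 270} ms within a 2,080-ms noise
#' carrier holding four gaps; human mode uses {1, 2, 3, 4, 10} ms in a 400-ms
#' carrier with a single gap. Gap and no-gap trials are interleaved in a
#' 1:1 ratio by default, with the gap length on each gap trial drawn
#' uniformly from the gap set.
#'
#' @param species_mode `"ferret"` or `"human"`; sets the defaults below.
#' @param gap_set gap lengths, ms; strictly positive and distinct (gap 0 is
#'   reserved for no-gap trials).
#' @param n_trials number of scheduled trials.
#' @param gap_ratio fraction of gap trials (in (0, 1)).
#' @param total_noise_ms stimulus duration, ms.
#' @param n_gaps_per_stimulus gaps interleaved per gap stimulus.
#' @param stimulus_band one of `"NBN1k"`, `"NBN4k"`, `"NBN16k"`, `"BBN"`.
#' @export
schedule_spec <- function(species_mode = c("ferret", "human"),
                          gap_set = NULL, n_trials = 500L, gap_ratio = 0.5,
                          total_noise_ms = NULL, n_gaps_per_stimulus = NULL,
                          stimulus_band = "BBN") {
  species_mode <- match.arg(species_mode)
  if (is.null(gap_set)) {
    gap_set <- if (species_mode == "ferret") c(3, 5, 10, 20, 50, 100, 270)
               else c(1, 2, 3, 4, 10)
  }
  if (is.null(total_noise_ms)) {
    total_noise_ms <- if (species_mode == "ferret") 2080 else 400
  }
  if (is.null(n_gaps_per_stimulus)) {
    n_gaps_per_stimulus <- if (species_mode == "ferret") 4L else 1L
  }
  if (any(gap_set <= 0)) {
    stop("gap_set must be strictly positive; gap 0 encodes no-gap trials")
  }
  if (anyDuplicated(gap_set)) stop("gap_set values must be distinct")
  stopifnot(n_trials > 0, gap_ratio > 0, gap_ratio < 1,
            stimulus_band %in% c("NBN1k", "NBN4k", "NBN16k", "BBN"))
  structure(list(species_mode = species_mode, gap_set = as.numeric(gap_set),
                 n_trials = as.integer(n_trials), gap_ratio = gap_ratio,
                 total_noise_ms = total_noise_ms,
                 n_gaps_per_stimulus = as.integer(n_gaps_per_stimulus),
                 stimulus_band = stimulus_band),
            class = "schedule_spec")
}

#' Simulate one behavioral session
#'
#' Draws a pseudorandom trial schedule (gap vs no-gap under `gap_ratio`, gap
#' length uniform over the gap set), generates responses from the observer's
#' psychometric curve, attaches ex-Gaussian latencies, and emits the bookwork
#' the real task produces: correction trials after errors (ferret mode) and
#' occasional center-reward trials, both flagged `excluded` so that only
#' first-response, unrewarded-at-center trials enter analysis.
#'
#' @param observer an [observer_model()].
#' @param schedule a [schedule_spec()].
#' @param subject,session_id identifiers stamped on every trial.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @param p_center_reward probability of a center-spout reward trial
#'   (flagged and excluded), ferret mode only.
#' @return a `gap_session` data frame with the canonical trial columns
#'   (see [read_trials()]) and the generating parameters stored in
#'   `attr(, "ground_truth")`.
#' @export
simulate_session <- function(observer, schedule, subject = "S1",
                             session_id = 1L, seed = 1L,
                             p_center_reward = 0.05) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(schedule, "schedule_spec"))
  set.seed(seed)
  n <- schedule$n_trials
  is_gap <- stats::runif(n) < schedule$gap_ratio
  gap_ms <- numeric(n)
  gap_ms[is_gap] <- schedule$gap_set[
    sample.int(length(schedule$gap_set), sum(is_gap), replace = TRUE)]

  p_gap_resp <- ifelse(is_gap,
                       psi_fun(gap_ms, observer$m, observer$w,
                               observer$gamma, observer$lam),
                       observer$gamma)
  says_gap <- stats::runif(n) < p_gap_resp
  response <- ifelse(says_gap, "gap", "nogap")
  correct <- says_gap == is_gap
  # gap report -> left spout (-30 deg), no-gap -> right (+30 deg)
  response_side <- ifelse(says_gap, "left", "right")
  rt_s <- simulate_rts(observer$rt_mu, observer$rt_sigma, observer$rt_tau,
                       n, seed = NULL)

  excluded_reason <- rep("none", n)
  if (schedule$species_mode == "ferret") {
    # correction trial follows each error; flagged, never analyzed
    corr_next <- c(FALSE, !correct[-n])
    excluded_reason[corr_next] <- "correction"
    center <- stats::runif(n) < p_center_reward
    excluded_reason[center & excluded_reason == "none"] <- "center_reward"
  }
  out <- data.frame(
    subject = subject, session = session_id,
    stimulus_band = schedule$stimulus_band,
    gap_ms = gap_ms, is_gap_trial = is_gap,
    response = response, correct = correct,
    rt_s = rt_s, response_side = response_side,
    excluded = excluded_reason != "none",
    excluded_reason = excluded_reason,
    stringsAsFactors = FALSE)
  class(out) <- c("gap_session", "data.frame")
  attr(out, "ground_truth") <- list(
    observer = unclass(observer), schedule = unclass(schedule), seed = seed)
  out
}

#' Sample ex-Gaussian latencies
#'
#' `Normal(mu, sigma) + Exponential(tau)`: the standard latency-distribution
#' model. Sample mean converges to `mu + tau`, variance to `sigma^2 + tau^2`.
#'
#' @param mu,sigma,tau ex-Gaussian parameters, s (`sigma`, `tau` > 0).
#' @param n number of samples.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @export
simulate_rts <- function(mu, sigma, tau, n, seed = 1L) {
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Simulate a 60 frames/s head-bearing trajectory
#'
#' Emits a bearing trace (degrees, rightward positive) that is flat (noise
#' only) until `turn_onset_s`, then turns at the observer's `head_bias`
#' deg/s for `turn_frames` frame-to-frame steps toward `final_bearing_deg`,
#' then holds. The generating truth (onset, final bearing, direction) is
#' stored in `attr(, "ground_truth")` so rule-based extraction can be checked
#' exactly on noise-free traces.
#'
#' @param observer an [observer_model()]; `head_noise` sets the per-frame
#'   jitter SD and the sign of `final_bearing_deg` the direction.
#' @param duration_s trace duration, s.
#' @param turn_onset_s time of the first frame of the turn, s; `NA` embeds no
#'   turn.
#' @param final_bearing_deg bearing reached at the end of the turn, deg.
#' @param turn_frames number of same-direction frame-to-frame steps in the
#'   turn (detection requires more than 3).
#' @param initial_bearing_deg resting bearing before the turn, deg.
#' @param departure_frame optional index of the frame at which the animal
#'   leaves the platform.
#' @param seed integer seed.
#' @return a `head_trajectory` list: `t` (s), `bearing` (deg),
#'   `departure_frame`, `initial_bearing`.
#' @export
simulate_head_trajectory <- function(observer, duration_s = 1.5,
                                     turn_onset_s = 0.2,
                                     final_bearing_deg = 25,
                                     turn_frames = 10L,
                                     initial_bearing_deg = 0,
                                     departure_frame = NULL, seed = 1L) {
  stopifnot(inherits(observer, "observer_model"), duration_s > 0)
  set.seed(seed)
  fps <- 60
  nf <- max(5L, floor(duration_s * fps) + 1L)
  t <- (seq_len(nf) - 1L) / fps
  bearing <- rep(initial_bearing_deg, nf)
  truth <- list(turn = FALSE, onset_s = NA_real_,
                final_bearing_deg = NA_real_, direction = NA_character_)
  if (!is.na(turn_onset_s)) {
    i0 <- which.min(abs(t - turn_onset_s))        # first frame of the turn
    i1 <- min(i0 + turn_frames, nf)
    ramp <- seq(initial_bearing_deg, final_bearing_deg,
                length.out = i1 - i0 + 1L)
    bearing[i0:i1] <- ramp
    if (i1 < nf) bearing[(i1 + 1L):nf] <- final_bearing_deg
    # truth final bearing follows the measurement rule (mean of the turn's
    # last three frames), evaluated on the noise-free ramp
    truth <- list(turn = TRUE, onset_s = t[i0],
                  final_bearing_deg = mean(bearing[max(i0, i1 - 2L):i1]),
                  direction = if (final_bearing_deg >= initial_bearing_deg)
                    "right" else "left")
  }
  if (observer$head_noise > 0) {
    bearing <- bearing + stats::rnorm(nf, 0, observer$head_noise)
  }
  traj <- head_trajectory(t, bearing, departure_frame = departure_frame,
                          initial_bearing = initial_bearing_deg)
  attr(traj, "ground_truth") <- truth
  traj
}
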