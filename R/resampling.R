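#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' `stats::cor(method = "spearman")`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  stats::cor(x, y, method = "spearman")
}

#' Shuffle-and-resample significance test for a Spearman correlation
#'
#' Builds a null reference distribution for the observed correlation by, on
#' each of `n_boot` replicates, randomly shuffling each variable and then
#' resampling n values with replacement from each shuffled set before pairing
#' them and recomputing rho; the pairing is broken both by the shuffle and by
#' the independent resampling. The two-sided p value is
#' `(1 + #(|rho*| >= |rho_obs|)) / (n_boot + 1)` (the +1 keeps p > 0). A
#' pure-permutation null (shuffle without the resampling step) is available
#' for sensitivity analysis; both are calibrated under independence.
#' Resampling the two variables with a *shared* index (duplicating whole
#' pairs) is deliberately not offered: duplicated pairs agree in both rank
#' vectors, which inflates the null spread of rho and makes the test
#' conservative.
#'
#' @param x,y paired observations, length >= 5.
#' @param n_boot null replicates (10,000 in the canonical analysis).
#' @param seed integer seed.
#' @param mode `"resample"` (shuffle then resample with replacement, the
#'   default) or `"permutation"` (shuffle only).
#' @return a `correlation_result` list: `rho`, `p_two_sided`, `n_pairs`,
#'   `n_boot`, `seed`, `mode`.
#' @export
bootstrap_correlation_p <- function(x, y, n_boot = 10000L, seed = 1L,
                                    mode = c("resample", "permutation")) {
  mode <- match.arg(mode)
  n <- length(x)
  stopifnot(length(y) == n, n >= 5L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, p_two_sided = NA_real_,
                          n_pairs = n, n_boot = n_boot, seed = seed,
                          mode = mode, defined = FALSE),
                     class = "correlation_result"))
  }
  rho_obs <- spearman_rho(x, y)
  set.seed(seed)
  rx <- rank(x)
  hits <- 0L
  for (b in seq_len(n_boot)) {
    if (mode == "resample") {
      xs <- x[sample.int(n, n, replace = TRUE)]
      ys <- y[sample.int(n, n, replace = TRUE)]
      rho_b <- stats::cor(xs, ys, method = "spearman")
    } else {
      rho_b <- stats::cor(rx, rank(y[sample.int(n)]))
    }
    if (is.na(rho_b)) next       # degenerate resample (all-tied draw)
    if (abs(rho_b) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
  }
  structure(list(rho = rho_obs,
                 p_two_sided = (1 + hits) / (n_boot + 1),
                 n_pairs = n, n_boot = n_boot, seed = seed, mode = mode,
                 defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.3f, two-sided p = %.4g (%s null, %d replicates, n = %d)\n",
    x$rho, x$p_two_sided, x$mode, x$n_boot, x$n_pairs))
  invisible(x)
}

#' Session-to-session threshold variability
#'
#' Standard deviation of per-session detection thresholds within each
#' subject x stimulus cell, the cross-subject mean SD per stimulus, and the
#' grand mean SD — the variability summary used to contrast species.
#'
#' @param results data frame of per-session summaries (see [sdt_summary()])
#'   with columns `subject`, `stimulus_band`, `threshold_ms`.
#' @param min_sessions minimum sessions per cell (cells below are dropped).
#' @return list of data frames: `per_cell` (subject, stimulus_band, n, sd),
#'   `per_stimulus` (mean SD across subjects), and `grand_mean_sd`.
#' @export
session_threshold_sd <- function(results, min_sessions = 2L) {
  ok <- is.finite(results$threshold_ms)
  r <- results[ok, , drop = FALSE]
  cells <- split(r, interaction(r$subject, r$stimulus_band, drop = TRUE))
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    if (nrow(cell) < min_sessions) return(NULL)
    data.frame(subject = cell$subject[1],
               stimulus_band = cell$stimulus_band[1],
               n_sessions = nrow(cell),
               sd_threshold_ms = stats::sd(cell$threshold_ms),
               stringsAsFactors = FALSE)
  }))
  rownames(per_cell) <- NULL
  per_stimulus <- stats::aggregate(
    sd_threshold_ms ~ stimulus_band, per_cell, mean)
  names(per_stimulus)[2] <- "mean_sd_threshold_ms"
  list(per_cell = per_cell, per_stimulus = per_stimulus,
       grand_mean_sd = mean(per_cell$sd_threshold_ms))
}

#' Best sessions by detection threshold
#'
#' The k lowest-threshold sessions per subject per stimulus; ties are broken
#' by earlier session index.
#'
#' @param results per-session summary data frame with `subject`,
#'   `stimulus_band`, `session`, `threshold_ms`.
#' @param k sessions to keep per cell.
#' @export
best_k_sessions <- function(results, k = 3L) {
  ok <- is.finite(results$threshold_ms)
  r <- results[ok, , drop = FALSE]
  cells <- split(r, interaction(r$subject, r$stimulus_band, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(cell) {
    ord <- order(cell$threshold_ms, cell$session)
    cell[ord[seq_len(min(k, nrow(cell)))], , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
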