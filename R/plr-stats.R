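# Stimulus-locked epoching and PLR statistics.
#
# Epochs run from 2 s before to 18 s after stimulus onset. The robust-PLR
# criterion compares per-trial mean darkness in the maximal-constriction
# window (1.5-2.5 s) against the 2 s pre-stimulus baseline with a paired
# two-tailed t-test; concordance between open- and closed-eye mean event
# time courses is quantified with Pearson r / R-squared and taken to the
# group level through the Fisher transformation.

#' Epoch a trace around stimulus onsets
#'
#' Cuts time-locked segments on a common axis (default -2 s to +18 s, i.e.
#' `round(20 * frame_rate)` samples). Trials whose window overruns the
#' trace are dropped with a warning.
#'
#' @param trace a [darkness_trace()], or a plain numeric vector (then
#'   `frame_rate_hz` must be given).
#' @param onsets_s stimulus onset times (s).
#' @param window_s c(start, end) of the epoch window relative to onset.
#' @param frame_rate_hz sampling rate; taken from `trace` when it is a
#'   `darkness_trace`.
#' @return An `epoch_matrix`: list(data = trials x samples matrix,
#'   t_s = common time axis, source_roi, frame_rate_hz, onsets_used).
#' @export
epoch_events <- function(trace, onsets_s, window_s = c(-2, 18), frame_rate_hz = NULL) {
  if (inherits(trace, "darkness_trace")) {
    values <- trace$values
    frame_rate_hz <- trace$frame_rate_hz
    roi <- trace$roi_label
  } else {
    values <- as.numeric(trace)
    if (is.null(frame_rate_hz)) stopf("frame_rate_hz required for a plain numeric trace")
    roi <- NA_character_
  }
  n <- length(values)
  ns <- as.integer(round((window_s[2] - window_s[1]) * frame_rate_hz))
  off0 <- as.integer(round(window_s[1] * frame_rate_hz))
  t_s <- (seq_len(ns) - 1 + off0) / frame_rate_hz
  rows <- list(); used <- numeric(0)
  for (on in onsets_s) {
    i0 <- as.integer(round(on * frame_rate_hz)) + 1L + off0
    i1 <- i0 + ns - 1L
    if (i0 < 1 || i1 > n) {
      warnf("epoch at onset %g s overruns the trace; trial dropped", on)
      next
    }
    rows[[length(rows) + 1L]] <- values[i0:i1]
    used <- c(used, on)
  }
  data <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, ns)
  structure(list(data = data, t_s = t_s, source_roi = roi,
                 frame_rate_hz = frame_rate_hz, onsets_used = used),
            class = "epoch_matrix")
}

#' Mean event response with its standard error
#'
#' @param epochs an `epoch_matrix` with >= 1 trial.
#' @return list(t_s, mean, sem); SEM is sd/sqrt(n) across trials (0 for a
#'   single trial).
#' @export
average_response <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  n <- nrow(epochs$data)
  if (n < 1) stopf("no trials to average")
  m <- colMeans(epochs$data)
  sem <- if (n == 1) rep(0, ncol(epochs$data)) else apply(epochs$data, 2, sd) / sqrt(n)
  list(t_s = epochs$t_s, mean = m, sem = sem, n_trials = n)
}

#' Robust-PLR test
#'
#' Per trial, the mean darkness in the maximal-constriction window
#' (1.5-2.5 s after onset) is paired with the mean over the 2 s
#' pre-stimulus baseline ([-2, 0) s) and compared across trials with a
#' two-tailed paired t-test. The response is "robust" when p < 0.05 and
#' the constriction mean is below the baseline mean.
#'
#' @param epochs an `epoch_matrix` (darkness) with >= 3 trials.
#' @param constriction_window_s,baseline_window_s analysis windows (s),
#'   closed-open intervals.
#' @param alpha significance cutoff.
#' @return list(t_stat, p_value, is_robust, constriction_mean,
#'   baseline_mean, df).
#' @export
robust_plr_test <- function(epochs, constriction_window_s = c(1.5, 2.5),
                            baseline_window_s = c(-2, 0), alpha = 0.05) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (nrow(epochs$data) < 3) stopf("robust-PLR test needs >= 3 trials")
  t_s <- epochs$t_s
  ic <- t_s >= constriction_window_s[1] & t_s < constriction_window_s[2]
  ib <- t_s >= baseline_window_s[1] & t_s < baseline_window_s[2]
  con <- rowMeans(epochs$data[, ic, drop = FALSE])
  bas <- rowMeans(epochs$data[, ib, drop = FALSE])
  diffs <- con - bas
  if (sd(diffs) == 0) {
    return(list(t_stat = NA_real_, p_value = 1, is_robust = FALSE,
                constriction_mean = mean(con), baseline_mean = mean(bas),
                df = length(diffs) - 1L))
  }
  tt <- t.test(con, bas, paired = TRUE, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       is_robust = tt$p.value < alpha && mean(con) < mean(bas),
       constriction_mean = mean(con), baseline_mean = mean(bas),
       df = unname(tt$parameter))
}

#' Concordance between two mean event traces
#'
#' @param a,b equal-length numeric traces (length >= 3, nonzero variance).
#' @return list(r = Pearson coefficient, r2 = r^2, fisher_z = atanh(r)).
#' @export
trace_correlation <- function(a, b) {
  if (length(a) != length(b)) stopf("traces must have equal length")
  if (length(a) < 3) stopf("traces must have length >= 3")
  if (sd(a) == 0 || sd(b) == 0) stopf("zero-variance trace; correlation undefined")
  r <- stats::cor(a, b)
  list(r = r, r2 = r^2, fisher_z = atanh(r))
}

#' Group-level test of per-participant correlations
#'
#' Applies the variance-stabilizing Fisher transformation atanh(r) and
#' tests the transformed values against zero with a two-sided one-sample
#' t-test.
#'
#' @param r_values per-participant Pearson coefficients (n >= 3, |r| < 1).
#' @return list(t_stat, p_value, df, ci = 95% CI on the mean transformed
#'   value, mean_z, mean_r = tanh(mean_z)).
#' @export
fisher_group_test <- function(r_values) {
  if (length(r_values) < 3) stopf("group test needs n >= 3 correlations")
  if (any(abs(r_values) >= 1)) stopf("|r| = 1 gives an infinite Fisher z")
  z <- atanh(r_values)
  if (sd(z) == 0 && mean(z) == 0) {
    return(list(t_stat = 0, p_value = 1, df = length(z) - 1L,
                ci = c(0, 0), mean_z = 0, mean_r = 0))
  }
  tt <- t.test(z, mu = 0, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), ci = unname(tt$conf.int),
       mean_z = mean(z), mean_r = tanh(mean(z)))
}

#' Mean absolute error
#'
#' @param a,b equal-length numeric vectors.
#' @return mean of |a - b|.
#' @export
mean_absolute_error <- function(a, b) {
  if (length(a) != length(b)) stopf("mean_absolute_error: length mismatch (%d vs %d)",
                                    length(a), length(b))
  mean(abs(a - b))
}
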