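# Heart-rate variability from photoplethysmography: smoothing, beat
# detection, normal-to-normal interval filtering, and RMSSD.

#' PPG trace container
#'
#' @param samples Numeric amplitude vector (arbitrary units), finite.
#' @param fs Sampling rate in Hz (default 200).
#' @return Object of class `ppg_trace`.
#' @export
ppg_trace <- function(samples, fs = 200) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("PPG samples must be finite")
  if (fs <= 0) stop("fs must be positive")
  structure(list(samples = samples, fs = fs), class = "ppg_trace")
}

#' Moving-average smoothing of a PPG trace
#'
#' Centered moving average whose window length equals the sampling rate
#' (one second of data), edge-padded by replication so the output length
#' equals the input length.
#'
#' @param ppg A [ppg_trace()].
#' @param window Window length in samples (default `fs`).
#' @return A smoothed [ppg_trace()].
#' @export
smooth_ppg <- function(ppg, window = NULL) {
  stopifnot(inherits(ppg, "ppg_trace"))
  x <- ppg$samples
  n <- length(x)
  if (is.null(window)) window <- round(ppg$fs)
  if (n <= window)
    stop(sprintf("signal length %d not longer than window %d", n, window))
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  padded <- c(rep(x[1], left), x, rep(x[n], right))
  cs <- cumsum(padded)
  sm <- (cs[(window):(n + window - 1L)] -
           c(0, cs[seq_len(n - 1L)])) / window
  ppg_trace(sm, fs = ppg$fs)
}

# rolling upper-quantile threshold on a coarse grid, linearly interpolated
rolling_quantile <- function(x, fs, prob = 0.9, window_s = 5) {
  n <- length(x)
  step <- max(1L, round(window_s * fs))
  centers <- seq(1L, n, by = step)
  q <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - step); hi <- min(n, c0 + step)
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Detect heartbeats in a smoothed PPG trace
#'
#' Local-maximum peak picking with an adaptive amplitude threshold and a
#' minimum peak separation given by the maximum plausible heart rate.
#' The threshold is computed on the baseline-removed trace (rolling
#' median subtracted): a peak must rise above half the rolling 90th
#' percentile of the local pulse amplitude, which makes the detector
#' robust to baseline drift and DC offset. Intervals implied outside the
#' heart-rate bounds are not removed here; the downstream NN filter
#' handles them.
#'
#' @param ppg A smoothed [ppg_trace()].
#' @param hr_bounds Minimum and maximum heart rate in bpm
#'   (default `c(60, 180)`).
#' @return Numeric vector of beat times in seconds.
#' @export
detect_beats <- function(ppg, hr_bounds = c(60, 180)) {
  stopifnot(inherits(ppg, "ppg_trace"))
  x <- ppg$samples
  n <- length(x)
  min_sep <- round(60 / hr_bounds[2] * ppg$fs)   # samples at max HR
  baseline <- rolling_quantile(x, ppg$fs, prob = 0.5,
                               window_s = 2 * 60 / hr_bounds[1])
  y <- x - baseline
  # local pulse-amplitude threshold with a global floor: the floor keeps
  # noise wiggles in near-flat stretches out, the local term adapts to
  # amplitude modulation of the pulse train
  thr <- pmax(0.3 * rolling_quantile(y, ppg$fs, prob = 0.9, window_s = 1.5),
              0.05 * stats::quantile(y, 0.9, names = FALSE))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > thr[cand]]
  if (!length(cand))
    stop("no peaks found: trace flat or threshold never exceeded")
  # enforce minimum separation, keeping the taller of conflicting peaks
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < min_sep) {
      if (y[i] > y[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  (keep - 1) / ppg$fs
}

#' Filter normal-to-normal intervals
#'
#' Removes artifact intervals: those outside the heart-rate-bound range
#' (`[60000/hr_max, 60000/hr_min]` ms) and those deviating more than
#' `threshold` (relative) from the median of a surrounding context window
#' of neighboring intervals.
#'
#' @param intervals Numeric vector of raw inter-beat intervals in ms.
#' @param threshold Relative deviation limit (default 0.2).
#' @param context Context window size in intervals (default 5).
#' @param hr_bounds Heart-rate bounds in bpm (default `c(60, 180)`).
#' @return An `nn_series`: list with `intervals` (ms), `n`, `n_rejected`.
#' @export
filter_nn <- function(intervals, threshold = 0.2, context = 5L,
                      hr_bounds = c(60, 180)) {
  intervals <- as.numeric(intervals)
  n0 <- length(intervals)
  if (n0 < 1) stop("no intervals supplied")
  lo <- 60000 / hr_bounds[2]; hi <- 60000 / hr_bounds[1]
  half <- max(1L, as.integer(context) %/% 2L)
  ok <- logical(n0)
  for (i in seq_len(n0)) {
    w <- intervals[max(1, i - half):min(n0, i + half)]
    md <- stats::median(w)
    ok[i] <- intervals[i] >= lo && intervals[i] <= hi &&
      abs(intervals[i] - md) <= threshold * md
  }
  if (!any(ok)) stop("all intervals rejected by the NN filter")
  structure(list(intervals = intervals[ok], n = sum(ok),
                 n_rejected = n0 - sum(ok), index = which(ok)),
            class = "nn_series")
}

#' Root mean square of successive differences
#'
#' `RMSSD = sqrt( (1/(n-1)) * sum_i (NN_{i+1} - NN_i)^2 )` in ms, the
#' time-domain HRV index of beat-to-beat (parasympathetic) variability.
#'
#' Only genuinely successive interval pairs enter the sum: when the NN
#' filter removed an interval, the pair straddling the gap is skipped
#' (its difference is not a beat-to-beat difference).
#'
#' @param nn An `nn_series` from [filter_nn()], or a numeric vector of
#'   NN intervals in ms.
#' @return An `hrv_result`: list with `rmssd` (ms), `n_beats`,
#'   `n_rejected`.
#' @export
rmssd <- function(nn) {
  if (is.numeric(nn)) nn <- list(intervals = nn, n = length(nn),
                                 n_rejected = 0L)
  iv <- nn$intervals
  if (length(iv) < 2) stop("need at least 2 NN intervals for RMSSD")
  d <- diff(iv)
  if (!is.null(nn$index)) d <- d[diff(nn$index) == 1L]
  if (!length(d)) stop("no successive NN pairs survive filtering")
  val <- sqrt(sum(d^2) / length(d))
  structure(list(rmssd = val, n_beats = length(iv),
                 n_rejected = nn$n_rejected),
            class = "hrv_result")
}

#' Full HRV pipeline: PPG trace to RMSSD
#'
#' Smoothing, beat detection, NN filtering and RMSSD in one call.
#'
#' @param ppg A [ppg_trace()].
#' @param hr_bounds Heart-rate bounds in bpm (default `c(60, 180)`).
#' @param threshold,context NN-filter parameters (see [filter_nn()]).
#' @return An `hrv_result` (see [rmssd()]), with the filtered `nn`
#'   series and `beat_times` attached.
#' @export
hrv_analysis <- function(ppg, hr_bounds = c(60, 180), threshold = 0.2,
                         context = 5L) {
  sm <- smooth_ppg(ppg)
  beats <- detect_beats(sm, hr_bounds = hr_bounds)
  if (length(beats) < 3) stop("too few beats detected for HRV analysis")
  nn <- filter_nn(diff(beats) * 1000, threshold = threshold,
                  context = context, hr_bounds = hr_bounds)
  out <- rmssd(nn)
  out$nn <- nn
  out$beat_times <- beats
  out
}
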