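# Wavelet transform coherence and its reduction to a task-averaged
# functional-connectivity matrix.
#
# Squared coherence R^2 = |S(W_xy / s)|^2 / ( S(|W_x|^2 / s) S(|W_y|^2 / s) )
# with smoothing S in time (Gaussian of standard deviation equal to the
# scale) and across scales (boxcar of fixed octave width). Both smoothing
# constants are declared here and configurable; self-coherence is exactly 1
# by construction whatever their values.

wtc_defaults <- function() {
  list(omega0 = 6, voices = 12, scale_smooth_octaves = 0.6)
}

# Precomputed smoothing plan for one (scale set, length) pair: padded
# length, per-scale Gaussian kernel FFTs and edge-renormalization
# factors. Shared across every field smoothed during one matrix build.
smooth_plan <- function(scales, n, fs) {
  halves <- pmin(n - 1L, pmax(1L, ceiling(4 * scales * fs)))
  np <- stats::nextn(n + 2L * max(halves) + 1L, 2)
  S <- length(scales)
  kf <- matrix(0 + 0i, np, S)
  norm <- matrix(0, S, n)
  ones_f <- stats::fft(c(rep(1, n), numeric(np - n)))
  for (i in seq_len(S)) {
    sd_samp <- scales[i] * fs
    kern <- exp(-((-halves[i]:halves[i]) / sd_samp)^2 / 2)
    kern <- kern / sum(kern)
    kf[, i] <- stats::fft(c(kern, numeric(np - length(kern))))
    nrm <- Re(stats::fft(ones_f * kf[, i], inverse = TRUE) / np)
    norm[i, ] <- nrm[seq_len(n) + halves[i]]
  }
  list(np = np, kf = kf, norm = norm, halves = halves, n = n, S = S)
}

# Gaussian time smoothing per scale row (width proportional to scale),
# FFT convolution with edge renormalization; real or complex fields.
smooth_time_by_scale <- function(field, scales, fs, plan = NULL) {
  n <- ncol(field)
  if (is.null(plan)) plan <- smooth_plan(scales, n, fs)
  X <- matrix(0 + 0i, plan$np, plan$S)
  X[seq_len(n), ] <- t(field)
  conv <- stats::mvfft(stats::mvfft(X) * plan$kf, inverse = TRUE) / plan$np
  out <- matrix(if (is.complex(field)) 0 + 0i else 0, plan$S, n)
  for (i in seq_len(plan$S)) {
    v <- conv[seq_len(n) + plan$halves[i], i] / plan$norm[i, ]
    out[i, ] <- if (is.complex(field)) v else Re(v)
  }
  out
}

# boxcar across the scale dimension, truncated and renormalized at edges
smooth_scale_boxcar <- function(field, voices, octaves) {
  w <- max(1L, round(octaves * voices))
  half <- w %/% 2
  if (half == 0) return(field)
  ns <- nrow(field)
  cs <- rbind(0, field)
  for (i in seq_len(ns)) cs[i + 1L, ] <- cs[i + 1L, ] + cs[i, ]  # col cumsum
  lo <- pmax(1L, seq_len(ns) - half); hi <- pmin(ns, seq_len(ns) + half)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

smooth_field <- function(field, scales, fs, voices, octaves, plan = NULL) {
  smooth_scale_boxcar(smooth_time_by_scale(field, scales, fs, plan),
                      voices, octaves)
}

# smoothed scale-normalized power of one transform (reused across pairs)
wtc_auto_power <- function(ct, octaves, plan = NULL) {
  smooth_field(Mod(ct$coef)^2 / ct$scales, ct$scales, ct$fs, ct$voices,
               octaves, plan)
}

wtc_from_transforms <- function(cx, cy, auto_x, auto_y, octaves,
                                exclude_coi = FALSE, plan = NULL) {
  cross <- cx$coef * Conj(cy$coef) / cx$scales
  sc <- smooth_field(cross, cx$scales, cx$fs, cx$voices, octaves, plan)
  r2 <- Mod(sc)^2 / (auto_x * auto_y)
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  if (exclude_coi) {
    mask <- outer(cx$periods, cx$coi, ">")
    r2[mask] <- NA_real_
  }
  coherence_map(r2, periods = cx$periods, coi = cx$coi, fs = cx$fs)
}

coherence_map <- function(values, periods, coi, fs) {
  if (any(diff(periods) <= 0)) stop("periods must be strictly increasing")
  structure(list(values = values, periods = periods, freqs = 1 / periods,
                 coi = coi, fs = fs),
            class = "coherence_map")
}

#' Wavelet transform coherence of two signals
#'
#' Time- and frequency-resolved squared coherence between two equally
#' sampled series, from smoothed Morlet wavelet cross-spectra. Values lie
#' in `[0, 1]`; the coherence of a signal with itself is 1 everywhere.
#'
#' @param x,y Numeric vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param omega0,voices Morlet parameters (see [cwt_morlet()]).
#' @param scale_smooth_octaves Width of the boxcar smoothing across scales,
#'   in octaves (default 0.6).
#' @param period_range Optional Fourier-period bounds in seconds.
#' @param exclude_coi If `TRUE`, values inside the cone of influence
#'   (edge-affected region) are set to `NA`; by default they are kept.
#' @return A `coherence_map`: list with `values` (scales x time matrix),
#'   `periods` (s), `freqs` (Hz), `coi` (s), `fs`.
#' @export
wtc <- function(x, y, fs, omega0 = 6, voices = 12,
                scale_smooth_octaves = 0.6, period_range = NULL,
                exclude_coi = FALSE) {
  if (length(x) != length(y))
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  cx <- cwt_morlet(x, fs, omega0 = omega0, voices = voices,
                   period_range = period_range)
  cy <- cwt_morlet(y, fs, omega0 = omega0, voices = voices,
                   period_range = period_range)
  ax <- wtc_auto_power(cx, scale_smooth_octaves)
  ay <- wtc_auto_power(cy, scale_smooth_octaves)
  wtc_from_transforms(cx, cy, ax, ay, scale_smooth_octaves,
                      exclude_coi = exclude_coi)
}

#' Band- and task-averaged coherence
#'
#' Reduces a coherence map to one scalar: the mean coherence over scales
#' whose frequency falls inside `band` and time samples inside task
#' blocks, averaged with equal weight per task block.
#'
#' @param map A `coherence_map` from [wtc()].
#' @param paradigm A [task_paradigm()].
#' @param band Frequency band in Hz (default `c(0.01, 0.2)`).
#' @return Scalar in `[0, 1]`.
#' @export
band_task_average <- function(map, paradigm, band = c(0.01, 0.2)) {
  stopifnot(inherits(map, "coherence_map"), inherits(paradigm, "task_paradigm"))
  sel <- which(map$freqs >= band[1] & map$freqs <= band[2])
  if (!length(sel))
    stop(sprintf("band [%g, %g] Hz selects no scales (available %g-%g Hz)",
                 band[1], band[2], min(map$freqs), max(map$freqs)))
  n <- ncol(map$values)
  tb <- paradigm$blocks[paradigm$blocks$label == "task", , drop = FALSE]
  block_means <- numeric(0)
  for (b in seq_len(nrow(tb))) {
    i0 <- floor(tb$onset[b] * map$fs) + 1
    i1 <- min(n, floor((tb$onset[b] + tb$duration[b]) * map$fs))
    if (i0 > n || i1 < i0) next
    block_means <- c(block_means,
                     mean(map$values[sel, i0:i1, drop = FALSE], na.rm = TRUE))
  }
  if (!length(block_means))
    stop("no task samples fall inside the recording")
  mean(block_means)
}

#' Build a functional-connectivity matrix from hemoglobin signals
#'
#' For every unordered channel pair, computes wavelet transform coherence
#' and averages it over the frequency band of interest and the task
#' blocks, yielding a symmetric weighted undirected network. Per-channel
#' wavelet transforms and smoothed auto-powers are computed once and
#' shared across pairs.
#'
#' @param hemo A [hemo_signals()] object (typically the functional
#'   component).
#' @param paradigm A [task_paradigm()].
#' @param band Frequency band in Hz (default `c(0.01, 0.2)`).
#' @param signal `"hbo"` (default) or `"hbr"`: which chromophore carries
#'   the connectivity estimate.
#' @param roi_map,hemisphere_excluded Passed to [fc_matrix()].
#' @param omega0,voices,scale_smooth_octaves Coherence parameters.
#' @param exclude_coi Drop edge-affected values from the average.
#' @return An [fc_matrix()].
#' @export
build_fc_matrix <- function(hemo, paradigm, band = c(0.01, 0.2),
                            signal = c("hbo", "hbr"), roi_map = NULL,
                            hemisphere_excluded = NULL, omega0 = 6,
                            voices = 12, scale_smooth_octaves = 0.6,
                            exclude_coi = FALSE) {
  stopifnot(inherits(hemo, "hemo_signals"))
  signal <- match.arg(signal)
  sig <- if (signal == "hbo") hemo$hbo else hemo$hbr
  nc <- ncol(sig)
  if (nc < 2) stop("need at least 2 channels")
  # scales limited to the band plus margin for the scale smoother
  margin <- 2^((round(scale_smooth_octaves * voices) %/% 2 + 1) / voices)
  prange <- c((1 / band[2]) / margin, (1 / band[1]) * margin)
  cts <- vector("list", nc)
  autos <- vector("list", nc)
  plan <- NULL
  for (ch in seq_len(nc)) {
    cts[[ch]] <- cwt_morlet(sig[, ch], hemo$fs, omega0 = omega0,
                            voices = voices, period_range = prange)
    if (is.null(plan))
      plan <- smooth_plan(cts[[ch]]$scales, cts[[ch]]$n, hemo$fs)
    autos[[ch]] <- wtc_auto_power(cts[[ch]], scale_smooth_octaves, plan)
  }
  w <- matrix(NA_real_, nc, nc)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      map <- tryCatch(
        wtc_from_transforms(cts[[i]], cts[[j]], autos[[i]], autos[[j]],
                            scale_smooth_octaves, exclude_coi = exclude_coi,
                            plan = plan),
        error = function(e)
          stop(sprintf("coherence failed for pair (%s, %s): %s",
                       hemo$channel_ids[i], hemo$channel_ids[j],
                       conditionMessage(e))))
      w[i, j] <- w[j, i] <- band_task_average(map, paradigm, band)
    }
  }
  fc_matrix(w, channel_ids = hemo$channel_ids, roi_map = roi_map,
            hemisphere_excluded = hemisphere_excluded)
}
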