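# Preprocessing chain: intensity -> optical density -> wavelet motion
# correction -> modified Beer-Lambert -> low-pass -> hemodynamic modality
# separation. Order is fixed; preprocess() chains all stages.

#' Convert raw intensity to optical-density change
#'
#' `OD = -ln(I / mean(I over reference))` per channel and wavelength. By
#' construction the OD has (log-)zero mean over the reference window.
#'
#' @param raw A [raw_intensity()] object.
#' @param reference Integer vector of sample indices defining the reference
#'   window (default: the whole recording).
#' @return An [optical_density()] object.
#' @export
intensity_to_od <- function(raw, reference = NULL) {
  stopifnot(inherits(raw, "raw_intensity"))
  d <- raw$data
  n <- dim(d)[1]
  if (is.null(reference)) reference <- seq_len(n)
  reference <- as.integer(reference)
  if (length(reference) == 0 || any(reference < 1 | reference > n))
    stop("reference window empty or out of range")
  od <- d
  for (ch in seq_len(dim(d)[2])) {
    for (w in 1:2) {
      m <- mean(d[reference, ch, w])
      od[, ch, w] <- -log(d[, ch, w] / m)
    }
  }
  optical_density(od, fs = raw$fs, wavelengths = raw$wavelengths,
                  channel_ids = raw$channel_ids)
}

#' Wavelet motion-artifact correction
#'
#' Each channel/wavelength series is decomposed with a multi-level
#' [modwt()]; within every detail level, coefficients whose deviation from
#' the level median exceeds `iqr_factor` times the level interquartile
#' range are set to zero (motion artifacts concentrate in outlying
#' coefficients); the signal is then reconstructed. The approximation
#' level is never touched, so slow hemodynamics pass through.
#'
#' @param od An [optical_density()] object (a numeric vector is also
#'   accepted and returned as a vector).
#' @param iqr_factor Threshold multiplier (default 1.5).
#' @param levels Decomposition depth; default `floor(log2(n)) - 4`.
#' @param wavelet `"db5"` (default) or `"db2"`.
#' @return Object of the same type as `od`, same length.
#' @export
wavelet_motion_correct <- function(od, iqr_factor = 1.5, levels = NULL,
                                   wavelet = "db5") {
  if (iqr_factor <= 0) stop("iqr_factor must be positive")
  correct1 <- function(x) {
    w <- modwt(x, levels = levels, wavelet = wavelet)
    for (j in seq_len(w$levels)) {
      cj <- w$W[[j]]
      md <- stats::median(cj)
      iq <- stats::IQR(cj)
      out <- abs(cj - md) > iqr_factor * iq
      cj[out] <- 0
      w$W[[j]] <- cj
    }
    imodwt(w)
  }
  if (is.numeric(od) && is.null(dim(od))) return(correct1(od))
  stopifnot(inherits(od, "optical_density"))
  d <- od$data
  for (ch in seq_len(dim(d)[2])) for (wl in 1:2)
    d[, ch, wl] <- correct1(d[, ch, wl])
  optical_density(d, fs = od$fs, wavelengths = od$wavelengths,
                  channel_ids = od$channel_ids)
}

#' Zero-phase low-pass filter
#'
#' 3rd-order Butterworth applied forward and backward (zero phase, DC gain
#' 1), removing high-frequency noise above `cutoff`.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 1.0); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 3).
#' @return Filtered object of the same shape.
#' @export
lowpass <- function(x, fs, cutoff = 1.0, order = 3) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff must lie in (0, fs/2) = (0, %g)", fs / 2))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  f1 <- function(v) {
    mu <- mean(v)
    signal::filtfilt(bf, v - mu) + mu
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Optical density to hemoglobin concentration change
#'
#' Modified Beer-Lambert law: for each time sample and channel the 2x2
#' system `OD(lambda) = (eps_hbo(lambda)*dHbO + eps_hbr(lambda)*dHbR) *
#' d * DPF(lambda)` is solved for the two chromophores. Output is in
#' micromolar under the configured units (extinction in 1/(mM*mm),
#' distance in mm).
#'
#' @param od An [optical_density()] object.
#' @param cfg A [beer_lambert_config()].
#' @return A [hemo_signals()] object with `component_tag = "total"`.
#' @export
od_to_hemoglobin <- function(od, cfg = beer_lambert_config()) {
  stopifnot(inherits(od, "optical_density"),
            inherits(cfg, "beer_lambert_config"))
  A <- cfg$extinction * cfg$distance * cfg$dpf   # row-wise dpf scaling
  Ainv <- solve(A)
  n <- dim(od$data)[1]; nc <- dim(od$data)[2]
  hbo <- matrix(0, n, nc); hbr <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    odm <- cbind(od$data[, ch, 1], od$data[, ch, 2])   # time x wavelength
    conc <- odm %*% t(Ainv) * 1000                     # mM -> uM
    hbo[, ch] <- conc[, 1]
    hbr[, ch] <- conc[, 2]
  }
  hemo_signals(hbo, hbr, fs = od$fs, channel_ids = od$channel_ids,
               component_tag = "total")
}

# forward model used by the synthetic generator and round-trip tests
hemoglobin_to_od <- function(hemo, cfg = beer_lambert_config()) {
  A <- cfg$extinction * cfg$distance * cfg$dpf
  n <- nrow(hemo$hbo); nc <- ncol(hemo$hbo)
  od <- array(0, dim = c(n, nc, 2))
  for (ch in seq_len(nc)) {
    conc <- cbind(hemo$hbo[, ch], hemo$hbr[, ch]) / 1000  # uM -> mM
    od[, ch, ] <- conc %*% t(A)
  }
  optical_density(od, fs = hemo$fs, wavelengths = c(695, 830),
                  channel_ids = hemo$channel_ids)
}

#' Hemodynamic modality separation
#'
#' Splits measured hemoglobin signals into a functional (neuronal)
#' component with anti-phase HbR (`dHbR = k1 * dHbO_f`, `k1 < 0`) and a
#' systemic (circulatory) component with in-phase HbR
#' (`dHbR = k2 * dHbO_s`, `k2 > 0`), using the closed form
#' `dHbO_f = (k2 * dHbO - dHbR) / (k2 - k1)`. The two outputs sum back to
#' the input exactly.
#'
#' @param hemo A [hemo_signals()] object.
#' @param k1 Functional HbR/HbO ratio, negative (default -0.6).
#' @param k2 Systemic HbR/HbO ratio, positive (default 2.0).
#' @return List with elements `functional` and `systemic`, both
#'   [hemo_signals()].
#' @export
hms_separate <- function(hemo, k1 = -0.6, k2 = 2.0) {
  stopifnot(inherits(hemo, "hemo_signals"))
  if (k1 == k2) stop("k1 = k2 makes the separation singular")
  if (!(k1 < 0 && k2 > 0))
    stop("require k1 < 0 < k2 (anti-phase functional, in-phase systemic)")
  hbo_f <- (k2 * hemo$hbo - hemo$hbr) / (k2 - k1)
  hbr_f <- k1 * hbo_f
  # systemic = literal complement, so functional + systemic reproduces the
  # input bit for bit in both chromophores
  list(
    functional = hemo_signals(hbo_f, hbr_f, fs = hemo$fs,
                              channel_ids = hemo$channel_ids,
                              component_tag = "functional"),
    systemic   = hemo_signals(hemo$hbo - hbo_f, hemo$hbr - hbr_f,
                              fs = hemo$fs,
                              channel_ids = hemo$channel_ids,
                              component_tag = "systemic"))
}

#' Full preprocessing chain
#'
#' Intensity -> OD -> wavelet motion correction -> Beer-Lambert ->
#' zero-phase 1 Hz low-pass -> hemodynamic modality separation, returning
#' the functional component (plus intermediates).
#'
#' @param raw A [raw_intensity()] object.
#' @param cfg A [beer_lambert_config()].
#' @param cutoff Low-pass cut-off in Hz (default 1.0).
#' @param iqr_factor Motion-correction threshold (default 1.5).
#' @param k1,k2 Modality-separation constants (defaults -0.6, 2.0).
#' @param motion_correct Set `FALSE` to skip the wavelet step.
#' @return List with `functional`, `systemic`, `total` ([hemo_signals()])
#'   and `od` (the corrected [optical_density()]).
#' @export
preprocess <- function(raw, cfg = beer_lambert_config(), cutoff = 1.0,
                       iqr_factor = 1.5, k1 = -0.6, k2 = 2.0,
                       motion_correct = TRUE) {
  od <- intensity_to_od(raw)
  if (motion_correct) od <- wavelet_motion_correct(od, iqr_factor = iqr_factor)
  hemo <- od_to_hemoglobin(od, cfg)
  hemo$hbo <- lowpass(hemo$hbo, fs = hemo$fs, cutoff = cutoff)
  hemo$hbr <- lowpass(hemo$hbr, fs = hemo$fs, cutoff = cutoff)
  parts <- hms_separate(hemo, k1 = k1, k2 = k2)
  list(functional = parts$functional, systemic = parts$systemic,
       total = hemo, od = od)
}
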