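# Discrete and continuous wavelet machinery.
#
# MODWT (maximal-overlap discrete wavelet transform) backs the motion
# correction: it is defined for any signal length, is exactly invertible,
# and its per-level coefficient series align with the input in time.
# The continuous Morlet transform backs wavelet transform coherence.

# Daubechies scaling-filter taps (natural order, sum = sqrt(2)).
daubechies_filter <- function(name = c("db5", "db2")) {
  name <- match.arg(name)
  g <- switch(name,
    db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
            0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
            0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
            0.0033357252854737712),
    db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
            -0.12940952255126037))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror
  list(g = g, h = h, L = L)
}

circ_shift <- function(x, k) {
  # positive k delays: y[t] = x[t - k] (circular)
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[seq_len(n - k)])
}

#' Maximal-overlap discrete wavelet transform
#'
#' Circular MODWT of a univariate series using a Daubechies filter.
#' Returns per-level wavelet (detail) coefficient series, all of the
#' input's length, plus the final scaling (approximation) series.
#' [imodwt()] inverts it exactly.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth; default `floor(log2(n)) - 4`
#'   (at least 1).
#' @param wavelet `"db5"` (default) or `"db2"`.
#' @return List with `W` (list of detail vectors, level 1 = finest),
#'   `V` (coarsest scaling vector), `levels`, `wavelet`, `n`.
#' @export
modwt <- function(x, levels = NULL, wavelet = "db5") {
  n <- length(x)
  if (is.null(levels)) levels <- max(1L, floor(log2(n)) - 4L)
  if (n < 2^levels)
    stop(sprintf("signal length %d too short for %d levels (need >= %d)",
                 n, levels, 2^levels))
  f <- daubechies_filter(wavelet)
  gt <- f$g / sqrt(2); ht <- f$h / sqrt(2)
  V <- x
  W <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    Wj <- numeric(n); Vj <- numeric(n)
    for (l in seq_len(f$L)) {
      s <- circ_shift(V, (l - 1) * step)
      Wj <- Wj + ht[l] * s
      Vj <- Vj + gt[l] * s
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V, levels = levels, wavelet = wavelet, n = n)
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' @param w A decomposition from [modwt()] (coefficients may be modified).
#' @return Numeric vector of length `w$n`.
#' @export
imodwt <- function(w) {
  f <- daubechies_filter(w$wavelet)
  gt <- f$g / sqrt(2); ht <- f$h / sqrt(2)
  V <- w$V
  for (j in rev(seq_len(w$levels))) {
    step <- 2^(j - 1)
    Vprev <- numeric(w$n)
    for (l in seq_len(f$L)) {
      Vprev <- Vprev + ht[l] * circ_shift(w$W[[j]], -(l - 1) * step) +
                       gt[l] * circ_shift(V,        -(l - 1) * step)
    }
    V <- Vprev
  }
  V
}

# ---------------------------------------------------------------------------
# Continuous Morlet transform

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous Morlet wavelet transform
#'
#' Analytic Morlet transform over dyadic scales, FFT-based, with the
#' conventional normalization making the modulus comparable across scales.
#' Scales span Fourier periods from `2/fs` up to `n/(2*fs)` seconds unless
#' a `period_range` restricts them.
#'
#' @param x Numeric vector (length >= 4).
#' @param fs Sampling rate in Hz.
#' @param omega0 Morlet center frequency (default 6, the usual trade-off
#'   between time and frequency localization).
#' @param voices Voices per octave (default 12).
#' @param period_range Optional length-2 numeric, Fourier-period bounds in
#'   seconds; intersected with the admissible range.
#' @return List with `coef` (complex matrix scales x time), `scales`,
#'   `periods` (s), `freqs` (Hz), `coi` (cone-of-influence boundary as a
#'   maximum unaffected period per time sample, s), `fs`, `omega0`,
#'   `voices`.
#' @export
cwt_morlet <- function(x, fs, omega0 = 6, voices = 12, period_range = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short for a wavelet transform (need >= 4)")
  if (fs <= 0) stop("fs must be positive")
  dt <- 1 / fs
  ff <- morlet_fourier_factor(omega0)
  pmin_ <- 2 * dt
  pmax_ <- n * dt / 2
  if (!is.null(period_range)) {
    pmin_ <- max(pmin_, period_range[1])
    pmax_ <- min(pmax_, period_range[2])
    if (pmin_ >= pmax_) stop("period_range excludes all admissible scales")
  }
  s0 <- pmin_ / ff
  n_sc <- floor(log2(pmax_ / pmin_) * voices) + 1L
  scales <- s0 * 2^((seq_len(n_sc) - 1) / voices)
  periods <- scales * ff

  np <- stats::nextn(2L * n, 2)          # zero-pad to curb wraparound
  xhat <- stats::fft(c(x - mean(x), numeric(np - n)))
  k <- c(seq(0, np / 2), seq(-np / 2 + 1, -1, length.out = np / 2 - 1))
  omega <- 2 * pi * k / (np * dt)
  pos <- omega > 0
  PSI <- matrix(0, np, n_sc)
  for (i in seq_len(n_sc))
    PSI[pos, i] <- pi^(-0.25) * sqrt(2 * pi * scales[i] / dt) *
      exp(-(scales[i] * omega[pos] - omega0)^2 / 2)
  W <- stats::mvfft(xhat * PSI, inverse = TRUE) / np
  coef <- t(W[seq_len(n), , drop = FALSE])
  edge_dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- ff * edge_dist / sqrt(2)        # e-folding time of Morlet = sqrt(2)*s
  list(coef = coef, scales = scales, periods = periods, freqs = 1 / periods,
       coi = coi, fs = fs, omega0 = omega0, voices = voices, n = n)
}
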