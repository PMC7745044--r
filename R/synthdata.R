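# Seed-deterministic synthetic-data generators. Every generator returns
# its ground truth alongside the data so each pipeline stage can be
# verified without any real recording.
#
# The fNIRS generative model is the minimal structure wavelet coherence
# assumes: channels within a coupling block share a band-limited
# (0.01-0.2 Hz) latent oscillation whose amplitude is raised during task
# blocks, plus independent band-limited noise; deoxy-hemoglobin follows
# the modality-separation mixing (functional anti-phase at k1, systemic
# in-phase at k2); intensities come from the forward Beer-Lambert model.

#' Simulation specification
#'
#' Bundles every tunable of the synthetic generators with the defaults of
#' the emulated study: a 10 Hz, 32-channel recording under a block design
#' of 20 s rest followed by five 60 s task blocks (30 s rests between),
#' coherence band 0.01-0.2 Hz, and two groups of 19 subjects.
#'
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @param n_channels Number of fNIRS channels (default 32).
#' @param fs fNIRS sampling rate in Hz (default 10).
#' @param paradigm A [task_paradigm()].
#' @param coupling_blocks Integer vector of length `n_channels` assigning
#'   each channel to a coupling block (default: two halves).
#' @param coupling Latent-share mixing weight in `[0, 1)`: fraction of
#'   in-band variance shared within a block (default 0.5).
#' @param task_gain Amplitude gain of the shared latent during task
#'   blocks (default 2).
#' @param band Coupling band in Hz (default `c(0.01, 0.2)`).
#' @param noise_sd White wide-band sensor-noise SD relative to the
#'   functional signal SD (default 0.3).
#' @param amp_hbo Functional HbO amplitude in micromolar (default 0.5).
#' @param sys_amp Systemic HbO amplitude in micromolar (default 0.3).
#' @param k1,k2 Modality-separation constants (defaults -0.6, 2).
#' @param mean_hr Mean heart rate in bpm (default 80).
#' @param target_rmssd Target RMSSD in ms (default 50).
#' @param n_per_group Subjects per group (default `c(student = 19,
#'   nurse = 19)`).
#' @param planted_effects Optional list with numeric matrices `coupling`
#'   and/or `rmssd` (rows = groups, columns = states) of additive shifts
#'   applied to `coupling` / `target_rmssd` per group and state.
#' @return Validated list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1, n_channels = 32, fs = 10,
                     paradigm = task_paradigm(),
                     coupling_blocks = NULL, coupling = 0.5, task_gain = 2,
                     band = c(0.01, 0.2), noise_sd = 0.3, amp_hbo = 0.5,
                     sys_amp = 0.3, k1 = -0.6, k2 = 2, mean_hr = 80,
                     target_rmssd = 50,
                     n_per_group = c(student = 19, nurse = 19),
                     planted_effects = NULL) {
  if (is.null(coupling_blocks))
    coupling_blocks <- rep(1:2, each = ceiling(n_channels / 2))[1:n_channels]
  if (length(coupling_blocks) != n_channels)
    stop("coupling_blocks must have one entry per channel")
  if (coupling < 0 || coupling >= 1) stop("coupling must lie in [0, 1)")
  if (any(n_per_group < 2)) stop("group sizes must be >= 2")
  if (mean_hr <= 60 || mean_hr >= 180)
    stop("mean_hr must lie strictly inside (60, 180) bpm")
  if (target_rmssd < 0) stop("target_rmssd must be >= 0")
  structure(list(seed = as.integer(seed), n_channels = n_channels, fs = fs,
                 paradigm = paradigm, coupling_blocks = coupling_blocks,
                 coupling = coupling, task_gain = task_gain, band = band,
                 noise_sd = noise_sd, amp_hbo = amp_hbo, sys_amp = sys_amp,
                 k1 = k1, k2 = k2, mean_hr = mean_hr,
                 target_rmssd = target_rmssd, n_per_group = n_per_group,
                 planted_effects = planted_effects),
            class = "sim_spec")
}

paradigm_duration <- function(paradigm) {
  b <- paradigm$blocks
  max(b$onset + b$duration)
}

task_envelope <- function(paradigm, n, fs, gain) {
  env <- rep(1, n)
  tb <- paradigm$blocks[paradigm$blocks$label == "task", , drop = FALSE]
  for (b in seq_len(nrow(tb))) {
    i0 <- floor(tb$onset[b] * fs) + 1
    i1 <- min(n, floor((tb$onset[b] + tb$duration[b]) * fs))
    if (i0 <= n && i1 >= i0) env[i0:i1] <- gain
  }
  env
}

# unit-variance band-limited Gaussian noise via Fourier masking
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency
  mask <- f >= band[1] & f <= band[2]
  mask[1] <- FALSE
  if (!any(mask)) {
    # short series: fall back to the frequency bin nearest the band center
    target <- mean(band)
    k <- which.min(abs(f[-1] - target)) + 1L
    mask[f == f[k]] <- TRUE
  }
  xf[!mask] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for this length: empty spectrum")
  y / s
}

#' Generate a synthetic fNIRS recording
#'
#' Raw dual-wavelength intensities under the coupling model described in
#' [sim_spec()], with the ground-truth functional and systemic
#' hemoglobin components attached.
#'
#' @param spec A [sim_spec()].
#' @param use_seed Set `FALSE` when a caller manages the RNG state.
#' @return List: `raw` ([raw_intensity()]), `truth` (list `functional`,
#'   `systemic`, `total` of [hemo_signals()]), `spec`.
#' @export
gen_fnirs <- function(spec = sim_spec(), use_seed = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  if (use_seed) set.seed(spec$seed)
  n <- floor(paradigm_duration(spec$paradigm) * spec$fs)
  nc <- spec$n_channels
  env <- task_envelope(spec$paradigm, n, spec$fs, spec$task_gain)
  blocks <- unique(spec$coupling_blocks)
  latents <- lapply(blocks, function(b) band_noise(n, spec$fs, spec$band) * env)
  names(latents) <- as.character(blocks)
  hbo_f <- matrix(0, n, nc)
  cw <- sqrt(spec$coupling); nw <- sqrt(1 - spec$coupling)
  for (ch in seq_len(nc)) {
    own <- band_noise(n, spec$fs, spec$band) * env
    hbo_f[, ch] <- spec$amp_hbo *
      (cw * latents[[as.character(spec$coupling_blocks[ch])]] + nw * own)
  }
  tt <- seq_len(n) / spec$fs
  sys_wave <- sin(2 * pi * 0.1 * tt + stats::runif(1, 0, 2 * pi)) +
    0.5 * band_noise(n, spec$fs, c(0.05, 0.15))
  hbo_s <- matrix(spec$sys_amp * sys_wave / stats::sd(sys_wave), n, nc)
  hbo <- hbo_f + hbo_s
  hbr <- spec$k1 * hbo_f + spec$k2 * hbo_s
  ids <- paste0("ch", seq_len(nc))
  total <- hemo_signals(hbo, hbr, fs = spec$fs, channel_ids = ids)
  od <- hemoglobin_to_od(total)
  inten <- exp(-od$data)                      # baseline intensity 1
  inten <- inten * (1 + spec$noise_sd * 1e-4 *
                      array(stats::rnorm(length(inten)), dim = dim(inten)))
  list(raw = raw_intensity(inten, fs = spec$fs, channel_ids = ids),
       truth = list(
         functional = hemo_signals(hbo_f, spec$k1 * hbo_f, fs = spec$fs,
                                   channel_ids = ids,
                                   component_tag = "functional"),
         systemic = hemo_signals(hbo_s, spec$k2 * hbo_s, fs = spec$fs,
                                 channel_ids = ids,
                                 component_tag = "systemic"),
         total = total),
       spec = spec)
}

#' Generate a synthetic PPG trace
#'
#' Normal-to-normal intervals are drawn with the specified mean heart
#' rate and rescaled so the ground-truth RMSSD equals the target exactly;
#' each beat is rendered as an asymmetric pulse (fast rise, slow decay)
#' at the PPG sampling rate.
#'
#' @param spec A [sim_spec()] (uses `mean_hr`, `target_rmssd`, `seed`).
#' @param duration_s Trace duration in seconds (default 120).
#' @param fs PPG sampling rate in Hz (default 200).
#' @param use_seed Set `FALSE` when a caller manages the RNG state.
#' @return List: `ppg` ([ppg_trace()]), `truth` (list with `nn` intervals
#'   in ms, `beat_times` in s, `rmssd`).
#' @export
gen_ppg <- function(spec = sim_spec(), duration_s = 120, fs = 200,
                    use_seed = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  if (use_seed) set.seed(spec$seed)
  mean_nn <- 60000 / spec$mean_hr                       # ms
  lo <- 60000 / 180; hi <- 60000 / 60
  margin <- min(mean_nn - lo, hi - mean_nn)
  if (spec$target_rmssd > margin)
    stop(sprintf("target RMSSD %g ms infeasible at %g bpm within HR bounds",
                 spec$target_rmssd, spec$mean_hr))
  n_nn <- max(8L, floor((duration_s * 1000 - 3000) / mean_nn))
  repeat {
    # interval variability concentrated in the low-frequency band
    # (0.085-0.115 Hz, Mayer-wave dominated), the slow component that the
    # one-second smoothing of the analysis chain passes undistorted.
    # Intervals are kept below 930 ms: a pulse train with period equal to
    # the smoothing window is constant after smoothing, so beats near
    # that period are undetectable by construction of the analysis chain.
    fs_beat <- 1000 / mean_nn                          # beats per second
    dev <- band_noise(n_nn, fs_beat, c(0.085, 0.115))
    hi_clip <- min(margin, 930 - mean_nn)
    lo_clip <- min(margin, mean_nn - 600)
    if (hi_clip <= 0 || lo_clip <= 0)
      stop(sprintf("mean heart rate %g bpm outside the generator's workable range",
                   spec$mean_hr))
    if (spec$target_rmssd > 0) {
      for (it in 1:8) {
        r0 <- sqrt(sum(diff(dev)^2) / (n_nn - 1L))
        dev <- dev * spec$target_rmssd / r0
        dev <- pmax(pmin(dev, hi_clip), -lo_clip)
      }
      r1 <- sqrt(sum(diff(dev)^2) / (n_nn - 1L))
      if (abs(r1 - spec$target_rmssd) > 0.02 * spec$target_rmssd)
        stop(sprintf(
          "target RMSSD %g ms infeasible at %g bpm within HR bounds",
          spec$target_rmssd, spec$mean_hr))
      dev <- dev * spec$target_rmssd / r1              # exact final rescale
    } else dev <- dev * 0
    nn <- mean_nn + dev                                # per-interval, ms
    beat_times <- 0.5 + cumsum(c(0, nn)) / 1000        # first beat at 0.5 s
    if (max(beat_times) <= duration_s - 0.5) break
    n_nn <- n_nn - 2L                                  # rare: drift too far
    if (n_nn < 8L) stop("duration too short for the requested heart rate")
  }
  n <- floor(duration_s * fs)
  tt <- seq_len(n) / fs
  sig <- numeric(n)
  for (b in beat_times) {
    d <- tt - b
    w <- which(d > -0.45 & d < 0.75)
    sgma <- ifelse(d[w] < 0, 0.13, 0.22)               # asymmetric pulse
    sig[w] <- sig[w] + exp(-d[w]^2 / (2 * sgma^2))
  }
  sig <- sig + 0.01 * stats::rnorm(n)
  truth_rmssd <- sqrt(sum(diff(nn)^2) / (length(nn) - 1))
  list(ppg = ppg_trace(sig, fs = fs),
       truth = list(nn = nn, beat_times = beat_times, rmssd = truth_rmssd))
}

#' Generate a toy network with known semi-metric structure
#'
#' Builds a complete coherence matrix whose non-planted edges all lie in
#' a narrow strong-weight band (every direct edge is its own shortest
#' path, hence metric) and then weakens the planted edges enough that a
#' two-hop route beats them. The exact semi-metric label set - and hence
#' the SMP, `n_planted / C(n, 2)` - is known by construction.
#'
#' @param n Number of nodes (>= 3).
#' @param planted_semimetric 2-column matrix (or list of length-2
#'   vectors) of node-index pairs to plant as semi-metric edges.
#' @param seed Integer seed.
#' @return List: `fc` ([fc_matrix()]), `planted` (canonical 2-column
#'   matrix), `smp_true`.
#' @export
gen_toy_network <- function(n, planted_semimetric = NULL, seed = 1) {
  if (n < 3) stop("need at least 3 nodes")
  set.seed(seed)
  if (is.list(planted_semimetric))
    planted_semimetric <- do.call(rbind, planted_semimetric)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w), arr.ind = TRUE)
  w[up] <- stats::runif(nrow(up), 0.5, 0.6)
  planted <- matrix(integer(0), 0, 2)
  if (!is.null(planted_semimetric) && nrow(planted_semimetric)) {
    p <- cbind(pmin(planted_semimetric[, 1], planted_semimetric[, 2]),
               pmax(planted_semimetric[, 1], planted_semimetric[, 2]))
    if (any(p[, 1] == p[, 2]) || any(p < 1) || any(p > n))
      stop("planted edges must be off-diagonal node pairs within 1..n")
    if (anyDuplicated(paste(p[, 1], p[, 2])))
      stop("duplicate planted edges")
    is_planted <- matrix(FALSE, n, n)
    is_planted[p] <- TRUE; is_planted[p[, 2:1, drop = FALSE]] <- TRUE
    for (r in seq_len(nrow(p))) {
      i <- p[r, 1]; j <- p[r, 2]
      k_ok <- setdiff(seq_len(n), c(i, j))
      k_ok <- k_ok[!is_planted[i, k_ok] & !is_planted[k_ok, j]]
      if (!length(k_ok))
        stop(sprintf(
          "infeasible planting: edge (%d, %d) has no two-hop metric detour",
          i, j))
      w[i, j] <- stats::runif(1, 0.1, 0.25)
    }
    planted <- p
  }
  w <- w + t(w)
  list(fc = fc_matrix(w),
       planted = planted,
       smp_true = nrow(planted) / (n * (n - 1) / 2))
}

#' Generate a full synthetic study
#'
#' Simulates every subject of a two-group (between) by two-state (within)
#' design, runs the requested parts of the pipeline per subject and
#' state, and returns the long study table plus the planted truth.
#' Planted effects shift the coupling strength (raising functional
#' connectivity) and/or the RMSSD target per group and state.
#'
#' @param spec A [sim_spec()]; `n_per_group` and `planted_effects` drive
#'   the design.
#' @param indices Character subset of `c("SMP", "E_global", "E_local",
#'   "CC", "lambda", "E_nodal", "RMSSD")` to compute (fewer = faster).
#' @param level `"hemo"` (default) simulates hemoglobin directly;
#'   `"intensity"` simulates raw intensities and runs the full
#'   preprocessing chain.
#' @param ppg_duration_s Duration of each PPG trace (default 60).
#' @param subject_sd Between-subject SD of the RMSSD target (default 5 ms).
#' @param voices Voices per octave for the coherence stage (default 12).
#' @return List: `table` (long data frame: subject, group, state, region,
#'   index, value), `truth` (the per-cell coupling and RMSSD targets).
#' @export
gen_study <- function(spec = sim_spec(),
                      indices = c("SMP", "RMSSD"),
                      level = c("hemo", "intensity"),
                      ppg_duration_s = 60, subject_sd = 5, voices = 12) {
  stopifnot(inherits(spec, "sim_spec"))
  level <- match.arg(level)
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)
  if (is.null(groups)) groups <- paste0("group", seq_along(spec$n_per_group))
  states <- c("affective", "neutral")
  pe <- spec$planted_effects
  shift <- function(mat, g, s) {
    if (is.null(mat)) return(0)
    mat[match(g, groups), match(s, states)]
  }
  need_fc <- any(indices %in% c("SMP", "E_global", "E_local", "CC",
                                "lambda", "E_nodal"))
  need_regional <- any(indices %in% c("E_nodal")) ||
    ("SMP" %in% indices && spec$n_channels >= 4)
  roi_map <- NULL
  if (need_regional) {
    ids <- paste0("ch", seq_len(spec$n_channels))
    half <- spec$n_channels %/% 2
    roi_map <- stats::setNames(
      rep(c("left_PFC", "right_PFC"), c(half, spec$n_channels - half)), ids)
  }
  rows <- list()
  truth <- list()
  sub_id <- 0L
  for (g in groups) {
    for (k in seq_len(spec$n_per_group[[g]])) {
      sub_id <- sub_id + 1L
      sid <- sprintf("s%02d", sub_id)
      subj_rmssd_off <- stats::rnorm(1, 0, subject_sd)
      for (s in states) {
        cpl <- min(0.95, max(0, spec$coupling + shift(pe$coupling, g, s)))
        rms <- max(5, spec$target_rmssd + shift(pe$rmssd, g, s) +
                     subj_rmssd_off)
        truth[[paste(sid, s, sep = ".")]] <-
          list(coupling = cpl, rmssd = rms)
        if (need_fc) {
          sspec <- spec
          sspec$coupling <- cpl
          if (level == "hemo") {
            fn <- gen_fnirs_hemo(sspec)
          } else {
            sim <- gen_fnirs(sspec, use_seed = FALSE)
            fn <- preprocess(sim$raw, k1 = spec$k1, k2 = spec$k2)$functional
          }
          fc <- build_fc_matrix(fn, spec$paradigm, band = spec$band,
                                roi_map = roi_map,
                                hemisphere_excluded = character(),
                                voices = voices)
          if ("SMP" %in% indices) {
            sm <- semimetric_analysis(fc)
            rows[[length(rows) + 1L]] <- data.frame(
              subject = sid, group = g, state = s, region = "global",
              index = "SMP", value = sm$smp_global)
            if (!is.null(sm$smp_regional))
              for (r in names(sm$smp_regional))
                rows[[length(rows) + 1L]] <- data.frame(
                  subject = sid, group = g, state = s, region = r,
                  index = "SMP", value = sm$smp_regional[[r]])
          }
          if (any(indices %in% c("E_global", "E_local", "CC", "lambda",
                                 "E_nodal"))) {
            gm <- graph_metrics(fc)
            gmap <- c(E_global = "e_global", E_local = "e_local",
                      CC = "cc", lambda = "lambda")
            for (ix in intersect(indices, names(gmap)))
              rows[[length(rows) + 1L]] <- data.frame(
                subject = sid, group = g, state = s, region = "global",
                index = ix, value = gm$global[[gmap[[ix]]]])
            if ("E_nodal" %in% indices && !is.null(gm$regional))
              for (r in names(gm$regional))
                rows[[length(rows) + 1L]] <- data.frame(
                  subject = sid, group = g, state = s, region = r,
                  index = "E_nodal", value = gm$regional[[r]]$e_nodal)
          }
        }
        if ("RMSSD" %in% indices) {
          sspec <- spec
          sspec$target_rmssd <- rms
          pg <- gen_ppg(sspec, duration_s = ppg_duration_s, use_seed = FALSE)
          hr <- hrv_analysis(pg$ppg)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, group = g, state = s, region = "global",
            index = "RMSSD", value = hr$rmssd)
        }
      }
    }
  }
  list(table = do.call(rbind, rows), truth = truth)
}

# hemoglobin-level shortcut used by gen_study(level = "hemo"): the
# functional component only, skipping the optical forward/inverse model
gen_fnirs_hemo <- function(spec) {
  n <- floor(paradigm_duration(spec$paradigm) * spec$fs)
  nc <- spec$n_channels
  env <- task_envelope(spec$paradigm, n, spec$fs, spec$task_gain)
  blocks <- unique(spec$coupling_blocks)
  latents <- lapply(blocks, function(b) band_noise(n, spec$fs, spec$band) * env)
  names(latents) <- as.character(blocks)
  hbo_f <- matrix(0, n, nc)
  cw <- sqrt(spec$coupling); nw <- sqrt(1 - spec$coupling)
  for (ch in seq_len(nc)) {
    own <- band_noise(n, spec$fs, spec$band) * env
    hbo_f[, ch] <- spec$amp_hbo *
      (cw * latents[[as.character(spec$coupling_blocks[ch])]] + nw * own)
  }
  hemo_signals(hbo_f, spec$k1 * hbo_f, fs = spec$fs,
               channel_ids = paste0("ch", seq_len(nc)),
               component_tag = "functional")
}
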