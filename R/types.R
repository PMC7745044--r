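# S3 containers for the pipeline's signal and network objects.
# All constructors validate their invariants and fail with informative errors.

#' Raw dual-wavelength fNIRS intensity
#'
#' Container for raw light-intensity recordings from a continuous-wave fNIRS
#' system: one time series per channel and wavelength, in arbitrary device
#' units. Intensities must be strictly positive (they enter a logarithm when
#' converted to optical density).
#'
#' @param data Numeric array `time x channel x wavelength` (third dimension
#'   must have length 2), all values strictly positive, no `NA`.
#' @param fs Sampling rate in Hz (default 10, a typical continuous-wave
#'   system rate).
#' @param wavelengths Length-2 numeric vector of wavelengths in nm
#'   (default `c(695, 830)`).
#' @param channel_ids Character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `raw_intensity`.
#' @export
raw_intensity <- function(data, fs = 10, wavelengths = c(695, 830),
                          channel_ids = NULL) {
  data <- as_3d_array(data)
  if (dim(data)[3] != 2L)
    stop("raw_intensity requires exactly 2 wavelengths, got ", dim(data)[3])
  if (anyNA(data) || !all(is.finite(data)))
    stop("raw_intensity data must be finite with no NA")
  bad <- which(apply(data <= 0, 2, any))
  if (length(bad))
    stop("non-positive intensity in channel(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (length(wavelengths) != 2L)
    stop("wavelengths must have length 2")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channel_ids) != dim(data)[2])
    stop("channel_ids length does not match channel dimension")
  structure(list(data = data, fs = fs, wavelengths = as.numeric(wavelengths),
                 channel_ids = as.character(channel_ids)),
            class = "raw_intensity")
}

#' Optical-density change
#'
#' Dimensionless optical-density change per channel and wavelength,
#' relative to a reference window (see [intensity_to_od()]).
#'
#' @param data Numeric array `time x channel x wavelength`, finite.
#' @param fs Sampling rate in Hz.
#' @param wavelengths Length-2 numeric vector (nm).
#' @param channel_ids Character channel labels.
#' @return An object of class `optical_density`.
#' @export
optical_density <- function(data, fs, wavelengths, channel_ids = NULL) {
  data <- as_3d_array(data)
  if (!all(is.finite(data))) stop("optical_density data must be finite")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, fs = fs, wavelengths = as.numeric(wavelengths),
                 channel_ids = as.character(channel_ids)),
            class = "optical_density")
}

#' Hemoglobin concentration-change signals
#'
#' Paired time-by-channel matrices of oxygenated (`hbo`) and deoxygenated
#' (`hbr`) hemoglobin concentration change, in micromolar under the
#' declared differential pathlength factor and source-detector distance.
#' `component_tag` records which hemodynamic component the object carries:
#' `"total"` (as measured), `"functional"` (neuronal, anti-phase HbR) or
#' `"systemic"` (circulatory, in-phase HbR).
#'
#' @param hbo,hbr Numeric matrices `time x channel` of equal dimension.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Character channel labels.
#' @param component_tag One of `"total"`, `"functional"`, `"systemic"`.
#' @return An object of class `hemo_signals`.
#' @export
hemo_signals <- function(hbo, hbr, fs, channel_ids = NULL,
                         component_tag = "total") {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr)))
    stop("hbo and hbr must share dimensions")
  if (!all(is.finite(hbo)) || !all(is.finite(hbr)))
    stop("hemo_signals must be finite")
  component_tag <- match.arg(component_tag,
                             c("total", "functional", "systemic"))
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(hbo)))
  if (length(channel_ids) != ncol(hbo))
    stop("channel_ids length does not match channel count")
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 channel_ids = as.character(channel_ids),
                 component_tag = component_tag),
            class = "hemo_signals")
}

#' Modified Beer-Lambert configuration
#'
#' Constants of the modified Beer-Lambert law: a 2x2 extinction-coefficient
#' table (rows = wavelengths, columns = chromophores HbO, HbR; units
#' 1/(mM*mm)), per-wavelength differential pathlength factors, and the
#' source-detector separation in mm. With these units and OD dimensionless,
#' recovered concentrations are in mM; the pipeline reports micromolar.
#'
#' The default extinction values are approximate literature values for
#' 695/830 nm and are shipped as editable defaults: they scale the output
#' amplitude but cancel exactly in round trips.
#'
#' @param extinction 2x2 numeric matrix, `extinction[w, c]` for wavelength
#'   `w` and chromophore `c` in `c("hbo","hbr")`. Must be invertible.
#' @param dpf Length-2 positive numeric, differential pathlength factor per
#'   wavelength (default 6.0 for both).
#' @param distance Source-detector separation in mm (default 30).
#' @return An object of class `beer_lambert_config`.
#' @export
beer_lambert_config <- function(extinction = default_extinction(),
                                dpf = c(6.0, 6.0), distance = 30) {
  extinction <- as.matrix(extinction)
  if (!identical(dim(extinction), c(2L, 2L)))
    stop("extinction must be a 2x2 matrix")
  if (abs(det(extinction)) < 1e-12 || !all(is.finite(extinction)))
    stop("extinction matrix is singular or non-finite")
  if (length(dpf) == 1L) dpf <- rep(dpf, 2L)
  if (any(dpf <= 0)) stop("dpf must be positive")
  if (distance <= 0) stop("distance must be positive")
  structure(list(extinction = extinction, dpf = as.numeric(dpf),
                 distance = distance),
            class = "beer_lambert_config")
}

#' Default extinction-coefficient table
#'
#' Approximate molar extinction coefficients of HbO and HbR at 695 and
#' 830 nm, converted to 1/(mM*mm). Editable; see [beer_lambert_config()].
#'
#' @return 2x2 numeric matrix with dimnames `(wavelength, chromophore)`.
#' @export
default_extinction <- function() {
  m <- matrix(c(0.0298, 0.1846,
                0.0974, 0.0693), nrow = 2, byrow = TRUE)
  dimnames(m) <- list(c("695", "830"), c("hbo", "hbr"))
  m
}

#' Block-design task paradigm
#'
#' Timing of rest and task blocks. The default mirrors a block design with
#' 20 s of initial rest followed by five 60 s task periods alternating with
#' rest periods.
#'
#' @param blocks Data frame with columns `onset` (s), `duration` (s) and
#'   `label` (`"rest"` or `"task"`); blocks must be time-ordered and
#'   non-overlapping and all task blocks must share one duration.
#' @return An object of class `task_paradigm`.
#' @export
task_paradigm <- function(blocks = default_paradigm_blocks()) {
  blocks <- as.data.frame(blocks)
  need <- c("onset", "duration", "label")
  if (!all(need %in% names(blocks)))
    stop("blocks needs columns onset, duration, label")
  if (!all(blocks$label %in% c("rest", "task")))
    stop("block labels must be 'rest' or 'task'")
  o <- order(blocks$onset)
  blocks <- blocks[o, , drop = FALSE]
  ends <- blocks$onset + blocks$duration
  if (nrow(blocks) > 1 && any(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9))
    stop("blocks overlap")
  td <- blocks$duration[blocks$label == "task"]
  if (length(td) && diff(range(td)) > 1e-9)
    stop("task blocks must share a single duration")
  rownames(blocks) <- NULL
  structure(list(blocks = blocks), class = "task_paradigm")
}

#' Default block schedule: 20 s rest, then 5 x (60 s task + 30 s rest)
#'
#' @param n_task_blocks Number of task blocks (default 5).
#' @param task_duration Task-block duration in s (default 60).
#' @param initial_rest Initial rest duration in s (default 20).
#' @param inter_rest Rest duration between task blocks in s (default 30).
#' @return Data frame of blocks suitable for [task_paradigm()].
#' @export
default_paradigm_blocks <- function(n_task_blocks = 5, task_duration = 60,
                                    initial_rest = 20, inter_rest = 30) {
  onset <- initial_rest
  rows <- list(data.frame(onset = 0, duration = initial_rest, label = "rest"))
  for (b in seq_len(n_task_blocks)) {
    rows[[length(rows) + 1L]] <-
      data.frame(onset = onset, duration = task_duration, label = "task")
    onset <- onset + task_duration
    if (b < n_task_blocks) {
      rows[[length(rows) + 1L]] <-
        data.frame(onset = onset, duration = inter_rest, label = "rest")
      onset <- onset + inter_rest
    }
  }
  do.call(rbind, rows)
}

#' Functional-connectivity matrix
#'
#' Symmetric channel-by-channel matrix of coherence weights in `[0, 1]`;
#' the diagonal is stored as `NA` and ignored throughout. Carries the
#' channel-to-hemisphere map used for regional analyses and the channels
#' dropped from hemispheric contrasts.
#'
#' @param weights Symmetric numeric matrix with off-diagonal values in
#'   `[0, 1]`.
#' @param channel_ids Character channel labels (defaults to rownames or
#'   `"ch1"`, ...).
#' @param roi_map Named character vector mapping channel id to ROI label
#'   (e.g. `"left_PFC"`/`"right_PFC"`), or `NULL`.
#' @param hemisphere_excluded Channel ids dropped when the two hemispheres
#'   are compared (default `c("ch16", "ch37")` when present).
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(weights, channel_ids = NULL, roi_map = NULL,
                      hemisphere_excluded = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(weights)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(n))
  }
  diag(weights) <- NA_real_
  off <- weights[row(weights) != col(weights)]
  if (anyNA(off) || !all(is.finite(off)))
    stop("off-diagonal weights must be finite")
  asym <- abs(weights - t(weights))
  asym[is.na(asym)] <- 0
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("weights not symmetric at pair (%s, %s): |w_ij - w_ji| = %g",
                 channel_ids[ij[1]], channel_ids[ij[2]], max(asym)))
  }
  if (any(off < -1e-12) || any(off > 1 + 1e-12)) {
    ij <- which(weights < -1e-12 | weights > 1 + 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("weight outside [0,1] at pair (%s, %s)",
                 channel_ids[ij[1]], channel_ids[ij[2]]))
  }
  weights[weights < 0] <- 0
  weights[weights > 1] <- 1
  weights <- (weights + t(weights)) / 2
  diag(weights) <- NA_real_
  dimnames(weights) <- list(channel_ids, channel_ids)
  if (!is.null(roi_map)) {
    miss <- setdiff(channel_ids, names(roi_map))
    # channels without an ROI are allowed; they drop out of regional analyses
    roi_map <- roi_map[intersect(names(roi_map), channel_ids)]
    if (length(miss) == length(channel_ids))
      stop("roi_map covers none of the channels")
  }
  if (is.null(hemisphere_excluded))
    hemisphere_excluded <- intersect(c("ch16", "ch37"), channel_ids)
  structure(list(weights = weights, channel_ids = channel_ids,
                 roi_map = roi_map,
                 hemisphere_excluded = hemisphere_excluded,
                 n = n),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("<fc_matrix> %d channels, %d unique edges, weight range [%.3f, %.3f]\n",
              x$n, x$n * (x$n - 1) / 2, min(off), max(off)))
  invisible(x)
}

#' @export
print.hemo_signals <- function(x, ...) {
  cat(sprintf("<hemo_signals:%s> %d samples x %d channels @ %g Hz\n",
              x$component_tag, nrow(x$hbo), ncol(x$hbo), x$fs))
  invisible(x)
}

# coerce matrix (time x channel, single wavelength) or 3d array
as_3d_array <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a time x channel x wavelength array")
  storage.mode(data) <- "double"
  data
}
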