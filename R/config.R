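# Pipeline configuration: one validated bag of tunables with the study's
# default parameters, loadable from a YAML file.

pipeline_defaults <- function() {
  list(
    band = c(0.01, 0.2),        # coherence band of interest, Hz
    cutoff = 1.0,               # low-pass cut-off, Hz
    iqr_factor = 1.5,           # motion-correction threshold
    signal_choice = "hbo",      # chromophore carrying the FC estimate
    k1 = -0.6, k2 = 2.0,        # modality-separation constants
    dpf = c(6.0, 6.0),
    distance = 30,              # source-detector separation, mm
    semimetric_tol = 1e-9,
    eps = 1e-6,                 # weight clamp floor
    omega0 = 6, voices = 12,
    scale_smooth_octaves = 0.6,
    exclude_coi = FALSE,
    roi_map_path = NULL,
    exclusions = c("ch16", "ch37"),
    hr_bounds = c(60, 180),     # bpm
    nn_threshold = 0.2,
    fdr_q = 0.05,
    seed = 1)
}

#' Pipeline configuration
#'
#' Validated list of every tunable the pipeline stages accept, with the
#' study defaults (band 0.01-0.2 Hz, 1 Hz low-pass, 1.5 x IQR motion
#' threshold, k1 = -0.6 / k2 = 2, heart-rate bounds 60-180 bpm, FDR
#' q = 0.05, channels 16/37 excluded from hemispheric contrasts).
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown config key(s): ",
           paste(if (length(unknown)) unknown else "<unnamed>",
                 collapse = ", "))
    cfg[names(over)] <- over
  }
  with(cfg, {
    if (!(band[1] > 0 && band[2] > band[1])) stop("invalid band")
    if (cutoff <= 0) stop("cutoff must be positive")
    if (iqr_factor <= 0) stop("iqr_factor must be positive")
    if (!signal_choice %in% c("hbo", "hbr")) stop("signal_choice: hbo or hbr")
    if (!(k1 < 0 && k2 > 0)) stop("require k1 < 0 < k2")
    if (!(hr_bounds[1] > 0 && hr_bounds[2] > hr_bounds[1]))
      stop("invalid hr_bounds")
    if (fdr_q <= 0 || fdr_q > 1) stop("fdr_q must lie in (0, 1]")
  })
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file of `key: value` overrides.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
format.pipeline_config <- function(x, ...) {
  paste0(names(x), " = ",
         vapply(x, function(v)
           if (is.null(v)) "NULL" else paste(format(v), collapse = ", "),
           character(1)),
         collapse = "; ")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", format(x), "\n")
  invisible(x)
}
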