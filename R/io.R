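# Delimited-text readers and writers for every pipeline artifact.
# Round-trip property: everything a writer emits, its reader restores to
# numerical equality (1e-12).

#' Write / read a connectivity matrix as TSV
#'
#' Tab-separated with a channel header row and a leading channel column;
#' the diagonal is written as `NA`.
#'
#' @param fc An [fc_matrix()].
#' @param path File path.
#' @return `write_fc_tsv`: the path, invisibly. `read_fc_tsv`: an
#'   [fc_matrix()].
#' @export
write_fc_tsv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  df <- data.frame(channel = fc$channel_ids,
                   fc$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param roi_map,hemisphere_excluded Passed to [fc_matrix()].
#' @rdname write_fc_tsv
#' @export
read_fc_tsv <- function(path, roi_map = NULL, hemisphere_excluded = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "channel")
    stop(path, ": first column must be 'channel'")
  ids <- as.character(df$channel)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), ids))
    stop(path, ": header channels do not match the channel column")
  mode(m) <- "double"
  rownames(m) <- ids
  diag(m) <- NA_real_
  asym <- abs(m - t(m)); asym[is.na(asym)] <- 0
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: asymmetric entry at pair (%s, %s)",
                 path, ids[ij[1]], ids[ij[2]]))
  }
  fc_matrix(m, channel_ids = ids, roi_map = roi_map,
            hemisphere_excluded = hemisphere_excluded)
}

#' Write / read a task-event file
#'
#' Three tab-separated columns: `onset` (s), `duration` (s), `label`.
#'
#' @param paradigm A [task_paradigm()].
#' @param path File path.
#' @return `write_events`: path, invisibly; `read_events`: a
#'   [task_paradigm()].
#' @export
write_events <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  utils::write.table(paradigm$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  need <- c("onset", "duration", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!df$label %in% c("rest", "task"))
  if (length(bad))
    stop(sprintf("%s: row %d: label must be 'rest' or 'task'",
                 path, bad[1]))
  task_paradigm(df)
}

#' Write / read a time-by-channel signal matrix as TSV
#'
#' First column `time` in seconds, remaining columns one per channel.
#'
#' @param mat Numeric matrix `time x channel`.
#' @param fs Sampling rate in Hz.
#' @param path File path.
#' @param channel_ids Channel labels (default `colnames(mat)`).
#' @return `write_signal_tsv`: path, invisibly; `read_signal_tsv`: list
#'   with `data` (matrix), `fs`, `channel_ids`.
#' @export
write_signal_tsv <- function(mat, fs, path, channel_ids = NULL) {
  mat <- as.matrix(mat)
  if (is.null(channel_ids))
    channel_ids <- colnames(mat) %||% paste0("ch", seq_len(ncol(mat)))
  df <- data.frame(time = (seq_len(nrow(mat)) - 1) / fs, mat)
  names(df) <- c("time", channel_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "time")
    stop(path, ": first column must be 'time' (seconds)")
  if (nrow(df) < 2) stop(path, ": need at least 2 samples")
  dt <- diff(df$time)
  if (any(dt <= 0))
    stop(sprintf("%s: row %d: time not strictly increasing",
                 path, which(dt <= 0)[1] + 1L))
  fs <- 1 / stats::median(dt)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "double"
  if (anyNA(m)) {
    ij <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: row %d, channel %s: non-numeric or missing value",
                 path, ij[1], colnames(m)[ij[2]]))
  }
  list(data = m, fs = fs, channel_ids = colnames(m))
}

#' Read a PPG trace from 2-column delimited text
#'
#' Columns: time (s), amplitude.
#'
#' @param path File path.
#' @return A [ppg_trace()].
#' @export
read_ppg_txt <- function(path) {
  s <- read_signal_tsv(path)
  if (ncol(s$data) != 1)
    stop(path, ": expected a single amplitude column")
  ppg_trace(s$data[, 1], fs = s$fs)
}

#' Read / write a channel-to-ROI map
#'
#' Two tab-separated columns: `channel`, `roi`.
#'
#' @param path File path.
#' @return `read_roi_map`: named character vector channel -> ROI.
#' @export
read_roi_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  if (!all(c("channel", "roi") %in% names(df)))
    stop(path, ": need columns 'channel' and 'roi'")
  stats::setNames(as.character(df$roi), as.character(df$channel))
}

#' Default prefrontal ROI map
#'
#' The shipped 32-channel prefrontal set of a 52-channel 3 x 11 probe
#' layout, numbered row-wise in rows of 10, 11, 10, 11, 10 channels.
#' The midline channels of the 11-wide rows (16 and 37) carry a nominal
#' hemisphere label but are excluded from hemispheric contrasts
#' ([default_hemisphere_exclusions()]), leaving 15 channels per
#' hemisphere. The layout is a declared convention shipped as an
#' editable table (`inst/extdata/roi_map_52ch.tsv`); replace it to match
#' a different montage.
#'
#' @return Named character vector: channel id -> `"left_PFC"` /
#'   `"right_PFC"`.
#' @export
default_roi_map <- function() {
  path <- system.file("extdata", "roi_map_52ch.tsv", package = "semifc")
  if (nzchar(path)) return(read_roi_map(path))
  # fallback when called from a source checkout
  left <- c(11:16, 22:26, 32:36)
  right <- c(17:21, 27:31, 37:42)
  stats::setNames(rep(c("left_PFC", "right_PFC"),
                      c(length(left), length(right))),
                  paste0("ch", c(left, right)))
}

#' Channels excluded from hemispheric contrasts
#'
#' @return Character vector `c("ch16", "ch37")`, the midline channels.
#' @export
default_hemisphere_exclusions <- function() c("ch16", "ch37")

#' Write / read a long study table as CSV
#'
#' @param table Long study table (see [mixed_anova()]).
#' @param path File path.
#' @return `write_study_csv`: path invisibly; `read_study_csv`: data
#'   frame.
#' @export
write_study_csv <- function(table, path) {
  validate_study_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(df)
  df
}

#' Write a results list as JSON
#'
#' @param x Named list of results.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
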