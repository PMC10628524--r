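#' ROI time-series container
#'
#' A light S3 record holding a parcellated source-space recording: a
#' samples-by-channels numeric matrix plus sampling metadata. This is the
#' raw input of the connectivity pipeline; in the motivating application
#' each channel is one of the 68 cortical regions of the Desikan--Killiany
#' atlas sampled at 500 Hz.
#'
#' @param data Numeric matrix, samples in rows, channels (ROIs) in columns.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique ROI names, one per column.
#'   Defaults to `roi_01 ... roi_NN`.
#' @param subject_id Subject identifier string.
#' @param condition Recording condition, `"EO"` (eyes open) or `"EC"`
#'   (eyes closed).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, fs, labels = NULL, subject_id = "s01",
                   condition = c("EO", "EC")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    stop("roi_ts data contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("roi_%02d", seq_len(ncol(data)))
  }
  if (length(labels) != ncol(data)) {
    stop("labels length (", length(labels), ") != number of channels (",
         ncol(data), ")", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("ROI labels must be unique", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         subject_id = subject_id, condition = condition),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> ", x$subject_id, " [", x$condition, "] ",
      nrow(x$data), " samples x ", ncol(x$data), " channels @ ",
      x$fs, " Hz (", round(nrow(x$data) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Duration of an ROI time series in seconds
#' @param ts A `roi_ts`.
#' @return Length in seconds.
#' @export
ts_duration <- function(ts) nrow(ts$data) / ts$fs

#' Instantaneous-phase container
#'
#' Per-channel analytic-signal phases for one band-limited epoch. Values
#' are wrapped to (-pi, pi].
#'
#' @param phases Samples-by-channels matrix of phases in radians.
#' @param band One-row band tibble (see [band_definition()]).
#' @param epoch_index Epoch number within the recording.
#' @param labels Channel labels.
#' @return An object of class `phase_epoch`.
#' @export
phase_epoch <- function(phases, band, epoch_index = 1L, labels = NULL) {
  phases <- as.matrix(phases)
  if (!all(is.finite(phases))) {
    stop("phase matrix contains non-finite values", call. = FALSE)
  }
  if (any(phases <= -pi - 1e-9) || any(phases > pi + 1e-9)) {
    stop("phases must be wrapped to (-pi, pi]", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("roi_%02d", seq_len(ncol(phases)))
  structure(
    list(phases = phases, band = band, epoch_index = as.integer(epoch_index),
         labels = labels),
    class = "phase_epoch"
  )
}

#' Connectivity-matrix container
#'
#' Symmetric channels-by-channels matrix of PLI weights in \[0, 1\] with a
#' zero diagonal, for one band and one epoch (or an epoch average).
#'
#' @param weights Symmetric numeric matrix, zero diagonal, entries in
#'   \[0, 1\].
#' @param band One-row band tibble.
#' @param subject_id,condition Provenance metadata.
#' @param n_epochs_averaged Number of epochs averaged into `weights`.
#' @param labels Channel labels.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, band, subject_id = "s01",
                                condition = "EO", n_epochs_averaged = 1L,
                                labels = NULL) {
  weights <- as.matrix(weights)
  n <- ncol(weights)
  if (nrow(weights) != n) stop("weights must be square", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(weights < -1e-12) || any(weights > 1 + 1e-12)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("roi_%02d", seq_len(n))
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, band = band, subject_id = subject_id,
         condition = condition,
         n_epochs_averaged = as.integer(n_epochs_averaged),
         labels = labels),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$subject_id, " [", x$condition, "] band=",
      x$band$band, " ", ncol(x$weights), "x", ncol(x$weights),
      " (mean of ", x$n_epochs_averaged, " epoch",
      if (x$n_epochs_averaged != 1) "s", ")\n", sep = "")
  invisible(x)
}
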