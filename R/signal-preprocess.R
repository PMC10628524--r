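#' Resample, notch-filter, and band-limit a recording
#'
#' Mirrors the standard MEG preprocessing chain: down-sampling to a target
#' rate, notch filters at the power-line frequency and harmonics, and a
#' broadband band-pass. Filters are applied forward and backward
#' (zero-phase) so that phase estimates downstream are not biased.
#'
#' @param ts A [roi_ts()].
#' @param target_fs Target sampling rate in Hz; must not exceed `ts$fs`.
#'   Default 500.
#' @param notch_freqs Numeric vector of notch frequencies in Hz (default
#'   60, 120, 180); may be empty. All must be below `target_fs / 2`.
#' @param broadband Length-2 numeric vector, broadband band-pass edges in
#'   Hz (default `c(0.5, 200)`); `NULL` skips the broadband filter.
#' @param notch_bw Half-width of each notch in Hz (default 1).
#' @param order Butterworth order for the broadband filter (default 4).
#' @return A new `roi_ts` at `target_fs`.
#' @export
preprocess <- function(ts, target_fs = 500, notch_freqs = c(60, 120, 180),
                       broadband = c(0.5, 200), notch_bw = 1, order = 4) {
  stopifnot(inherits(ts, "roi_ts"))
  if (target_fs > ts$fs) {
    stop("target_fs (", target_fs, ") exceeds input rate ", ts$fs,
         call. = FALSE)
  }
  nyq <- target_fs / 2
  if (length(notch_freqs) && any(notch_freqs >= nyq)) {
    stop("notch frequencies must be below the target Nyquist ", nyq, " Hz",
         call. = FALSE)
  }
  x <- ts$data
  # resample first so notch frequencies are defined at the working rate
  if (target_fs != ts$fs) {
    p <- ratio_int(target_fs, ts$fs)
    x <- apply(x, 2, function(col) signal::resample(col, p[1], p[2]))
    n_target <- floor(nrow(ts$data) * target_fs / ts$fs)
    x <- x[seq_len(min(nrow(x), n_target)), , drop = FALSE]
  }
  for (f0 in notch_freqs) {
    bf <- signal::butter(2, c(f0 - notch_bw, f0 + notch_bw) / nyq, "stop")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  if (!is.null(broadband)) {
    lo <- max(broadband[1], 1e-3)
    hi <- min(broadband[2], nyq * 0.999)
    bf <- signal::butter(order, c(lo, hi) / nyq, "pass")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  roi_ts(x, fs = target_fs, labels = ts$labels, subject_id = ts$subject_id,
         condition = ts$condition)
}

# reduce target/source rate ratio to small integers for polyphase resampling
ratio_int <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  # work with rates scaled to integers (rates are given in Hz, allow 0.5 Hz)
  a2 <- round(a * 2); b2 <- round(b * 2)
  d <- g(a2, b2)
  c(a2 / d, b2 / d)
}

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' The recording is split into the maximal number of consecutive
#' non-overlapping epochs of `epoch_s` seconds; any trailing remainder is
#' discarded.
#'
#' @param ts A [roi_ts()].
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A list of `roi_ts`, one per epoch.
#' @export
segment_epochs <- function(ts, epoch_s = 5) {
  stopifnot(inherits(ts, "roi_ts"))
  n_per <- floor(epoch_s * ts$fs)
  n <- nrow(ts$data)
  if (n < n_per) {
    stop("recording (", round(n / ts$fs, 3), " s) shorter than epoch_s = ",
         epoch_s, " s", call. = FALSE)
  }
  k <- n %/% n_per
  lapply(seq_len(k), function(i) {
    rows <- ((i - 1L) * n_per + 1L):(i * n_per)
    roi_ts(ts$data[rows, , drop = FALSE], fs = ts$fs, labels = ts$labels,
           subject_id = ts$subject_id, condition = ts$condition)
  })
}

#' Zero-phase band-pass filter an epoch
#'
#' @param epoch A [roi_ts()].
#' @param band One-row band tibble (see [band_definition()]).
#' @param order Butterworth order (default 4; the effective order doubles
#'   under the forward-backward application).
#' @return A band-limited `roi_ts` of the same length.
#' @export
bandpass_epoch <- function(epoch, band, order = 4) {
  stopifnot(inherits(epoch, "roi_ts"))
  validate_band(band, epoch$fs)
  nyq <- epoch$fs / 2
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, "pass")
  x <- apply(epoch$data, 2, function(col) signal::filtfilt(bf, col))
  roi_ts(x, fs = epoch$fs, labels = epoch$labels,
         subject_id = epoch$subject_id, condition = epoch$condition)
}
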