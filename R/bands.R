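#' Canonical MEG frequency bands
#'
#' The five bands used throughout the pipeline: delta (2--4 Hz), theta
#' (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz), and gamma (30--60 Hz).
#' Note the gamma band deliberately extends to 60 Hz, wider than the
#' 30--45 Hz convention of much of the EEG literature, to capture
#' higher-frequency activity implicated in memory function.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz), ordered from
#'   delta to gamma.
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(2, 4, 8, 13, 30),
    f_hi = c(4, 8, 13, 30, 60)
  )
}

#' Construct a single band definition
#'
#' @param name Band name; one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @param f_lo,f_hi Band edges in Hz. Defaults to the canonical edges for
#'   `name`.
#' @return A one-row tibble (`band`, `f_lo`, `f_hi`).
#' @export
band_definition <- function(name, f_lo = NULL, f_hi = NULL) {
  ref <- canonical_bands()
  if (!name %in% ref$band) {
    stop("unknown band name '", name, "'; must be one of: ",
         paste(ref$band, collapse = ", "), call. = FALSE)
  }
  row <- ref[ref$band == name, ]
  if (!is.null(f_lo)) row$f_lo <- f_lo
  if (!is.null(f_hi)) row$f_hi <- f_hi
  if (!(row$f_lo > 0 && row$f_lo < row$f_hi)) {
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  row
}

# validate a band row against a sampling rate (Nyquist)
validate_band <- function(band, fs) {
  stopifnot(is.data.frame(band), nrow(band) == 1)
  if (band$f_hi >= fs / 2) {
    stop("band '", band$band, "' upper edge (", band$f_hi,
         " Hz) must be below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  }
  invisible(band)
}
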