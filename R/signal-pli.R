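#' Instantaneous phase via the analytic signal
#'
#' Computes the per-channel analytic signal by the frequency-domain
#' Hilbert method (zeroing negative frequencies of the FFT) and returns
#' its argument, wrapped to (-pi, pi]. Input should already be
#' band-limited for the phase to be physically interpretable.
#'
#' @param epoch A band-limited [roi_ts()].
#' @param band One-row band tibble recorded into the result (defaults to
#'   an `NA` placeholder when phases are computed outside the band loop).
#' @param epoch_index Epoch number for provenance.
#' @return A [phase_epoch()].
#' @export
instantaneous_phase <- function(epoch, band = NULL, epoch_index = 1L) {
  stopifnot(inherits(epoch, "roi_ts"))
  x <- epoch$data
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- epoch$labels[which(v == 0)]
    stop("constant (zero-variance) channel(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- analytic_signal(x)
  ph <- Arg(z) # in (-pi, pi]
  if (is.null(band)) {
    band <- tibble::tibble(band = NA_character_, f_lo = NA_real_,
                           f_hi = NA_real_)
  }
  phase_epoch(ph, band = band, epoch_index = epoch_index,
              labels = epoch$labels)
}

# analytic signal of each column: x + i * H[x], via the FFT one-sided
# spectrum construction
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Phase lag index for one epoch
#'
#' For every channel pair, the PLI is the absolute mean sign of the
#' wrapped instantaneous phase difference over the epoch:
#' \deqn{PLI = | N^{-1} \sum_k \mathrm{sign}(\Delta\phi(t_k)) |.}
#' It ranges from 0 (no consistent lag, including perfect zero-lag
#' synchrony, which makes the index insensitive to field spread) to 1 (a
#' phase difference whose sign never changes). Ties
#' (\eqn{\Delta\phi = 0}) contribute 0 to the sum.
#'
#' A fraction of samples at each end of the epoch can be excluded from the
#' summation to discard analytic-signal edge distortion; set
#' `edge_trim = 0` to evaluate the bare formula.
#'
#' @param phase A [phase_epoch()] with at least 2 channels.
#' @param edge_trim Fraction of samples dropped at each end (default 0.05).
#' @return A [connectivity_matrix()] with `n_epochs_averaged = 1`.
#' @export
pli_epoch <- function(phase, edge_trim = 0.05) {
  stopifnot(inherits(phase, "phase_epoch"))
  P <- phase$phases
  n_ch <- ncol(P)
  if (n_ch < 2L) stop("need at least 2 channels", call. = FALSE)
  n <- nrow(P)
  drop_k <- floor(edge_trim * n)
  if (n - 2L * drop_k < 1L) {
    stop("edge_trim leaves no samples", call. = FALSE)
  }
  if (drop_k > 0L) P <- P[(drop_k + 1L):(n - drop_k), , drop = FALSE]
  # sign(wrapped(phi_i - phi_j)) == sign(sin(phi_i - phi_j)) for the
  # (-pi, pi] wrap; computed from one sin/cos pass per channel
  S <- sin(P); C <- cos(P)
  W <- matrix(0, n_ch, n_ch)
  for (j in seq_len(n_ch - 1L)) {
    idx <- (j + 1L):n_ch
    cross <- S[, idx, drop = FALSE] * C[, j] - C[, idx, drop = FALSE] * S[, j]
    W[j, idx] <- abs(colMeans(sign(cross)))
  }
  W <- W + t(W)
  connectivity_matrix(W, band = phase$band, n_epochs_averaged = 1L,
                      labels = phase$labels)
}

#' Average connectivity matrices over epochs
#'
#' Element-wise mean of per-epoch PLI matrices belonging to the same
#' subject, condition, and band.
#'
#' @param mats Non-empty list of [connectivity_matrix()] objects with
#'   identical shape and band.
#' @return A [connectivity_matrix()] with `n_epochs_averaged` equal to the
#'   sum over inputs.
#' @export
average_connectivity <- function(mats) {
  if (!length(mats)) stop("no matrices to average", call. = FALSE)
  stopifnot(all(vapply(mats, inherits, logical(1), "connectivity_matrix")))
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(dim(m$weights), dim(ref$weights))) {
      stop("connectivity matrices have mixed shapes", call. = FALSE)
    }
    if (!identical(m$band$band, ref$band$band)) {
      stop("connectivity matrices have mixed bands (",
           ref$band$band, " vs ", m$band$band, ")", call. = FALSE)
    }
  }
  n_eps <- vapply(mats, function(m) m$n_epochs_averaged, integer(1))
  wbar <- Reduce(`+`, lapply(mats, function(m) m$weights)) / length(mats)
  connectivity_matrix(wbar, band = ref$band,
                      subject_id = ref$subject_id, condition = ref$condition,
                      n_epochs_averaged = sum(n_eps), labels = ref$labels)
}
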