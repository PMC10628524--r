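#' Specification for coupled band-limited oscillators
#'
#' Describes a set of narrowband oscillatory channels with a controllable
#' pairwise phase-coupling structure. Channels with `coupling` near 1 and
#' a fixed nonzero `lag` produce a PLI near 1 in the band; channels with
#' `coupling` 0 carry independent phases and produce a PLI near chance
#' level.
#'
#' @param n_channels Number of channels (default 68).
#' @param band Length-2 numeric, band edges in Hz (default alpha, 8--13).
#' @param coupling Symmetric matrix in \[0, 1\] with unit diagonal:
#'   target phase-locking strength per pair. Default: identity (all
#'   channels independent).
#' @param lag Antisymmetric matrix of phase offsets in radians, zero
#'   diagonal. `lag[i, j]` is the target phase lead of channel i over
#'   channel j. Default: all zero.
#' @param noise_sd SD of additive broadband white noise (signal amplitude
#'   is order 1).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz (default 500); must exceed twice the
#'   band's upper edge.
#' @param phase_jitter SD (radians/sample) of the random-walk phase noise
#'   given to every phase process (default 0.01). Injected into the
#'   common phase before the deterministic lag, so lag signs are
#'   preserved.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(n_channels = 68, band = c(8, 13),
                            coupling = NULL, lag = NULL, noise_sd = 0,
                            duration_s = 120, fs = 500,
                            phase_jitter = 0.01, seed = 1L) {
  if (is.null(coupling)) coupling <- diag(n_channels)
  if (is.null(lag)) lag <- matrix(0, n_channels, n_channels)
  coupling <- as.matrix(coupling); lag <- as.matrix(lag)
  if (!all(dim(coupling) == c(n_channels, n_channels))) {
    stop("coupling must be ", n_channels, "x", n_channels, call. = FALSE)
  }
  if (max(abs(coupling - t(coupling))) > 1e-12) {
    stop("coupling must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(coupling) - 1) > 1e-12)) {
    stop("coupling must have unit diagonal", call. = FALSE)
  }
  if (any(coupling < 0) || any(coupling > 1)) {
    stop("coupling entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(lag + t(lag))) > 1e-12) {
    stop("lag must be antisymmetric with zero diagonal", call. = FALSE)
  }
  if (fs <= 2 * band[2]) {
    stop("fs (", fs, ") must exceed twice the band upper edge (",
         band[2], " Hz)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(n_channels = n_channels, band = band, coupling = coupling,
         lag = lag, noise_sd = noise_sd, duration_s = duration_s, fs = fs,
         phase_jitter = phase_jitter, seed = as.integer(seed)),
    class = "oscillator_spec"
  )
}

#' Generate coupled band-limited oscillator signals
#'
#' Channels are grouped into coupling clusters (connected components of
#' the off-diagonal coupling structure). Each cluster shares a common
#' band-limited phase process; channel i of a cluster is
#' `w_i * cos(phi_cluster(t) + o_i) + (1 - w_i) * cos(phi_i(t))` plus
#' white noise, where `w_i` is the channel's coupling strength, `o_i` its
#' deterministic phase offset (taken from the `lag` matrix relative to
#' the cluster's first channel), and `phi_i` an independent oscillator in
#' the same band. Phase noise is shared through the common process, so the
#' sign of the pairwise lag -- what the PLI measures -- is preserved.
#'
#' @param spec An [oscillator_spec()].
#' @param subject_id,condition Metadata for the output.
#' @return A [roi_ts()] of `duration_s * fs` samples by `n_channels`.
#' @export
generate_coupled_oscillators <- function(spec, subject_id = "s01",
                                         condition = "EO") {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- round(spec$duration_s * spec$fs)
  p <- spec$n_channels
  withr_seed(spec$seed, {
    off <- spec$coupling
    diag(off) <- 0
    comp <- connected_components(off > 0)
    # one common phase process per cluster, one private process per channel
    x <- matrix(0, n, p)
    for (cl in unique(comp)) {
      members <- which(comp == cl)
      ref <- members[1L]
      phi_common <- band_phase_process(n, spec$fs, spec$band,
                                       spec$phase_jitter)
      for (i in members) {
        w <- if (length(members) > 1L) max(off[i, members]) else 0
        o_i <- spec$lag[i, ref]
        xi <- w * cos(phi_common + o_i)
        if (w < 1) {
          phi_priv <- band_phase_process(n, spec$fs, spec$band,
                                         spec$phase_jitter)
          xi <- xi + (1 - w) * cos(phi_priv)
        }
        x[, i] <- xi
      }
    }
    if (spec$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    }
  })
  roi_ts(x, fs = spec$fs, subject_id = subject_id, condition = condition)
}

# a band-limited phase process: random centre frequency within the band,
# random initial phase, plus a random-walk phase jitter
band_phase_process <- function(n, fs, band, jitter_sd) {
  f0 <- stats::runif(1, band[1], band[2])
  phi0 <- stats::runif(1, -pi, pi)
  drift <- if (jitter_sd > 0) cumsum(stats::rnorm(n, 0, jitter_sd)) else 0
  phi0 + 2 * pi * f0 * (seq_len(n) - 1) / fs + drift
}

# connected components of a logical adjacency matrix (tiny n; label
# propagation)
connected_components <- function(adj) {
  p <- ncol(adj)
  comp <- seq_len(p)
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[i], comp[nb])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

#' Convenience spec for a pair of coupled channels
#'
#' @param coupling Coupling strength in \[0, 1\].
#' @param lag Phase lead of channel 1 over channel 2, radians.
#' @param ... Passed to [oscillator_spec()].
#' @return An [oscillator_spec()] with 2 channels.
#' @export
pair_spec <- function(coupling = 1, lag = 0.5, ...) {
  cp <- matrix(c(1, coupling, coupling, 1), 2, 2)
  lg <- matrix(c(0, lag, -lag, 0), 2, 2, byrow = TRUE)
  oscillator_spec(n_channels = 2, coupling = cp, lag = lg, ...)
}
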