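test_that("PLI evaluates the sign-mean formula on prescribed phase sequences", {
  # constant positive lag: every sign +1
  expect_equal(pli_epoch(phase_pair(rep(0.3, 8)), edge_trim = 0)$weights[1, 2],
               1)
  # sign pattern (+,+,+,-): |(3 - 1)/4|
  expect_equal(pli_epoch(phase_pair(c(0.3, 0.3, 0.3, -0.3)),
                         edge_trim = 0)$weights[1, 2], 0.5)
  # balanced signs cancel
  expect_equal(pli_epoch(phase_pair(rep(c(0.3, -0.3), 5)),
                         edge_trim = 0)$weights[1, 2], 0)
  # zero phase difference contributes nothing
  expect_equal(pli_epoch(phase_pair(c(0, 0, 0.3)),
                         edge_trim = 0)$weights[1, 2], 1 / 3)
})

test_that("PLI matches the direct-formula oracle on random phases", {
  set.seed(10)
  for (r in 1:20) {
    p <- matrix(stats::runif(3 * 50, -pi, pi), 50, 3)
    W <- pli_epoch(phase_epoch(p, band_definition("alpha")),
                   edge_trim = 0)$weights
    for (i in 1:2) {
      for (j in (i + 1):3) {
        expect_equal(W[i, j], oracle_pli(p[, i], p[, j]), tolerance = 1e-12)
      }
    }
    expect_equal(W, t(W))
    expect_equal(unname(diag(W)), rep(0, 3))
    expect_true(all(W >= 0 & W <= 1))
  }
})

test_that("PLI is invariant to channel-wise amplitude scaling", {
  sp <- pair_spec(coupling = 0.7, lag = 0.8, duration_s = 10,
                  noise_sd = 0.1, seed = 21)
  ts <- generate_coupled_oscillators(sp)
  scaled <- roi_ts(ts$data %*% diag(c(13.7, 0.02)), fs = ts$fs,
                   subject_id = ts$subject_id, condition = ts$condition)
  band <- band_definition("alpha")
  pli_of <- function(x) {
    ep <- segment_epochs(x, 5)[[1]]
    pli_epoch(instantaneous_phase(bandpass_epoch(ep, band), band))$weights[1, 2]
  }
  expect_equal(pli_of(scaled), pli_of(ts), tolerance = 1e-9)
})

test_that("a fully coupled lagged pair reaches PLI 1 and zero lag suppresses it", {
  band <- band_definition("alpha")
  pli_of <- function(ts) {
    ep <- segment_epochs(ts, 5)[[1]]
    pli_epoch(instantaneous_phase(bandpass_epoch(ep, band), band))$weights[1, 2]
  }
  lagged <- generate_coupled_oscillators(
    pair_spec(coupling = 1, lag = 0.5, duration_s = 10, noise_sd = 0,
              seed = 31))
  expect_equal(pli_of(lagged), 1)
  zerolag <- generate_coupled_oscillators(
    pair_spec(coupling = 1, lag = 0, duration_s = 10, noise_sd = 0,
              seed = 31))
  expect_lt(pli_of(zerolag), 0.05)
})

test_that("PLI declines as additive noise grows", {
  band <- band_definition("alpha")
  mean_pli <- function(noise_sd) {
    vals <- vapply(1:4, function(s) {
      ts <- generate_coupled_oscillators(
        pair_spec(coupling = 1, lag = 0.8, duration_s = 15,
                  noise_sd = noise_sd, seed = 40 + s))
      eps <- segment_epochs(ts, 5)
      mean(vapply(eps, function(e) {
        pli_epoch(instantaneous_phase(bandpass_epoch(e, band),
                                      band))$weights[1, 2]
      }, numeric(1)))
    }, numeric(1))
    mean(vals)
  }
  grid <- vapply(c(0, 1, 4), mean_pli, numeric(1))
  expect_true(all(diff(grid) <= 0))
  expect_lt(grid[3], grid[1])
})

test_that("epoch averaging is the element-wise mean with epoch bookkeeping", {
  band <- band_definition("alpha")
  m1 <- connectivity_matrix(matrix(c(0, 0.2, 0.2, 0), 2), band)
  m2 <- connectivity_matrix(matrix(c(0, 0.4, 0.4, 0), 2), band)
  avg <- average_connectivity(list(m1, m2))
  expect_equal(avg$weights[1, 2], 0.3)
  expect_identical(avg$n_epochs_averaged, 2L)
  expect_equal(average_connectivity(list(m1))$weights, m1$weights)
  m3 <- connectivity_matrix(matrix(c(0, 0.4, 0.4, 0), 2),
                            band_definition("beta"))
  expect_error(average_connectivity(list(m1, m3)), "mixed bands")
  m4 <- connectivity_matrix(matrix(0, 3, 3), band)
  expect_error(average_connectivity(list(m1, m4)), "shapes")
})
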