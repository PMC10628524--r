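test_that("preprocess is an identity when no resampling or filtering applies", {
  set.seed(1)
  ts <- roi_ts(matrix(rnorm(1000 * 3), 1000, 3), fs = 500)
  out <- preprocess(ts, target_fs = 500, notch_freqs = numeric(0),
                    broadband = NULL)
  expect_equal(out$data, ts$data, tolerance = 1e-12)
  expect_identical(out$fs, 500)
})

test_that("notch filter removes a pure power-line tone", {
  t <- (0:4999) / 500
  x <- sin(2 * pi * 60 * t)
  ts <- roi_ts(cbind(x), fs = 500)
  out <- preprocess(ts, target_fs = 500, notch_freqs = 60, broadband = NULL)
  # interior samples to avoid filter edge transients
  mid <- 1000:4000
  expect_lt(sqrt(mean(out$data[mid, 1]^2)) / sqrt(mean(x[mid]^2)), 0.01)
})

test_that("down-sampling scales the sample count by the rate ratio", {
  set.seed(2)
  ts <- roi_ts(matrix(rnorm(8000 * 2), 8000, 2), fs = 2000)
  out <- preprocess(ts, target_fs = 500, notch_freqs = numeric(0),
                    broadband = NULL)
  expect_identical(nrow(out$data), 2000L)
  expect_identical(out$fs, 500)
})

test_that("preprocess validates notch frequencies against Nyquist", {
  ts <- roi_ts(matrix(rnorm(1000), 500, 2), fs = 500)
  expect_error(preprocess(ts, target_fs = 500, notch_freqs = 300),
               "Nyquist")
  expect_error(preprocess(ts, target_fs = 1000), "exceeds")
})

test_that("epoch segmentation keeps full epochs and discards the remainder", {
  set.seed(3)
  mk <- function(secs) roi_ts(matrix(rnorm(round(secs * 500) * 2),
                                     ncol = 2), fs = 500)
  eps <- segment_epochs(mk(120), 5)
  expect_length(eps, 24)
  expect_true(all(vapply(eps, function(e) nrow(e$data), integer(1)) == 2500L))
  expect_length(segment_epochs(mk(12.5), 5), 2)
  expect_length(segment_epochs(mk(5), 5), 1)
  expect_error(segment_epochs(mk(3), 5), "shorter")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  t <- (0:2499) / 500
  x <- sin(2 * pi * 10 * t)
  ts <- roi_ts(cbind(x), fs = 500)
  mid <- 500:2000
  inband <- bandpass_epoch(ts, band_definition("alpha"))
  expect_lt(abs(1 - max(abs(inband$data[mid, 1]))), 0.05)
  outband <- bandpass_epoch(ts, band_definition("gamma"))
  expect_lt(sqrt(mean(outband$data[mid, 1]^2)) / sqrt(mean(x[mid]^2)), 0.05)
  # zero in, zero out
  z <- roi_ts(matrix(0, 2500, 1), fs = 500)
  expect_equal(max(abs(bandpass_epoch(z, band_definition("alpha"))$data)), 0)
  expect_error(bandpass_epoch(ts, band_definition("gamma", f_hi = 400)),
               "Nyquist")
})

test_that("instantaneous phase tracks a cosine's analytic phase", {
  fs <- 500
  t <- (0:2499) / fs
  ts <- roi_ts(cbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t - 0.5)),
               fs = fs)
  ph <- instantaneous_phase(ts, band_definition("alpha"))
  mid <- 200:2300
  # unwrapped slope of channel 1 ~ 2*pi*10 per second
  steps <- diff(ph$phases[mid, 1])
  steps <- atan2(sin(steps), cos(steps))
  slope <- mean(steps) * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # constant phase offset recovered at interior samples
  d <- ph$phases[mid, 1] - ph$phases[mid, 2]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - 0.5)), 0.02)
})

test_that("sign-flipping a signal shifts its phase by pi", {
  fs <- 500
  t <- (0:2499) / fs
  x <- cos(2 * pi * 10 * t)
  ph1 <- instantaneous_phase(roi_ts(cbind(x), fs = fs))
  ph2 <- instantaneous_phase(roi_ts(cbind(-x), fs = fs))
  mid <- 200:2300
  d <- ph1$phases[mid, 1] - ph2$phases[mid, 1]
  expect_lt(max(abs(abs(atan2(sin(d), cos(d))) - pi)), 1e-6)
})

test_that("constant channels are rejected by name", {
  ts <- roi_ts(cbind(a = rnorm(100), b = rep(1, 100)), fs = 500,
               labels = c("lh_precentral", "rh_precentral"))
  expect_error(instantaneous_phase(ts), "rh_precentral")
})
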