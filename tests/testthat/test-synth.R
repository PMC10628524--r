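test_that("oscillator generation is a pure function of its spec", {
  sp <- pair_spec(coupling = 0.5, lag = 0.3, duration_s = 5, noise_sd = 0.2,
                  seed = 7)
  a <- generate_coupled_oscillators(sp)
  b <- generate_coupled_oscillators(sp)
  expect_identical(a$data, b$data)
  sp2 <- pair_spec(coupling = 0.5, lag = 0.3, duration_s = 5,
                   noise_sd = 0.2, seed = 8)
  expect_false(identical(generate_coupled_oscillators(sp2)$data, a$data))
})

test_that("oscillator specs reject invalid coupling, lag, and rates", {
  bad_cpl <- matrix(c(1, 0.2, 0.8, 1), 2, 2)
  expect_error(oscillator_spec(n_channels = 2, coupling = bad_cpl),
               "symmetric")
  expect_error(oscillator_spec(n_channels = 2,
                               coupling = matrix(c(0.5, 0, 0, 1), 2)),
               "diagonal")
  expect_error(pair_spec(coupling = 1, lag = 0.5, band = c(30, 60),
                         fs = 100), "fs")
  expect_error(pair_spec(noise_sd = -1), "noise_sd")
})

test_that("uncoupled channels show chance-level PLI across many epochs", {
  band <- band_definition("alpha")
  ts <- generate_coupled_oscillators(
    pair_spec(coupling = 0, lag = 0.5, duration_s = 500, seed = 5))
  vals <- vapply(segment_epochs(ts, 5), function(e) {
    pli_epoch(instantaneous_phase(bandpass_epoch(e, band), band))$weights[1, 2]
  }, numeric(1))
  expect_length(vals, 100)
  expect_lt(mean(vals), 0.15)
})

test_that("the circular mean of the pairwise phase difference matches the lag", {
  band <- band_definition("alpha")
  for (lag in c(-1.2, 0.5, 2.0)) {
    ts <- generate_coupled_oscillators(
      pair_spec(coupling = 1, lag = lag, duration_s = 60, noise_sd = 0,
                seed = 60))
    ph <- instantaneous_phase(bandpass_epoch(segment_epochs(ts, 5)[[1]],
                                             band), band)
    d <- ph$phases[126:2375, 1] - ph$phases[126:2375, 2]
    cm <- Arg(mean(exp(1i * d)))
    expect_lt(abs(atan2(sin(cm - lag), cos(cm - lag))), 0.05)
  }
})

test_that("subject tables reproduce their generative model exactly when noiseless", {
  sp <- subject_table_spec(n_per_group = c(control = 5, AD = 5),
                           beta_disease = 0, beta_condition = 0,
                           beta_age = 0, beta_recall = 0,
                           intercept = 1.3, sigma_subject = 0,
                           sigma_resid = 0, seed = 3)
  tab <- generate_subject_table(sp)
  expect_equal(nrow(tab), 10 * 2 * 5)
  expect_true(all(tab$sw == 1.3))
  expect_true(all(tab$reactivity == 0))
  # determinism
  expect_identical(generate_subject_table(sp), tab)
})

test_that("subject-table covariate marginals match their spec distributions", {
  sp <- subject_table_spec(n_per_group = c(control = 400, AD = 400),
                           seed = 9)
  tab <- generate_subject_table(sp)
  subj <- dplyr::distinct(tab, subject_id, group, age, delayed_recall)
  for (g in c("control", "AD")) {
    d <- subj[subj$group == g, ]
    ad <- sp$age_dist[[g]]; rd <- sp$recall_dist[[g]]
    expect_lt(abs(mean(d$age) - ad[1]), 3 * ad[2] / sqrt(nrow(d)))
    expect_lt(abs(mean(d$delayed_recall) - rd[1]), 3 * rd[2] / sqrt(nrow(d)))
    expect_lt(abs(stats::sd(d$age) - ad[2]), 3 * ad[2] / sqrt(2 * nrow(d)))
  }
  expect_error(subject_table_spec(n_per_group = c(control = 1, AD = 5)),
               "group sizes")
  expect_error(subject_table_spec(sigma_resid = -0.1), "SDs")
})

test_that("benchmark graphs have their textbook metric values", {
  k5 <- generate_benchmark_graph("complete", 5)
  expect_equal(clustering_coefficient(k5), 1)
  expect_equal(characteristic_path_length(k5), 1)
  s4 <- generate_benchmark_graph("star", 5)
  expect_equal(clustering_coefficient(s4), 0)
  p3 <- generate_benchmark_graph("path", 3)
  expect_equal(characteristic_path_length(p3), 4 / 3)
  lat <- generate_benchmark_graph("lattice", 20, k = 4)
  expect_true(all(rowSums(lat$adjacency) == 4))
  expect_error(generate_benchmark_graph("lattice", 20, k = 5), "even k")
  expect_error(generate_benchmark_graph("random", 2), "n must be")
  # random/smallworld draws are connected and reproducible
  er <- generate_benchmark_graph("random", 30, k = 4, seed = 11)
  expect_identical(er$adjacency,
                   generate_benchmark_graph("random", 30, k = 4,
                                            seed = 11)$adjacency)
  D <- plisw:::hop_distances(er$adjacency)
  expect_true(all(is.finite(D)))
})

test_that("a Watts-Strogatz graph scores above 1 on small-worldness", {
  ws <- generate_benchmark_graph("smallworld", 68, k = 13, p = 0.1,
                                 seed = 4)
  C <- clustering_coefficient(ws)
  L <- characteristic_path_length(ws)
  nul <- rewire_null_ensemble(ws, n_null = 100, seed = 5)
  expect_gt(small_worldness(C, L, nul$C_rand, nul$L_rand), 1)
})
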