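test_that("pooled two-sample t from summaries matches closed-form cases", {
  r <- two_sample_t_from_summary(10, 2, 10, 10, 2, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_identical(r$df, 18)
  # hand-computed: diff 1, sp = 2, n = 50 each -> t = 1 / (2 * sqrt(2/50))
  r2 <- two_sample_t_from_summary(11, 2, 50, 10, 2, 50)
  expect_equal(r2$statistic, 1 / (2 * sqrt(2 / 50)), tolerance = 1e-12)
  expect_error(two_sample_t_from_summary(1, 0, 5, 2, 0, 5), "unequal means")
  expect_error(two_sample_t_from_summary(1, 1, 1, 2, 1, 5), ">= 2")
})

test_that("2x2 chi-square matches closed forms", {
  expect_equal(chi_square_2x2(10, 10, 5, 5)$statistic, 0)
  # perfectly diagonal table: chi2 = N
  expect_equal(chi_square_2x2(20, 0, 0, 20)$statistic, 40, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margins")
  expect_error(chi_square_2x2(-1, 2, 3, 4), ">= 0")
})

test_that("mixed-model condition coding flips the sign but not the evidence", {
  sp <- subject_table_spec(n_per_group = c(control = 30, AD = 30), seed = 41)
  tab <- generate_subject_table(sp)
  f1 <- fit_sw_mixed_model(tab, "alpha")
  tab2 <- dplyr::mutate(tab,
    condition = ifelse(condition == "EO", "EC", "EO"))
  f2 <- fit_sw_mixed_model(tab2, "alpha")
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$estimate[t2$term == "condition"],
               -t1$estimate[t1$term == "condition"], tolerance = 1e-6)
  expect_equal(abs(t2$statistic[t2$term == "condition"]),
               abs(t1$statistic[t1$term == "condition"]), tolerance = 1e-6)
  # statistic is estimate / robust_se by construction
  expect_equal(t1$statistic, t1$estimate / t1$robust_se, tolerance = 1e-10)
  expect_true(all(t1$p.value >= 0 & t1$p.value <= 1))
})

test_that("mixed-model estimates ignore subject relabeling and row order", {
  sp <- subject_table_spec(n_per_group = c(control = 20, AD = 20), seed = 43)
  tab <- generate_subject_table(sp)
  f1 <- fit_sw_mixed_model(tab, "beta")
  set.seed(1)
  shuf <- tab[sample(nrow(tab)), ]
  shuf$subject_id <- paste0("x_", shuf$subject_id)
  f2 <- fit_sw_mixed_model(shuf, "beta")
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-6)
  expect_equal(tidy(f2)$robust_se, tidy(f1)$robust_se, tolerance = 1e-6)
})

test_that("with no between-subject variance the mixed fit matches pooled OLS", {
  sp <- subject_table_spec(n_per_group = c(control = 250, AD = 250),
                           beta_recall = 0, sigma_subject = 0,
                           sigma_resid = 0.1, seed = 44)
  tab <- generate_subject_table(sp)
  f <- fit_sw_mixed_model(tab, "gamma")
  d <- dplyr::filter(tab, band == "gamma")
  d$disease <- as.numeric(d$group == "AD")
  d$eo <- as.numeric(d$condition == "EO")
  ols <- stats::lm(sw ~ disease + eo + age, data = d)
  expect_lt(max(abs(tidy(f)$estimate - stats::coef(ols))), 1e-4)
})

test_that("robust and model-based mixed-model SEs agree for homoscedastic data", {
  sp <- subject_table_spec(n_per_group = c(control = 150, AD = 150),
                           seed = 45)
  tab <- generate_subject_table(sp)
  fr <- fit_sw_mixed_model(tab, "alpha", se = "cluster-robust")
  fm <- fit_sw_mixed_model(tab, "alpha", se = "model-based")
  ratio <- tidy(fr)$robust_se / tidy(fm)$robust_se
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("recall regressions are equivariant under covariate rescaling", {
  sp <- subject_table_spec(n_per_group = c(control = 40, AD = 40), seed = 46)
  tab <- generate_subject_table(sp)
  f1 <- fit_recall_regression(tab, "alpha", "AD", "EO")
  tab10 <- dplyr::mutate(tab, delayed_recall = delayed_recall * 10)
  f2 <- fit_recall_regression(tab10, "alpha", "AD", "EO")
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$estimate[t2$term == "delayed_recall"],
               t1$estimate[t1$term == "delayed_recall"] / 10,
               tolerance = 1e-9)
  expect_equal(t2$statistic[t2$term == "delayed_recall"],
               t1$statistic[t1$term == "delayed_recall"], tolerance = 1e-9)
  expect_error(fit_recall_regression(tab[1:15, ], "alpha", "AD", "EO"),
               "more than 3")
})

test_that("reactivity regressions flag degenerate all-zero outcomes", {
  sp <- subject_table_spec(n_per_group = c(control = 10, AD = 10),
                           beta_disease = 0, beta_condition = 0,
                           beta_age = 0, beta_recall = 0,
                           sigma_subject = 0, sigma_resid = 0, seed = 47)
  tab <- generate_subject_table(sp) # reactivity identically 0
  f <- fit_reactivity_regression(tab, "alpha", "AD")
  expect_true(glance(f)$degenerate)
  td <- tidy(f)
  expect_equal(td$estimate[td$term != "(Intercept)"], c(0, 0))
  # permutation invariance on a non-degenerate fit
  sp2 <- subject_table_spec(n_per_group = c(control = 30, AD = 30),
                            seed = 48)
  tab2 <- generate_subject_table(sp2)
  f1 <- fit_reactivity_regression(tab2, "alpha", "AD")
  set.seed(2)
  f2 <- fit_reactivity_regression(tab2[sample(nrow(tab2)), ], "alpha", "AD")
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-12)
})

test_that("the two-tier significance policy applies strict thresholds", {
  res <- tibble::tibble(term = c("a", "b", "c"),
                        p.value = c(0.031, 0.049, 0.051))
  m <- significance_policy(res, "mixed")
  expect_identical(m$significant, c(TRUE, TRUE, FALSE))
  res2 <- tibble::tibble(term = c("a", "b", "c"),
                         p.value = c(0.029, 0.025, 0.0249))
  r <- significance_policy(res2, "regression")
  expect_identical(r$significant, c(FALSE, FALSE, TRUE)) # strict p < alpha
  expect_identical(unique(r$alpha), 0.025)
})

test_that("tidy and glance expose the fit record", {
  sp <- subject_table_spec(n_per_group = c(control = 15, AD = 15), seed = 49)
  tab <- generate_subject_table(sp)
  f <- fit_sw_mixed_model(tab, "delta")
  td <- tidy(f)
  expect_setequal(
    c("family", "outcome", "band", "term", "estimate", "robust_se",
      "statistic", "p.value", "effect_size", "significant"),
    intersect(names(td), c("family", "outcome", "band", "term", "estimate",
                           "robust_se", "statistic", "p.value",
                           "effect_size", "significant")))
  g <- glance(f)
  expect_identical(g$n_subjects, 30L)
  expect_identical(g$n_obs, 60L)
  expect_identical(g$statistic_type, "z")
})
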