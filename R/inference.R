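#' Mixed model for small-worldness
#'
#' Fits, for one frequency band, a linear mixed-effects model predicting
#' small-worldness from disease status (AD vs control), recording
#' condition (EO vs EC), and age, with subject-specific random
#' intercepts, by maximum likelihood. Inference on the fixed effects uses
#' cluster-robust (sandwich, clustered by subject) standard errors and z
#' statistics; significance is declared at `alpha` (default 0.05,
#' strictly `p < alpha`).
#'
#' Coding: control = 0 / AD = 1 and EC = 0 / EO = 1, so a negative
#' disease coefficient means lower small-worldness in patients.
#'
#' @param table Long-format subject table with columns `subject_id`,
#'   `group`, `condition`, `age`, `band`, `sw` (see
#'   [generate_subject_table()]).
#' @param band Which band to analyse.
#' @param se `"cluster-robust"` (default) or `"model-based"`.
#' @param reml Fit by REML instead of ML (default `FALSE`).
#' @param alpha Significance threshold (default 0.05).
#' @return A `plisw_fit` object; see [tidy.plisw_fit()].
#' @export
fit_sw_mixed_model <- function(table, band, se = c("cluster-robust",
                                                   "model-based"),
                               reml = FALSE, alpha = 0.05) {
  se <- match.arg(se)
  d <- dplyr::filter(table, .data$band == !!band)
  if (!nrow(d)) stop("no rows for band '", band, "'", call. = FALSE)
  if (length(unique(d$condition)) < 2L) {
    stop("both conditions must be present", call. = FALSE)
  }
  d$disease <- as.numeric(d$group == "AD")
  d$eo <- as.numeric(d$condition == "EO")
  fit <- suppressMessages(lme4::lmer(
    sw ~ disease + eo + age + (1 | subject_id),
    data = d, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  b <- lme4::fixef(fit)
  V <- if (se == "cluster-robust") {
    lmer_cluster_vcov(fit, d$subject_id)
  } else {
    as.matrix(stats::vcov(fit))
  }
  rse <- sqrt(diag(V))
  z <- b / rse
  p <- 2 * stats::pnorm(-abs(z))
  # standardized coefficients as a descriptive effect-size column
  sdx <- c(`(Intercept)` = NA_real_,
           disease = stats::sd(d$disease), eo = stats::sd(d$eo),
           age = stats::sd(d$age))
  es <- unname(b * sdx[names(b)] / stats::sd(d$sw))
  term_names <- c(`(Intercept)` = "(Intercept)", disease = "disease",
                  eo = "condition", age = "age")
  out <- tibble::tibble(
    term = unname(term_names[names(b)]),
    estimate = unname(b), robust_se = unname(rse),
    statistic = unname(z), p.value = unname(p), effect_size = es
  )
  new_plisw_fit(out, outcome = "sw", family = "mixed", band = band,
                alpha = alpha, statistic_type = "z",
                se_flavor = if (se == "cluster-robust") {
                  "heteroscedasticity-robust"
                } else "model-based",
                n_obs = nrow(d), n_subjects = length(unique(d$subject_id)),
                singular = singular, model = fit)
}

# cluster-robust sandwich vcov for the fixed effects of a random-intercept
# lmer fit: bread = (sum_g X_g' W_g X_g)^-1 with W_g the inverse marginal
# covariance of cluster g, meat = sum_g (X_g' W_g r_g)(X_g' W_g r_g)',
# scaled by G/(G-1)
lmer_cluster_vcov <- function(fit, cluster) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  b <- lme4::fixef(fit)
  r <- y - as.vector(X %*% b)
  s2 <- stats::sigma(fit)^2
  vc <- lme4::VarCorr(fit)
  tau2 <- as.numeric(vc[[1]])
  k <- ncol(X)
  A <- matrix(0, k, k)
  M <- matrix(0, k, k)
  groups <- split(seq_along(y), cluster)
  for (idx in groups) {
    ng <- length(idx)
    Xg <- X[idx, , drop = FALSE]
    rg <- r[idx]
    # W_g = (sigma2 I + tau2 J)^-1 via Sherman-Morrison
    c1 <- 1 / s2
    c2 <- -tau2 / (s2 * (s2 + ng * tau2))
    WX <- c1 * Xg + c2 * matrix(colSums(Xg), ng, k, byrow = TRUE)
    A <- A + crossprod(Xg, WX)
    sg <- crossprod(WX, rg)
    M <- M + tcrossprod(sg)
  }
  G <- length(groups)
  Ainv <- solve(A)
  (G / (G - 1)) * Ainv %*% M %*% Ainv
}

#' Regression of small-worldness on delayed recall and age
#'
#' Ordinary least squares of a network outcome (by default `sw`) on the
#' WMS-R delayed-recall index and age, within one group x condition x
#' band slice. Standard errors are heteroscedasticity-robust (HC1) by
#' default; `se = "auto"` uses robust errors only when a Breusch--Pagan
#' variance-homogeneity check rejects at 0.05, `se = "model"` always uses
#' classical errors. t statistics are referenced against n - 3 residual
#' degrees of freedom; significance is declared at `alpha` (default
#' 0.025, the family-wise level for the two disease groups).
#'
#' Per-term partial eta squared is reported as `t^2 / (t^2 + df)`.
#'
#' @param table Long-format subject table (one row per subject for the
#'   selected band after slicing).
#' @param band,group,condition Slice selectors.
#' @param outcome Outcome column (default `"sw"`).
#' @param se `"robust"` (default), `"auto"`, or `"model"`.
#' @param alpha Significance threshold (default 0.025).
#' @return A `plisw_fit` object.
#' @export
fit_recall_regression <- function(table, band, group, condition,
                                  outcome = "sw",
                                  se = c("robust", "auto", "model"),
                                  alpha = 0.025) {
  se <- match.arg(se)
  d <- dplyr::filter(table, .data$band == !!band, .data$group == !!group,
                     .data$condition == !!condition)
  d <- dplyr::distinct(d, .data$subject_id, .keep_all = TRUE)
  ols_robust_fit(d, outcome, family = "regression", band = band,
                 group = group, condition = condition, se = se,
                 alpha = alpha)
}

#' Regression of eyes-state reactivity on delayed recall and age
#'
#' As [fit_recall_regression()], but the outcome is the per-subject
#' relative difference in small-worldness between the eyes-open and
#' eyes-closed conditions, `(EO - EC) / (EO + EC)`, one value per
#' subject.
#'
#' @param table Long-format subject table containing a `reactivity`
#'   column.
#' @param band,group Slice selectors.
#' @param se,alpha See [fit_recall_regression()].
#' @return A `plisw_fit` object; flagged degenerate when the outcome has
#'   zero variance.
#' @export
fit_reactivity_regression <- function(table, band, group,
                                      se = c("robust", "auto", "model"),
                                      alpha = 0.025) {
  se <- match.arg(se)
  d <- dplyr::filter(table, .data$band == !!band, .data$group == !!group)
  d <- dplyr::distinct(d, .data$subject_id, .keep_all = TRUE)
  ols_robust_fit(d, "reactivity", family = "reactivity", band = band,
                 group = group, condition = NA_character_, se = se,
                 alpha = alpha)
}

ols_robust_fit <- function(d, outcome, family, band, group, condition, se,
                           alpha) {
  if (nrow(d) <= 3L) {
    stop("need more than 3 subjects in the slice (got ", nrow(d), ")",
         call. = FALSE)
  }
  y <- d[[outcome]]
  degenerate <- stats::var(y) == 0
  form <- stats::as.formula(paste(outcome, "~ delayed_recall + age"))
  fit <- stats::lm(form, data = d)
  use_robust <- switch(se,
    robust = TRUE,
    model = FALSE,
    auto = {
      if (degenerate || !requireNamespace("lmtest", quietly = TRUE)) {
        TRUE
      } else {
        lmtest::bptest(fit)$p.value < 0.05
      }
    }
  )
  V <- if (use_robust && !degenerate) {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    stats::vcov(fit)
  }
  b <- stats::coef(fit)
  if (degenerate) {
    b[] <- ifelse(names(b) == "(Intercept)", y[1], 0)
    V[] <- 0
  }
  rse <- sqrt(diag(V))
  df <- fit$df.residual
  tstat <- ifelse(rse > 0, b / rse, 0)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[rse == 0] <- 1
  eta2 <- tstat^2 / (tstat^2 + df)
  out <- tibble::tibble(
    term = names(b), estimate = unname(b), robust_se = unname(rse),
    statistic = unname(tstat), p.value = unname(p),
    effect_size = unname(eta2)
  )
  new_plisw_fit(out, outcome = outcome, family = family, band = band,
                group = group, condition = condition, alpha = alpha,
                statistic_type = "t",
                se_flavor = if (use_robust) "heteroscedasticity-robust"
                            else "model-based",
                n_obs = nrow(d), n_subjects = nrow(d),
                singular = FALSE, degenerate = degenerate, model = fit)
}

new_plisw_fit <- function(tidy_tbl, ..., model = NULL) {
  meta <- list(...)
  meta$tidy <- dplyr::mutate(
    tidy_tbl,
    significant = .data$p.value < meta$alpha & .data$term != "(Intercept)"
  )
  meta$model <- model
  structure(meta, class = "plisw_fit")
}

#' @export
print.plisw_fit <- function(x, ...) {
  cat("<plisw_fit> family=", x$family, " outcome=", x$outcome,
      if (!is.null(x$band)) paste0(" band=", x$band),
      " (", x$statistic_type, " statistics, ", x$se_flavor, " SEs, alpha=",
      x$alpha, ")\n", sep = "")
  print(x$tidy)
  if (isTRUE(x$singular)) cat("note: singular random-effects fit\n")
  if (isTRUE(x$degenerate)) cat("note: degenerate (zero-variance) outcome\n")
  invisible(x)
}

#' Two-sample t test from group summaries
#'
#' Pooled-variance Student's t statistic computed from printed group
#' means, SDs, and sizes, with `n1 + n2 - 2` degrees of freedom and a
#' two-sided p value. Useful for reproducing demographic tables when only
#' summaries are available.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variable Label for the result row.
#' @return A one-row tibble (`variable`, `statistic_type`, `statistic`,
#'   `df`, `p_value`).
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                      variable = "") {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (mean1 != mean2) {
      stop("zero pooled variance with unequal means", call. = FALSE)
    }
    t <- 0
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tibble::tibble(variable = variable, statistic_type = "t", statistic = t,
                 df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom, two-sided p.
#'
#' @param a,b First row counts (e.g. males in each group).
#' @param c,d Second row counts.
#' @param variable Label for the result row.
#' @return A one-row tibble (`variable`, `statistic_type`, `statistic`,
#'   `df`, `p_value`).
#' @export
chi_square_2x2 <- function(a, b, c, d, variable = "") {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(variable = variable, statistic_type = "chi2",
                 statistic = unname(ct$statistic), df = 1,
                 p_value = unname(ct$p.value))
}

#' Apply the two-tier significance policy
#'
#' Flags terms significant at the family's alpha level: 0.05 for the
#' mixed-model family, 0.025 for the regression and reactivity families
#' (the stricter level reflects correcting across the two disease groups
#' only; no correction is applied across frequency bands). The comparison
#' is strict (`p < alpha`).
#'
#' @param results A tibble with a `p.value` column (e.g. bound
#'   [tidy.plisw_fit()] rows), or a list of `plisw_fit` objects.
#' @param analysis_family `"mixed"`, `"regression"`, or `"reactivity"`.
#' @return The input tibble with `alpha` and `significant` columns (for a
#'   list input, one bound tibble).
#' @export
significance_policy <- function(results,
                                analysis_family = c("mixed", "regression",
                                                    "reactivity")) {
  analysis_family <- match.arg(analysis_family)
  alpha <- if (analysis_family == "mixed") 0.05 else 0.025
  if (!is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(results, tidy))
  }
  dplyr::mutate(results, alpha = alpha,
                significant = .data$p.value < alpha)
}
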