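#' Specification for a synthetic subject table
#'
#' Describes the generative linear model for per-subject, per-condition,
#' per-band small-worldness values:
#' \deqn{sw = \alpha_b + \beta_{dis,b} AD + \beta_{cond,b} EO +
#'   \beta_{age,b} (age - \bar{age}) + \beta_{rec,b} (recall -
#'   \overline{recall}) + u_s + \epsilon}
#' with subject random intercepts \eqn{u_s \sim N(0, \sigma_{subj}^2)}
#' and residuals \eqn{\epsilon \sim N(0, (\sigma_{resid} h_s)^2)}, where
#' \eqn{h_s = 1 + hetero_factor |z_{recall,s}|} introduces optional
#' heteroscedasticity tied to the recall covariate. Age and recall are
#' centred at their population means so the intercept sets the typical
#' small-worldness scale.
#'
#' Per-band coefficients may be given as a single number (recycled over
#' the five canonical bands) or a named vector
#' `c(delta = ..., theta = ..., alpha = ..., beta = ..., gamma = ...)`.
#' The defaults use effect magnitudes typical of MEG small-world studies
#' of Alzheimer's disease: a negative disease effect growing with
#' frequency, small condition effects, age slopes near 0.01 per year, and
#' small negative recall slopes.
#'
#' @param n_per_group Named integer vector `c(control = ..., AD = ...)`;
#'   default `c(control = 24, AD = 18)`.
#' @param beta_disease,beta_condition,beta_age,beta_recall Per-band fixed
#'   effects (AD vs control; EO vs EC; per year; per recall index point).
#' @param intercept Baseline small-worldness (default 1.05).
#' @param sigma_subject Random-intercept SD (default 0.08).
#' @param sigma_resid Residual SD (default 0.12).
#' @param hetero_factor Heteroscedasticity multiplier (default 0: i.i.d.
#'   residuals).
#' @param age_dist,recall_dist Named lists `list(control = c(mean, sd),
#'   AD = c(mean, sd))` for the age (years) and WMS-R delayed-recall
#'   index distributions. Defaults reflect an elderly AD/control cohort:
#'   ages around 68/72, recall around 99/61.
#' @param prop_male Probability a subject is male (default 0.62).
#' @param reactivity_model Optional list
#'   `list(intercept, beta_recall, beta_age, sigma)` giving a direct
#'   linear model for the per-subject reactivity column; when `NULL`
#'   (default) reactivity is derived from the generated EO/EC
#'   small-worldness values.
#' @param seed Integer seed.
#' @return An object of class `subject_table_spec`.
#' @export
subject_table_spec <- function(
    n_per_group = c(control = 24, AD = 18),
    beta_disease = c(delta = -0.059, theta = -0.020, alpha = -0.056,
                     beta = -0.114, gamma = -0.132),
    beta_condition = c(delta = -0.073, theta = 0.078, alpha = 0.031,
                       beta = -0.023, gamma = 0.018),
    beta_age = c(delta = -0.001, theta = 0.005, alpha = 0.011,
                 beta = 0.014, gamma = 0.011),
    beta_recall = c(delta = -0.013, theta = -0.009, alpha = -0.013,
                    beta = -0.011, gamma = -0.007),
    intercept = 1.05,
    sigma_subject = 0.08, sigma_resid = 0.12, hetero_factor = 0,
    age_dist = list(control = c(68.4, 6.9), AD = c(71.8, 6.2)),
    recall_dist = list(control = c(98.8, 11.7), AD = c(60.8, 11.1)),
    prop_male = 0.62,
    reactivity_model = NULL,
    seed = 1L) {
  if (any(n_per_group < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (sigma_subject < 0 || sigma_resid < 0) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  bands <- canonical_bands()$band
  expand <- function(b, nm) {
    if (length(b) == 1L && is.null(names(b))) {
      b <- stats::setNames(rep(b, 5), bands)
    }
    if (!all(bands %in% names(b))) {
      stop(nm, " must be scalar or named by the five canonical bands",
           call. = FALSE)
    }
    b[bands]
  }
  structure(
    list(n_per_group = n_per_group,
         beta_disease = expand(beta_disease, "beta_disease"),
         beta_condition = expand(beta_condition, "beta_condition"),
         beta_age = expand(beta_age, "beta_age"),
         beta_recall = expand(beta_recall, "beta_recall"),
         intercept = intercept,
         sigma_subject = sigma_subject, sigma_resid = sigma_resid,
         hetero_factor = hetero_factor,
         age_dist = age_dist, recall_dist = recall_dist,
         prop_male = prop_male,
         reactivity_model = reactivity_model,
         seed = as.integer(seed)),
    class = "subject_table_spec"
  )
}

#' Generate a synthetic subject table
#'
#' Draws covariates and per-band small-worldness values from the linear
#' model encoded in the spec. Output is in long format: one row per
#' subject x condition x band. The true coefficients are recorded in the
#' `"truth"` attribute.
#'
#' @param spec A [subject_table_spec()].
#' @return A tibble with columns `subject_id`, `group`, `sex`,
#'   `condition`, `age`, `delayed_recall`, `band`, `sw`, `reactivity`
#'   (the reactivity value is repeated on both condition rows of a
#'   subject x band).
#' @export
generate_subject_table <- function(spec) {
  stopifnot(inherits(spec, "subject_table_spec"))
  bands <- canonical_bands()$band
  n_c <- spec$n_per_group[["control"]]
  n_a <- spec$n_per_group[["AD"]]
  n_s <- n_c + n_a
  tab <- withr_seed(spec$seed, {
    subj <- tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(n_s)),
      group = rep(c("control", "AD"), c(n_c, n_a)),
      sex = ifelse(stats::runif(n_s) < spec$prop_male, "M", "F"),
      age = c(stats::rnorm(n_c, spec$age_dist$control[1],
                           spec$age_dist$control[2]),
              stats::rnorm(n_a, spec$age_dist$AD[1], spec$age_dist$AD[2])),
      delayed_recall = c(
        stats::rnorm(n_c, spec$recall_dist$control[1],
                     spec$recall_dist$control[2]),
        stats::rnorm(n_a, spec$recall_dist$AD[1], spec$recall_dist$AD[2])),
      u = stats::rnorm(n_s, 0, spec$sigma_subject)
    )
    age_bar <- (n_c * spec$age_dist$control[1] + n_a * spec$age_dist$AD[1]) /
      n_s
    rec_bar <- (n_c * spec$recall_dist$control[1] +
                  n_a * spec$recall_dist$AD[1]) / n_s
    rec_sd <- (n_c * spec$recall_dist$control[2] +
                 n_a * spec$recall_dist$AD[2]) / n_s
    long <- tidyr::expand_grid(
      subject_id = subj$subject_id,
      condition = c("EO", "EC"),
      band = bands
    )
    long <- dplyr::left_join(long, subj, by = "subject_id")
    h <- 1 + spec$hetero_factor *
      abs((long$delayed_recall - rec_bar) / rec_sd)
    mu <- spec$intercept +
      spec$beta_disease[long$band] * as.numeric(long$group == "AD") +
      spec$beta_condition[long$band] * as.numeric(long$condition == "EO") +
      spec$beta_age[long$band] * (long$age - age_bar) +
      spec$beta_recall[long$band] * (long$delayed_recall - rec_bar) +
      long$u
    long$sw <- mu + stats::rnorm(nrow(long), 0, spec$sigma_resid * h)
    long <- dplyr::select(long, "subject_id", "group", "sex", "condition",
                          "age", "delayed_recall", "band", "sw")
    # reactivity: either derived from the generated EO/EC sw, or drawn
    # directly from its own linear model when one is supplied
    if (is.null(spec$reactivity_model)) {
      re <- long |>
        tidyr::pivot_wider(names_from = "condition", values_from = "sw") |>
        dplyr::mutate(reactivity = (.data$EO - .data$EC) /
                        (.data$EO + .data$EC)) |>
        dplyr::select("subject_id", "band", "reactivity")
    } else {
      rm_ <- spec$reactivity_model
      re <- tidyr::expand_grid(subject_id = subj$subject_id, band = bands)
      re <- dplyr::left_join(re, subj, by = "subject_id")
      re$reactivity <- rm_$intercept +
        rm_$beta_recall * (re$delayed_recall - rec_bar) +
        rm_$beta_age * (re$age - age_bar) +
        stats::rnorm(nrow(re), 0, rm_$sigma)
      re <- dplyr::select(re, "subject_id", "band", "reactivity")
    }
    dplyr::left_join(long, re, by = c("subject_id", "band"))
  })
  attr(tab, "truth") <- list(
    intercept = spec$intercept,
    beta_disease = spec$beta_disease, beta_condition = spec$beta_condition,
    beta_age = spec$beta_age, beta_recall = spec$beta_recall,
    sigma_subject = spec$sigma_subject, sigma_resid = spec$sigma_resid,
    hetero_factor = spec$hetero_factor,
    reactivity_model = spec$reactivity_model
  )
  tab
}
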