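#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a plisw model fit
#'
#' One row per model term with the estimate, robust standard error, test
#' statistic, p value, effect size, and significance flag at the fit's
#' alpha level, plus identifying columns for the analysis slice.
#'
#' @param x A `plisw_fit` (from [fit_sw_mixed_model()],
#'   [fit_recall_regression()], or [fit_reactivity_regression()]).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plisw_fit
#' @export
tidy.plisw_fit <- function(x, ...) {
  out <- x$tidy
  out$outcome <- x$outcome
  out$family <- x$family
  out$band <- x$band %||% NA_character_
  out$group <- x$group %||% NA_character_
  out$condition <- x$condition %||% NA_character_
  dplyr::relocate(out, "family", "outcome", "band", "group", "condition")
}

#' Glance at a plisw model fit
#'
#' @param x A `plisw_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level metadata (`family`, `outcome`,
#'   `band`, `n_obs`, `n_subjects`, `statistic_type`, `se_flavor`,
#'   `alpha`, `singular`, `degenerate`).
#' @method glance plisw_fit
#' @export
glance.plisw_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, outcome = x$outcome, band = x$band %||% NA_character_,
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    statistic_type = x$statistic_type, se_flavor = x$se_flavor,
    alpha = x$alpha,
    singular = isTRUE(x$singular), degenerate = isTRUE(x$degenerate)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
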