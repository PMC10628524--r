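#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a connectivity matrix
#'
#' @param object A [connectivity_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  n <- ncol(object$weights)
  df <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  df$pli <- as.vector(object$weights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pli)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLI") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s [%s], %s band (%d epochs)", object$subject_id,
                      object$condition, object$band$band,
                      object$n_epochs_averaged),
      x = "ROI", y = "ROI") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a model fit
#'
#' Estimates with approximate 95% robust confidence intervals, intercept
#' omitted.
#'
#' @param object A `plisw_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plisw_fit
#' @export
autoplot.plisw_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  crit <- if (object$statistic_type == "z") stats::qnorm(0.975) else {
    stats::qt(0.975, object$n_obs - nrow(d) - 1)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - crit * .data$robust_se,
      xmax = .data$estimate + crit * .data$robust_se)) +
    ggplot2::labs(title = sprintf("%s model (%s)", object$family,
                                  object$outcome),
                  x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Small-worldness by band, group, and condition
#'
#' Boxplots of per-subject small-worldness from a metrics table, faceted
#' by band, the usual first look at a study's network results.
#'
#' @param metrics Metrics tibble from [compute_connectivity()], joined or
#'   joinable with a covariate table carrying `group`.
#' @param subjects Optional covariate tibble with `subject_id`, `group`.
#' @return A ggplot.
#' @export
plot_small_worldness <- function(metrics, subjects = NULL) {
  d <- metrics
  if (!is.null(subjects) && !"group" %in% names(d)) {
    d <- dplyr::inner_join(d, subjects, by = "subject_id")
  }
  d$band <- factor(d$band, levels = canonical_bands()$band)
  mapping <- if ("group" %in% names(d)) {
    ggplot2::aes(x = .data$condition, y = .data$sw, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$condition, y = .data$sw)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~band, nrow = 1) +
    ggplot2::labs(x = NULL, y = "small-worldness") +
    ggplot2::theme_minimal()
}
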