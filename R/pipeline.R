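#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. The defaults
#' reproduce the reference settings of the motivating study design: the
#' five canonical bands, 5-s epochs, proportional threshold 0.2, 1000
#' rewired null graphs, and the two-tier significance policy (0.05 for
#' the mixed family, 0.025 for the regression families).
#'
#' @param bands Band tibble (default [canonical_bands()]).
#' @param epoch_s Epoch length in seconds (default 5).
#' @param kappa Proportional threshold (default 0.2).
#' @param n_null Null-ensemble size (default 1000).
#' @param master_seed Master seed; per-stage seeds are derived from it
#'   with a documented hash so partial reruns stay reproducible.
#' @param se_flavor `"robust"` or `"model"` for the regression layer.
#' @param alpha_mixed,alpha_regression Significance thresholds.
#' @param edge_trim_fraction Fraction of samples trimmed at each epoch
#'   edge in the PLI summation (default 0.05).
#' @param rewire_mode `"per_edge"` or `"total"` (see [rewire_graph()]).
#' @return An object of class `plisw_config`.
#' @export
pipeline_config <- function(bands = canonical_bands(), epoch_s = 5,
                            kappa = 0.2, n_null = 1000, master_seed = 1L,
                            se_flavor = "robust", alpha_mixed = 0.05,
                            alpha_regression = 0.025,
                            edge_trim_fraction = 0.05,
                            rewire_mode = "per_edge") {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1,
            epoch_s > 0, kappa > 0, kappa <= 1, n_null >= 1)
  structure(
    list(bands = bands, epoch_s = epoch_s, kappa = kappa, n_null = n_null,
         master_seed = as.integer(master_seed), se_flavor = se_flavor,
         alpha_mixed = alpha_mixed, alpha_regression = alpha_regression,
         edge_trim_fraction = edge_trim_fraction,
         rewire_mode = rewire_mode),
    class = "plisw_config"
  )
}

#' Derive a stage seed from the master seed
#'
#' Deterministic fan-out of the master seed into per-stage, per-item
#' seeds: a small polynomial rolling hash of `"stage:key"` folded into
#' the master seed modulo 2^31 - 1. Documented so that any stage can be
#' re-run in isolation.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name (e.g. `"signals"`, `"null"`).
#' @param key Item key (e.g. a subject/condition label).
#' @return A positive integer seed below 2^31.
#' @export
stage_seed <- function(master_seed, stage, key = "") {
  s <- paste0(stage, ":", key)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 7919) %% 2147483647 + 1)
}

#' Simulate a complete synthetic study
#'
#' Generates the two inputs of the pipeline: (a) per-subject,
#' per-condition multichannel oscillator signals whose band-wise coupling
#' differs by group and condition, and (b) a subject covariate table. By
#' default the study mirrors a 42-participant cohort (24 controls, 18
#' patients) with two 120-s recordings each; miniature studies for smoke
#' tests are obtained by lowering `n_per_group` and `duration_s`.
#'
#' Signals are sums of band-limited oscillator sets, one per analysis
#' band. Within each band the channels form four coupling clusters with
#' random pairwise lags; the coupling strength is modulated by condition
#' (stronger alpha synchrony with eyes closed) and by group (weaker gamma
#' synchrony in patients), which gives the downstream metrics realistic
#' band, group, and condition structure.
#'
#' @param config A [pipeline_config()].
#' @param n_per_group Named vector `c(control = ..., AD = ...)` (default
#'   `c(control = 24, AD = 18)`).
#' @param duration_s Recording length in seconds (default 120).
#' @param n_channels Number of ROIs (default 68).
#' @param noise_sd Additive noise SD (default 0.5).
#' @param out_dir Optional directory; when given, signals are written as
#'   delimited matrices with JSON sidecars and the subject table as CSV.
#' @return A list with `subjects` (covariate tibble) and `signals` (list
#'   of [roi_ts()] keyed `"<subject>_<condition>"`), invisibly also
#'   written to `out_dir` when requested.
#' @export
simulate_study <- function(config = pipeline_config(),
                           n_per_group = c(control = 24, AD = 18),
                           duration_s = 120, n_channels = 68,
                           noise_sd = 0.5, out_dir = NULL) {
  stopifnot(inherits(config, "plisw_config"))
  sspec <- subject_table_spec(
    n_per_group = n_per_group,
    seed = stage_seed(config$master_seed, "subjects")
  )
  subjects <- generate_subject_table(sspec) |>
    dplyr::distinct(.data$subject_id, .data$group, .data$sex, .data$age,
                    .data$delayed_recall)
  clusters <- cluster_assignment(n_channels, 4L)
  signals <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    for (cond in c("EO", "EC")) {
      seed_i <- stage_seed(config$master_seed, "signals",
                          paste0(sid, "_", cond))
      x <- NULL
      for (bi in seq_len(nrow(config$bands))) {
        bd <- config$bands[bi, ]
        cpl <- band_coupling_level(bd$band, grp, cond)
        ospec <- oscillator_spec(
          n_channels = n_channels, band = c(bd$f_lo, bd$f_hi),
          coupling = cluster_coupling(clusters, cpl),
          lag = cluster_lags(clusters, seed = seed_i + bi),
          noise_sd = 0, duration_s = duration_s, fs = 500,
          seed = seed_i + 100L * bi
        )
        xb <- generate_coupled_oscillators(ospec, subject_id = sid,
                                           condition = cond)$data
        x <- if (is.null(x)) xb else x + xb
      }
      if (noise_sd > 0) {
        x <- x + withr_seed(seed_i + 9999L, {
          matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
        })
      }
      ts <- roi_ts(x, fs = 500, subject_id = sid, condition = cond)
      signals[[paste0(sid, "_", cond)]] <- ts
      if (!is.null(out_dir)) {
        write_roi_ts(ts, file.path(out_dir, paste0(sid, "_", cond)))
      }
    }
  }
  if (!is.null(out_dir)) {
    readr::write_csv(subjects, file.path(out_dir, "subjects.csv"))
    write_manifest(file.path(out_dir, "manifest_simulate.json"), config,
                   stage = "simulate",
                   counts = list(subjects = nrow(subjects),
                                 signals = length(signals)))
  }
  list(subjects = subjects, signals = signals)
}

# band- group- and condition-specific within-cluster coupling level; the
# alpha band reacts to eye closure, the gamma band to disease
band_coupling_level <- function(band, group, condition) {
  base <- c(delta = 0.55, theta = 0.55, alpha = 0.5, beta = 0.55,
            gamma = 0.6)[[band]]
  if (band == "alpha" && condition == "EC") base <- base + 0.25
  if (band == "gamma" && group == "AD") base <- base - 0.2
  base
}

cluster_assignment <- function(n_channels, n_clusters) {
  sort(rep_len(seq_len(n_clusters), n_channels))
}

cluster_coupling <- function(clusters, level) {
  same <- outer(clusters, clusters, `==`)
  cpl <- ifelse(same, level, 0)
  diag(cpl) <- 1
  cpl
}

cluster_lags <- function(clusters, seed, lag_sd = 0.6) {
  p <- length(clusters)
  withr_seed(seed, {
    o <- stats::rnorm(p, 0, lag_sd) # per-channel offsets => consistent lags
    lg <- outer(o, o, `-`)
    diag(lg) <- 0
    lg
  })
}

#' Compute connectivity and graph metrics for a study
#'
#' Runs the signal and graph stages for every subject and condition:
#' epoch segmentation, per-band zero-phase filtering, analytic-signal
#' phases, per-epoch PLI, epoch averaging, proportional-threshold
#' binarization, observed and null-normalized metrics, and eyes-state
#' reactivity. Subjects missing one of the two conditions are skipped
#' with a warning.
#'
#' @param signals Either a list of [roi_ts()] (as returned by
#'   [simulate_study()]) or a directory containing
#'   `<subject>_<condition>.tsv/.json` pairs written by [write_roi_ts()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for the metrics CSV and manifest.
#' @return A tibble with one row per subject x condition x band:
#'   `subject_id`, `condition`, `band`, `C`, `L`, `C_rand`, `L_rand`,
#'   `C_norm`, `L_norm`, `sw`, `reactivity`, `kappa`, `n_null`, `seed`.
#' @export
compute_connectivity <- function(signals, config = pipeline_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "plisw_config"))
  if (is.character(signals)) {
    signals <- read_signal_dir(signals)
  }
  keys <- names(signals)
  sids <- unique(sub("_(EO|EC)$", "", keys))
  rows <- list()
  for (sid in sids) {
    k_eo <- paste0(sid, "_EO")
    k_ec <- paste0(sid, "_EC")
    if (!k_eo %in% keys || !k_ec %in% keys) {
      warning("subject ", sid, " is missing a condition; skipped",
              call. = FALSE)
      next
    }
    conn <- lapply(c(EO = k_eo, EC = k_ec), function(k) {
      subject_connectivity(signals[[k]], config)
    })
    for (bi in seq_len(nrow(config$bands))) {
      bname <- config$bands$band[bi]
      rows[[paste0(sid, "_", bname)]] <- metrics_for_subject(
        conn$EO[[bname]], conn$EC[[bname]], kappa = config$kappa,
        n_null = config$n_null,
        seed = stage_seed(config$master_seed, "metrics",
                          paste0(sid, "_", bname)),
        mode = config$rewire_mode
      )
    }
  }
  metrics <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_manifest(file.path(out_dir, "manifest_connectivity.json"), config,
                   stage = "connectivity",
                   counts = list(metric_rows = nrow(metrics)))
  }
  metrics
}

#' Per-band epoch-averaged connectivity for one recording
#'
#' @param ts A [roi_ts()].
#' @param config A [pipeline_config()].
#' @return A named list of [connectivity_matrix()] objects, one per band.
#' @export
subject_connectivity <- function(ts, config = pipeline_config()) {
  epochs <- segment_epochs(ts, config$epoch_s)
  out <- list()
  for (bi in seq_len(nrow(config$bands))) {
    bd <- config$bands[bi, ]
    mats <- lapply(seq_along(epochs), function(e) {
      filt <- bandpass_epoch(epochs[[e]], bd)
      ph <- instantaneous_phase(filt, band = bd, epoch_index = e)
      pli_epoch(ph, edge_trim = config$edge_trim_fraction)
    })
    avg <- average_connectivity(mats)
    avg$subject_id <- ts$subject_id
    avg$condition <- ts$condition
    out[[bd$band]] <- avg
  }
  out
}

#' Statistical analysis of a metrics table
#'
#' Reproduces the inference layer on a joined metrics + covariates table:
#' per-band mixed models for small-worldness (disease, condition, age;
#' subject random intercepts; cluster-robust SEs), per-band x group x
#' condition regressions of small-worldness on delayed recall and age,
#' per-band x group regressions of the eyes-state reactivity, and a
#' demographic comparison of the groups.
#'
#' @param metrics Metrics tibble from [compute_connectivity()].
#' @param subjects Covariate tibble with `subject_id`, `group`, `age`,
#'   `delayed_recall` (and optionally `sex`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for results CSVs and a manifest.
#' @return A list of tibbles: `mixed`, `recall`, `reactivity`,
#'   `demographics`.
#' @export
analyze_study <- function(metrics, subjects, config = pipeline_config(),
                          out_dir = NULL) {
  stopifnot(inherits(config, "plisw_config"))
  orphans <- setdiff(metrics$subject_id, subjects$subject_id)
  if (length(orphans)) {
    stop("metric rows with no covariates for subject(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::inner_join(metrics, subjects, by = "subject_id")
  bands <- intersect(config$bands$band, unique(tab$band))
  if (!length(bands)) stop("no analysable bands in metrics", call. = FALSE)
  se_reg <- if (config$se_flavor == "robust") "robust" else "model"
  mixed <- purrr::map(bands, function(b) {
    tidy(fit_sw_mixed_model(tab, b, alpha = config$alpha_mixed))
  }) |> dplyr::bind_rows()
  slices <- tidyr::expand_grid(band = bands,
                               group = unique(tab$group),
                               condition = c("EO", "EC"))
  try_slice <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      warning("slice ", label, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  recall <- purrr::pmap(slices, function(band, group, condition) {
    try_slice(paste(band, group, condition),
              tidy(fit_recall_regression(tab, band, group, condition,
                                         se = se_reg,
                                         alpha = config$alpha_regression)))
  }) |> dplyr::bind_rows()
  rslices <- tidyr::expand_grid(band = bands, group = unique(tab$group))
  react <- purrr::pmap(rslices, function(band, group) {
    try_slice(paste(band, group),
              tidy(fit_reactivity_regression(tab, band, group, se = se_reg,
                                             alpha = config$alpha_regression)))
  }) |> dplyr::bind_rows()
  demo <- demographics_table(subjects)
  out <- list(mixed = mixed, recall = recall, reactivity = react,
              demographics = demo)
  if (!is.null(out_dir)) {
    readr::write_csv(mixed, file.path(out_dir, "results_mixed.csv"))
    readr::write_csv(recall, file.path(out_dir, "results_recall.csv"))
    readr::write_csv(react, file.path(out_dir, "results_reactivity.csv"))
    readr::write_csv(demo, file.path(out_dir, "results_demographics.csv"))
    write_manifest(file.path(out_dir, "manifest_analyze.json"), config,
                   stage = "analyze",
                   counts = lapply(out, nrow))
  }
  out
}

#' Demographic group comparison
#'
#' Two-sample pooled t tests for continuous covariates and a Pearson
#' chi-square (no continuity correction) for sex, comparing the control
#' and AD groups of a per-subject covariate table.
#'
#' @param subjects Per-subject tibble with `group` plus any of `age`,
#'   `delayed_recall`, `sex`.
#' @return A tibble of [two_sample_t_from_summary()] /
#'   [chi_square_2x2()] rows.
#' @export
demographics_table <- function(subjects) {
  g1 <- subjects[subjects$group == "control", ]
  g2 <- subjects[subjects$group == "AD", ]
  rows <- list()
  for (v in intersect(c("age", "delayed_recall"), names(subjects))) {
    rows[[v]] <- two_sample_t_from_summary(
      mean(g1[[v]]), stats::sd(g1[[v]]), nrow(g1),
      mean(g2[[v]]), stats::sd(g2[[v]]), nrow(g2), variable = v)
  }
  if ("sex" %in% names(subjects)) {
    rows$sex <- chi_square_2x2(sum(g1$sex == "M"), sum(g1$sex == "F"),
                               sum(g2$sex == "M"), sum(g2$sex == "F"),
                               variable = "sex")
  }
  dplyr::bind_rows(rows)
}

#' Run the full pipeline on synthetic data
#'
#' `simulate -> connectivity -> analyze` in one call; intended for smoke
#' tests and worked examples.
#'
#' @param config A [pipeline_config()].
#' @param n_per_group,duration_s,n_channels Passed to [simulate_study()].
#' @param out_dir Optional output directory.
#' @return A list with `subjects`, `metrics`, and `results`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         n_per_group = c(control = 24, AD = 18),
                         duration_s = 120, n_channels = 68,
                         out_dir = NULL) {
  sim <- simulate_study(config, n_per_group = n_per_group,
                        duration_s = duration_s, n_channels = n_channels,
                        out_dir = out_dir)
  metrics <- compute_connectivity(sim$signals, config, out_dir = out_dir)
  results <- analyze_study(metrics, sim$subjects, config, out_dir = out_dir)
  list(subjects = sim$subjects, metrics = metrics, results = results)
}
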