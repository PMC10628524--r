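#' Write an ROI time series as a delimited matrix plus JSON sidecar
#'
#' The matrix goes to `<prefix>.tsv` (tab-separated, no header, rows =
#' samples, columns = ROIs) and the metadata to `<prefix>.json`
#' (`fs`, `labels`, `subject`, `condition`).
#'
#' @param ts A [roi_ts()].
#' @param prefix Path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_roi_ts <- function(ts, prefix) {
  stopifnot(inherits(ts, "roi_ts"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ts$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = ts$fs, labels = ts$labels, subject = ts$subject_id,
         condition = ts$condition),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an ROI time series written by [write_roi_ts()]
#'
#' @param prefix Path prefix (without extension).
#' @return A [roi_ts()].
#' @export
read_roi_ts <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  side <- paste0(prefix, ".json")
  if (!file.exists(tsv)) stop("missing matrix file ", tsv, call. = FALSE)
  if (!file.exists(side)) stop("missing sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("fs", "labels", "subject", "condition")) {
    if (is.null(meta[[f]])) {
      stop("sidecar ", side, " is missing field '", f, "'", call. = FALSE)
    }
  }
  x <- as.matrix(utils::read.table(tsv, sep = "\t"))
  dimnames(x) <- NULL
  roi_ts(x, fs = meta$fs, labels = meta$labels, subject_id = meta$subject,
         condition = meta$condition)
}

#' Write a connectivity matrix as a delimited matrix plus JSON sidecar
#'
#' @param W A [connectivity_matrix()].
#' @param prefix Path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_connectivity <- function(W, prefix) {
  stopifnot(inherits(W, "connectivity_matrix"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(W$weights, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(band = as.list(W$band), subject = W$subject_id,
         condition = W$condition, n_epochs = W$n_epochs_averaged,
         labels = W$labels),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param prefix Path prefix (without extension).
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(x) <- NULL
  connectivity_matrix(x, band = tibble::as_tibble(meta$band),
                      subject_id = meta$subject, condition = meta$condition,
                      n_epochs_averaged = meta$n_epochs,
                      labels = meta$labels)
}

# read every <subject>_<EO|EC> pair in a directory into a named list
read_signal_dir <- function(dir) {
  sides <- list.files(dir, pattern = "_(EO|EC)\\.json$", full.names = TRUE)
  if (!length(sides)) stop("no signal sidecars found in ", dir, call. = FALSE)
  prefixes <- sub("\\.json$", "", sides)
  out <- lapply(prefixes, read_roi_ts)
  names(out) <- basename(prefixes)
  out
}

# run manifest: config snapshot, stage, record counts, package version
write_manifest <- function(path, config, stage, counts = list()) {
  cfg <- unclass(config)
  cfg$bands <- as.data.frame(cfg$bands)
  jsonlite::write_json(
    list(stage = stage, config = cfg, counts = counts,
         package_version = as.character(utils::packageVersion("plisw")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
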