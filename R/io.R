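config_defaults <- function() {
  list(channels = "all", bands = "all", kind = "de", window_s = 1,
       target_windows = 265L, a = 0.01, delta = 5, global_value = -1,
       use_srm = TRUE, use_global = TRUE, freeze_adjacency = FALSE,
       h1 = 128L, lr0 = 0.001, lr_decay = 0.96, epochs = 50L,
       batch_size = 64L, metric_window = 10L, seed = 1L)
}

#' Load a run configuration from YAML
#'
#' Fills defaults for absent keys (L1 strength `a = 0.01`, `lr0 = 0.001`,
#' `epochs = 50`, `batch_size = 64`, `delta = 5`, `channels = "all"`,
#' `bands = "all"`, ...); unknown keys are rejected by name.
#'
#' @param path YAML file; an empty or missing-key file yields the full
#'   default configuration.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  modifyList(defaults, user)
}

#' Write a band feature tensor to plain-text files
#'
#' Produces `features.csv` (long format: trial, subject, label, channel,
#' band, window, value) and `manifest.csv` (one row per trial) in `dir`.
#'
#' @param x a [band_tensor()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_features_csv <- function(x, dir) {
  stopifnot(inherits(x, "band_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$values)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3] * d[4]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3] * d[4]),
    band = rep(rep(x$band_names, each = d[1] * d[2]), times = d[4]),
    window = rep(seq_len(d[4]), each = d[1] * d[2] * d[3]),
    value = as.vector(x$values))
  write.csv(long, file.path(dir, "features.csv"), row.names = FALSE)
  manifest <- data.frame(trial = seq_len(d[1]), subject = x$subject_ids,
                         label = as.character(x$labels), n_windows = d[4],
                         feature_kind = x$feature_kind)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a band feature tensor written by [write_features_csv()]
#'
#' @param dir directory holding `features.csv` and `manifest.csv`.
#' @return A [band_tensor()].
#' @export
read_features_csv <- function(dir) {
  long <- read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  chans <- unique(long$channel)
  bands <- unique(long$band)
  d <- c(nrow(manifest), length(chans), length(bands), max(long$window))
  # long format is written in array order, so a straight fill restores it
  vals <- array(long$value, d)
  band_tensor(vals, chans, bands, manifest$subject, manifest$label,
              manifest$feature_kind[1])
}

#' Export an adjacency matrix as labelled CSV
#'
#' @param A square matrix with channel-name dimnames.
#' @param path output CSV path.
#' @export
write_adjacency_csv <- function(A, path) {
  stopifnot(is.matrix(A), !is.null(rownames(A)))
  df <- data.frame(channel = rownames(A), A, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation report
#'
#' Emits `summary.json` (mean/STD accuracy and per-fold accuracies),
#' `folds.csv`, `confusion.csv` (row-normalised percent), and
#' `manifest.json` (package version, seed, config snapshot, timestamp)
#' into `dir`.
#'
#' @param run an `sgcsrm_run` from [summarize_run()].
#' @param dir output directory (created if needed).
#' @param seed,config optional provenance recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir, seed = NULL, config = NULL) {
  stopifnot(inherits(run, "sgcsrm_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(acc_mean = run$acc_mean, acc_std = run$acc_std,
                  n_folds = length(run$fold_accuracies),
                  fold_accuracies = as.list(stats::setNames(
                    run$fold_accuracies, run$held_out)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(data.frame(fold = seq_along(run$fold_accuracies),
                       held_out = run$held_out,
                       accuracy = run$fold_accuracies),
            file.path(dir, "folds.csv"), row.names = FALSE)
  cp <- run$confusion_percent
  if (is.null(rownames(cp)))
    dimnames(cp) <- list(emotion_levels, emotion_levels)
  conf <- data.frame(truth = rownames(cp), cp, check.names = FALSE)
  write.csv(conf, file.path(dir, "confusion.csv"), row.names = FALSE)
  cfg_snapshot <- if (!is.null(config)) {
    cs <- unclass(config)
    cs$layout <- NULL
    cs
  } else NULL
  manifest <- list(package = "sgcsrm",
                   version = as.character(utils::packageVersion("sgcsrm")),
                   seed = seed, config = cfg_snapshot,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read back a report summary
#'
#' @param dir directory written by [write_report()].
#' @return The parsed `summary.json` as a list.
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
}
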