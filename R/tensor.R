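#' Band feature tensor
#'
#' Container for per-trial, per-channel, per-band, per-window EEG features:
#' a 4-D numeric array `values` of shape trial x channel x band x window,
#' together with channel and band names, a subject id and a class label per
#' trial, and the feature kind (`"de"` for differential entropy in nats,
#' `"psd"` for band power).
#'
#' @param values numeric 4-D array, trial x channel x band x window.
#' @param channel_names character vector, one name per channel (unique).
#' @param band_names character vector, one name per band (unique).
#' @param subject_ids character vector, one subject id per trial.
#' @param labels factor or character vector of class labels per trial, with
#'   values among `"negative"`, `"neutral"`, `"positive"`.
#' @param feature_kind `"de"` or `"psd"`.
#' @return An object of class `band_tensor`.
#' @export
band_tensor <- function(values, channel_names, band_names, subject_ids,
                        labels, feature_kind = c("de", "psd")) {
  feature_kind <- match.arg(feature_kind)
  if (length(dim(values)) != 4L)
    stop("`values` must be a 4-D array (trial x channel x band x window)")
  if (!all(is.finite(values))) stop("non-finite values in feature tensor")
  d <- dim(values)
  if (length(channel_names) != d[2]) stop("channel_names length mismatch")
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  if (length(band_names) != d[3]) stop("band_names length mismatch")
  if (anyDuplicated(band_names)) stop("duplicate band names")
  if (length(subject_ids) != d[1]) stop("subject_ids length mismatch")
  labels <- as_emotion_label(labels)
  if (length(labels) != d[1]) stop("labels length mismatch")
  structure(list(
    values        = values,
    channel_names = as.character(channel_names),
    band_names    = as.character(band_names),
    subject_ids   = as.character(subject_ids),
    labels        = labels,
    feature_kind  = feature_kind
  ), class = "band_tensor")
}

#' @export
print.band_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_tensor> %d trials x %d channels x %d bands x %d windows (%s)\n",
              d[1], d[2], d[3], d[4], toupper(x$feature_kind)))
  cat("  subjects:", paste(unique(x$subject_ids), collapse = " "), "\n")
  cat("  bands:   ", paste(x$band_names, collapse = " "), "\n")
  tb <- table(x$labels)
  cat("  labels:  ", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.band_tensor <- function(x) dim(x$values)

emotion_levels <- c("negative", "neutral", "positive")

as_emotion_label <- function(labels) {
  if (is.numeric(labels)) {
    # SEED convention {-1, 0, 1}
    if (!all(labels %in% c(-1, 0, 1))) stop("numeric labels must be -1/0/1")
    labels <- emotion_levels[labels + 2L]
  }
  labels <- as.character(labels)
  if (!all(labels %in% emotion_levels))
    stop("labels must be among: ", paste(emotion_levels, collapse = ", "))
  factor(labels, levels = emotion_levels)
}

#' The 12-channel subset suited to emotion classification
#'
#' Temporal/lateral electrodes over both hemispheres commonly selected for
#' EEG emotion recognition.
#' @return Character vector of 12 channel names.
#' @export
seed12_channels <- function() {
  c("FT7", "T7", "TP7", "P7", "C5", "CP5",
    "FT8", "T8", "TP8", "P8", "C6", "CP6")
}

#' Select and reorder channels of a band tensor
#'
#' @param x a [band_tensor()].
#' @param wanted character vector of channel names (the output order), or a
#'   preset: `"all"` (identity) or `"seed12"` (the 12-channel subset of
#'   [seed12_channels()]).
#' @return A `band_tensor` with the channel axis reduced/reordered.
#' @export
select_channels <- function(x, wanted = "all") {
  stopifnot(inherits(x, "band_tensor"))
  if (length(wanted) == 1L && wanted == "all") return(x)
  if (length(wanted) == 1L && wanted == "seed12") wanted <- seed12_channels()
  missing <- setdiff(wanted, x$channel_names)
  if (length(missing))
    stop("channels not present in tensor: ", paste(missing, collapse = ", "))
  idx <- match(wanted, x$channel_names)
  band_tensor(x$values[, idx, , , drop = FALSE], wanted, x$band_names,
              x$subject_ids, x$labels, x$feature_kind)
}

#' Select and reorder frequency bands of a band tensor
#'
#' @param x a [band_tensor()].
#' @param wanted character vector of band names, or a preset: `"all"`
#'   (delta, theta, alpha, beta, gamma) or `"four"` (theta, alpha, beta,
#'   gamma).
#' @return A `band_tensor` with the band axis reduced/reordered.
#' @export
select_bands <- function(x, wanted = "all") {
  stopifnot(inherits(x, "band_tensor"))
  if (length(wanted) == 1L && wanted %in% c("all", "four")) {
    wanted <- if (wanted == "four") c("theta", "alpha", "beta", "gamma")
              else x$band_names
  }
  missing <- setdiff(wanted, x$band_names)
  if (length(missing))
    stop("bands not present in tensor: ", paste(missing, collapse = ", "))
  if (identical(wanted, x$band_names)) return(x)
  idx <- match(wanted, x$band_names)
  band_tensor(x$values[, , idx, , drop = FALSE], x$channel_names, wanted,
              x$subject_ids, x$labels, x$feature_kind)
}

#' Pad or truncate the window axis to a fixed length
#'
#' Shorter trials are zero-filled at the end of the window axis; longer
#' trials are truncated from the end. Used to normalise trials of unequal
#' duration to a common processing period (265 one-second windows for the
#' SEED protocol).
#'
#' @param x a [band_tensor()].
#' @param target_windows integer, the fixed window-axis length.
#' @return A `band_tensor` with exactly `target_windows` windows.
#' @export
pad_windows <- function(x, target_windows = 265L) {
  stopifnot(inherits(x, "band_tensor"), target_windows >= 1)
  d <- dim(x$values)
  if (d[4] == target_windows) return(x)
  out <- array(0, c(d[1:3], target_windows))
  keep <- min(d[4], target_windows)
  out[, , , seq_len(keep)] <- x$values[, , , seq_len(keep)]
  band_tensor(out, x$channel_names, x$band_names, x$subject_ids, x$labels,
              x$feature_kind)
}

#' Standardise features within each subject
#'
#' For every subject independently, each (channel, band, window) feature is
#' centred to mean 0 and scaled to population standard deviation 1 across
#' that subject's trials. Features with standard deviation below `eps` map
#' to 0. Removes per-subject offsets before subject-independent
#' cross-validation; because every subject is normalised from its own trials
#' only, no information crosses the leave-one-subject-out boundary.
#'
#' @param x a [band_tensor()].
#' @param eps guard on small standard deviations.
#' @return A normalised `band_tensor`.
#' @export
normalize_subjects <- function(x, eps = 1e-8) {
  stopifnot(inherits(x, "band_tensor"))
  vals <- x$values
  d <- dim(vals)
  for (sid in unique(x$subject_ids)) {
    idx <- which(x$subject_ids == sid)
    n <- length(idx)
    # trial axis is first, so columns enumerate (channel, band, window)
    v <- matrix(vals[idx, , , , drop = FALSE], nrow = n)
    m <- colMeans(v)
    s <- sqrt(pmax(colMeans(v^2) - m^2, 0))
    centred <- sweep(v, 2, m)
    scaled <- sweep(centred, 2, pmax(s, eps), "/")
    scaled[, s <= eps] <- 0
    vals[idx, , , ] <- array(scaled, c(n, d[2:4]))
  }
  band_tensor(vals, x$channel_names, x$band_names, x$subject_ids, x$labels,
              x$feature_kind)
}

#' Subset trials of a band tensor
#'
#' @param x a [band_tensor()].
#' @param trials integer or logical index over the trial axis.
#' @return A `band_tensor` restricted to the selected trials.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "band_tensor"))
  band_tensor(x$values[trials, , , , drop = FALSE], x$channel_names,
              x$band_names, x$subject_ids[trials], x$labels[trials],
              x$feature_kind)
}
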