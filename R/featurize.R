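#' Raw multichannel EEG recording
#'
#' @param samples channel x time numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names one label per row of `samples`.
#' @param subject_id,trial_id identifiers.
#' @param label class label (`"negative"`, `"neutral"`, `"positive"`, or the
#'   SEED numeric coding -1/0/1).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names, subject_id, trial_id,
                          label) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (nrow(samples) != length(channel_names))
    stop("channel_names must match the number of rows of `samples`")
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  if (!all(is.finite(samples))) stop("non-finite samples")
  structure(list(
    samples = samples, fs = fs,
    channel_names = as.character(channel_names),
    subject_id = as.character(subject_id),
    trial_id = as.character(trial_id),
    label = as_emotion_label(label)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s trial %s (%s): %d channels, %.1f s @ %g Hz\n",
              x$subject_id, x$trial_id, as.character(x$label),
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-50 Hz.
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 14, 31),
             hi = c(3, 7, 13, 30, 50))
}

#' Per-window band variance via the short-time Fourier transform
#'
#' Splits each channel into non-overlapping windows of `window_s` seconds
#' (a partial trailing window is discarded), applies a Hamming window, and
#' sums the periodogram over the frequency bins inside `[lo, hi]`. The
#' periodogram is normalised so that summing over all bins recovers the
#' window's total power, i.e. the value is the portion of the signal
#' variance carried by the band.
#'
#' @param recording an [eeg_recording()].
#' @param lo,hi band edges in Hz (`0 < lo < hi < fs/2`).
#' @param window_s window length in seconds (default 1).
#' @return channel x window matrix of nonnegative band variances.
#' @export
band_variance <- function(recording, lo, hi, window_s = 1) {
  stopifnot(inherits(recording, "eeg_recording"), lo > 0, hi > lo)
  fs <- recording$fs
  if (hi >= fs / 2) stop("band exceeds Nyquist")
  n <- round(window_s * fs)
  nt <- ncol(recording$samples)
  if (nt < n) stop("trial too short: fewer samples than one window")
  nwin <- nt %/% n
  w <- as.numeric(signal::hamming(n))
  wnorm <- n * sum(w^2)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)    # two-sided spectrum, mirrored bins
  sel <- freqs >= lo & freqs <= hi
  out <- matrix(0, nrow(recording$samples), nwin)
  for (d in seq_len(nwin)) {
    seg <- recording$samples[, ((d - 1) * n + 1):(d * n), drop = FALSE]
    seg <- sweep(seg, 2, w, "*")
    spec <- Mod(t(stats::mvfft(t(seg))))^2
    out[, d] <- rowSums(spec[, sel, drop = FALSE]) / wnorm
  }
  rownames(out) <- recording$channel_names
  out
}

#' Differential entropy of a Gaussian band signal
#'
#' For a band-limited signal modelled as N(mu, sigma^2) the differential
#' entropy is `0.5 * log(2 * pi * e * sigma^2)` nats (natural logarithm).
#'
#' @param variance positive variance(s).
#' @return Differential entropy in nats, same shape as `variance`.
#' @export
differential_entropy <- function(variance) {
  if (any(variance <= 0)) stop("nonpositive variance")
  0.5 * log(2 * pi * exp(1) * variance)
}

#' Extract a band feature tensor from raw recordings
#'
#' Runs [band_variance()] for every recording and band, then either keeps
#' the band power (`kind = "psd"`) or transforms it with
#' [differential_entropy()] (`kind = "de"`). All recordings must share the
#' sampling rate and channel set; the number of windows is the minimum over
#' recordings unless `target_windows` is given, in which case every trial is
#' padded/truncated to that length via [pad_windows()].
#'
#' @param recordings list of [eeg_recording()].
#' @param bands data frame with `name`, `lo`, `hi` columns
#'   (default [default_bands()]).
#' @param kind `"de"` or `"psd"`.
#' @param window_s window length in seconds.
#' @param target_windows optional fixed window count (e.g. 265).
#' @param eps variance floor applied before the logarithm.
#' @return A [band_tensor()].
#' @export
extract_features <- function(recordings, bands = default_bands(),
                             kind = c("de", "psd"), window_s = 1,
                             target_windows = NULL, eps = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(length(recordings) >= 1)
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) stop("recordings have mixed sampling rates")
  chans <- recordings[[1]]$channel_names
  same <- vapply(recordings, function(r) identical(r$channel_names, chans),
                 logical(1))
  if (!all(same)) stop("recordings have mixed channel sets")
  per_trial <- lapply(recordings, function(rec) {
    lapply(seq_len(nrow(bands)), function(b)
      band_variance(rec, bands$lo[b], bands$hi[b], window_s))
  })
  nwin <- vapply(per_trial, function(tr) ncol(tr[[1]]), integer(1))
  D <- min(nwin)
  N <- length(recordings); C <- length(chans); B <- nrow(bands)
  vals <- array(0, c(N, C, B, D))
  for (n in seq_len(N)) for (b in seq_len(B))
    vals[n, , b, ] <- per_trial[[n]][[b]][, seq_len(D)]
  if (kind == "de") vals <- differential_entropy(pmax(vals, eps))
  x <- band_tensor(vals, chans, bands$name,
                   vapply(recordings, function(r) r$subject_id, character(1)),
                   vapply(recordings, function(r) as.character(r$label),
                          character(1)),
                   feature_kind = kind)
  if (!is.null(target_windows)) x <- pad_windows(x, target_windows)
  x
}
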