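# Shared fixtures: everything is generated in code at test time.

# A small random electrode layout (reproducible).
tiny_layout <- function(C = 4L, seed = 11L) {
  set.seed(seed)
  electrode_layout(paste0("E", seq_len(C)),
                   matrix(rnorm(3L * C), C, 3L))
}

# A small model configuration over the tiny layout.
tiny_config <- function(C = 4L, D = 6L, bands = c("theta", "alpha"),
                        h1 = 5L, conv_out = c(3L, 4L, 2L), ...) {
  model_config(channels = paste0("E", seq_len(C)), bands = bands, D = D,
               h1 = h1, conv_out = conv_out, layout = tiny_layout(C), ...)
}

# A random band tensor with balanced labels over a few subjects.
tiny_tensor <- function(n_subjects = 2L, trials_per_class = 2L, C = 4L,
                        bands = c("theta", "alpha"), D = 6L, seed = 5L) {
  set.seed(seed)
  per <- 3L * trials_per_class
  N <- n_subjects * per
  band_tensor(array(rnorm(N * C * length(bands) * D),
                    c(N, C, length(bands), D)),
              paste0("E", seq_len(C)), bands,
              rep(sprintf("S%02d", seq_len(n_subjects)), each = per),
              rep(rep(c("negative", "neutral", "positive"),
                      each = trials_per_class), n_subjects),
              "de")
}

# White-noise recording helper.
noise_recording <- function(C = 2L, fs = 200, secs = 10, sd = 1,
                            subject = "S01", trial = "T01", label = 0,
                            seed = 1L) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(C * fs * secs, 0, sd), C),
                fs, paste0("CH", seq_len(C)), subject, trial, label)
}

# Bind two (trial x channel x band x window) arrays along the trial axis.
abind_trials <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  out <- array(0, c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# Central finite difference of `fn` at scalar slot `i` of the vector `x0`.
central_fd <- function(fn, x0, i, h = 1e-5) {
  xp <- x0; xp[i] <- xp[i] + h
  xm <- x0; xm[i] <- xm[i] - h
  (fn(xp) - fn(xm)) / (2 * h)
}
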