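#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's trials are the test set, all other
#' subjects form the training set. Fold order follows the sorted unique
#' subject ids, so splits are deterministic.
#'
#' @param subject_ids character vector (one entry per trial, or the unique
#'   subject ids).
#' @return List of folds, each a list with `train_subjects` and
#'   `test_subject`.
#' @export
loso_folds <- function(subject_ids) {
  subjects <- sort(unique(as.character(subject_ids)))
  if (length(subjects) < 2) stop("need at least 2 distinct subjects")
  lapply(subjects, function(s)
    list(train_subjects = setdiff(subjects, s), test_subject = s))
}

confusion_counts <- function(truth, pred) {
  truth <- factor(as.character(truth), levels = emotion_levels)
  pred <- factor(as.character(pred), levels = emotion_levels)
  m <- table(truth = truth, pred = pred)
  matrix(as.integer(m), 3, 3, dimnames = dimnames(m))
}

#' Train and evaluate one cross-validation fold
#'
#' Fits the model on the training tensor, records test accuracy after every
#' epoch, and reports the fold accuracy as the mean test accuracy over the
#' last `metric_window` epochs. The confusion matrix is taken at the final
#' epoch.
#'
#' @param train,test [band_tensor()] objects from disjoint subject sets.
#' @param config optional [model_config()]; derived from `train` if `NULL`.
#' @param metric_window number of trailing epochs averaged into the fold
#'   accuracy.
#' @param keep_model retain the fitted model in the result.
#' @param ... passed to [sgcsrm()] (`epochs`, `batch_size`, `lr0`,
#'   `lr_decay`, `seed`, ...).
#' @return An object of class `sgcsrm_fold` with `held_out_subject`,
#'   `per_epoch_test_accuracy`, `fold_accuracy`, `confusion_counts`.
#' @export
train_fold <- function(train, test, config = NULL, metric_window = 10L,
                       keep_model = FALSE, ...) {
  overlap <- intersect(unique(train$subject_ids), unique(test$subject_ids))
  if (length(overlap))
    stop("subject leakage: ", paste(overlap, collapse = ", "),
         " present in both train and test")
  fit <- sgcsrm(train, config = config, eval_data = test, ...)
  acc <- fit$history$eval_accuracy
  if (length(acc) < metric_window)
    stop("fewer epochs than metric_window")
  pred <- predict(fit, test)
  res <- list(held_out_subject = paste(sort(unique(test$subject_ids)),
                                       collapse = "+"),
              per_epoch_test_accuracy = acc,
              fold_accuracy = mean(utils::tail(acc, metric_window)),
              confusion_counts = confusion_counts(test$labels, pred),
              n_test = dim(test$values)[1])
  if (keep_model) res$model <- fit
  structure(res, class = "sgcsrm_fold")
}

#' @export
print.sgcsrm_fold <- function(x, ...) {
  cat(sprintf("<sgcsrm_fold> held-out %s: accuracy %.3f (last-%d-epoch mean)\n",
              x$held_out_subject, x$fold_accuracy,
              min(10L, length(x$per_epoch_test_accuracy))))
  invisible(x)
}

#' Summarise a cross-validation run
#'
#' @param folds list of fold results from [train_fold()].
#' @return An object of class `sgcsrm_run`: `acc_mean`, `acc_std`
#'   (population SD over folds), `fold_accuracies`, `confusion_percent`
#'   (row-normalised aggregate confusion, percent), `confusion_counts`,
#'   and `folds`.
#' @export
summarize_run <- function(folds) {
  stopifnot(length(folds) >= 1)
  acc <- vapply(folds, `[[`, numeric(1), "fold_accuracy")
  counts <- Reduce(`+`, lapply(folds, `[[`, "confusion_counts"))
  rs <- rowSums(counts)
  pct <- 100 * counts / ifelse(rs > 0, rs, 1)
  structure(list(
    acc_mean = mean(acc),
    acc_std = sqrt(mean((acc - mean(acc))^2)),
    fold_accuracies = acc,
    held_out = vapply(folds, `[[`, character(1), "held_out_subject"),
    confusion_counts = counts,
    confusion_percent = pct,
    folds = folds
  ), class = "sgcsrm_run")
}

#' @export
print.sgcsrm_run <- function(x, ...) {
  cat(sprintf("<sgcsrm_run> %d folds: ACC %.2f%% +/- %.2f%%\n",
              length(x$fold_accuracies), 100 * x$acc_mean, 100 * x$acc_std))
  cat("row-normalised confusion (%):\n")
  print(round(x$confusion_percent, 1))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' Normalises features within each subject (once, before splitting — each
#' subject is standardised from its own trials only, so nothing leaks
#' across the train/test boundary), then trains one model per held-out
#' subject and aggregates fold accuracies.
#'
#' @param x a [band_tensor()] holding all subjects.
#' @param config optional [model_config()] shared by all folds.
#' @param normalize apply [normalize_subjects()] first.
#' @param metric_window trailing epochs averaged per fold.
#' @param seed base seed; fold k trains with `seed + k - 1`.
#' @param verbose print fold progress.
#' @param ... passed to [sgcsrm()].
#' @return An `sgcsrm_run` from [summarize_run()].
#' @export
loso_cv <- function(x, config = NULL, normalize = TRUE,
                    metric_window = 10L, seed = 1L, verbose = FALSE, ...) {
  stopifnot(inherits(x, "band_tensor"))
  if (normalize) x <- normalize_subjects(x)
  folds <- loso_folds(x$subject_ids)
  results <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    tr <- subset_trials(x, x$subject_ids %in% f$train_subjects)
    te <- subset_trials(x, x$subject_ids == f$test_subject)
    results[[k]] <- train_fold(tr, te, config = config,
                               metric_window = metric_window,
                               seed = seed + k - 1L, ...)
    if (verbose)
      message(sprintf("fold %d/%d (held-out %s): %.3f", k, length(folds),
                      f$test_subject, results[[k]]$fold_accuracy))
  }
  summarize_run(results)
}

#' Ablation runner
#'
#' Re-runs leave-one-subject-out cross-validation under model switches:
#' `"-global"` removes the global left-right connections, `"-SRM"` removes
#' the style recalibration gates, `"-global-SRM"` removes both, and
#' `"freeze_adjacency"` keeps the geometric graph fixed. The base
#' configuration is always included under `"base"`; all runs share data,
#' folds and seeds.
#'
#' @param x a [band_tensor()].
#' @param config base [model_config()]; derived from `x` if `NULL`.
#' @param switches character vector of ablation switches.
#' @param ... passed to [loso_cv()].
#' @return Named list of `sgcsrm_run` summaries (one per configuration).
#' @export
ablate <- function(x, config = NULL,
                   switches = c("-global", "-SRM", "-global-SRM"), ...) {
  known <- c("-global", "-SRM", "-global-SRM", "freeze_adjacency")
  bad <- setdiff(switches, known)
  if (length(bad)) stop("unknown ablation switch: ", paste(bad, collapse = ", "))
  if (is.null(config))
    config <- model_config(channels = x$channel_names, bands = x$band_names,
                           D = dim(x$values)[4])
  variants <- c(list(base = config), lapply(stats::setNames(switches, switches),
    function(sw) {
      cfg <- config
      if (sw %in% c("-global", "-global-SRM")) cfg$use_global <- FALSE
      if (sw %in% c("-SRM", "-global-SRM")) cfg$use_srm <- FALSE
      if (sw == "freeze_adjacency") cfg$freeze_adjacency <- TRUE
      cfg
    }))
  lapply(variants, function(cfg) loso_cv(x, config = cfg, ...))
}

# Collapse the band axis into the window axis (direct multi-band input: one
# shared encoder sees the concatenated band features, no fusion layer).
concat_bands <- function(x) {
  d <- dim(x$values)
  arr <- aperm(x$values, c(1, 2, 4, 3))
  dim(arr) <- c(d[1], d[2], 1L, d[4] * d[3])
  band_tensor(arr, x$channel_names, "concat", x$subject_ids, x$labels,
              x$feature_kind)
}

#' Band configuration sweep
#'
#' Runs leave-one-subject-out cross-validation over band configurations:
#' one single-band model per band (`single:<band>`), direct multi-band
#' models whose concatenated band features feed one shared encoder
#' (`direct:four`, `direct:all`), and parallel per-band encoders fused by
#' learnable softmax weights (`fusion:four`, `fusion:all`). The default
#' mode list over a five-band tensor yields nine configurations.
#'
#' @param x a [band_tensor()] containing all requested bands.
#' @param modes character vector of mode strings.
#' @param layout,conv_out,h1,a forwarded to [model_config()] when building
#'   the per-mode configuration (a shared `config` is not meaningful here
#'   because the band axis changes between modes).
#' @param ... passed to [loso_cv()].
#' @return Named list of `sgcsrm_run` summaries keyed by mode.
#' @export
band_sweep <- function(x, modes = NULL, layout = NULL, conv_out = NULL,
                       h1 = 128L, a = 0.01, ...) {
  if (is.null(modes))
    modes <- c(paste0("single:", x$band_names),
               "direct:four", "direct:all", "fusion:four", "fusion:all")
  run_mode <- function(mode) {
    parts <- strsplit(mode, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("mode must look like single:<band>, direct:<set> or fusion:<set>")
    kind <- parts[1]; which <- parts[2]
    xt <- switch(kind,
      single = select_bands(x, which),
      direct = concat_bands(select_bands(x, which)),
      fusion = select_bands(x, which),
      stop("unknown band-sweep mode kind: ", kind))
    cfg <- model_config(channels = xt$channel_names, bands = xt$band_names,
                        D = dim(xt$values)[4], layout = layout,
                        conv_out = conv_out, h1 = h1, a = a)
    loso_cv(xt, config = cfg, ...)
  }
  lapply(stats::setNames(modes, modes), run_mode)
}
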