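# Adam optimiser over nested parameter trees ---------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_update <- function(params, grads, m, v, t, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, m1, v1) {
    m1 <- beta1 * m1 + (1 - beta1) * g
    v1 <- beta2 * v1 + (1 - beta2) * g^2
    mhat <- m1 / (1 - beta1^t)
    vhat <- v1 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m1, v = v1)
  }
  rec <- function(p, g, m1, v1) {
    if (is.list(p)) {
      # gradient trees may order elements differently or omit entries
      # (e.g. SRM parameters when the gates are ablated): match by name
      keys <- names(p)
      res <- lapply(seq_along(p), function(i) {
        gi <- if (!is.null(keys) && !is.null(names(g))) g[[keys[i]]]
              else g[[i]]
        if (is.null(gi)) list(p = p[[i]], m = m1[[i]], v = v1[[i]])
        else rec(p[[i]], gi, m1[[i]], v1[[i]])
      })
      out <- list(p = lapply(res, `[[`, "p"),
                  m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v"))
      if (!is.null(keys)) {
        names(out$p) <- keys; names(out$m) <- keys; names(out$v) <- keys
      }
      out
    } else step(p, g, m1, v1)
  }
  rec(params, grads, m, v)
}

#' Learning-rate schedule
#'
#' Exponential decay: `lr0 * decay^epoch`, with `epoch` counted from 0.
#'
#' @param lr0 initial learning rate.
#' @param decay per-epoch decay factor in (0, 1].
#' @param epoch 0-based epoch index (vectorised).
#' @return Learning rate(s).
#' @export
lr_schedule <- function(lr0, decay, epoch) lr0 * decay^epoch

check_tensor_matches <- function(x, cfg) {
  stopifnot(inherits(x, "band_tensor"))
  if (!identical(x$channel_names, cfg$channels))
    stop("tensor channels do not match the model configuration")
  if (!identical(x$band_names, cfg$bands))
    stop("tensor bands do not match the model configuration")
  if (dim(x$values)[4] != cfg$D)
    stop("tensor window count does not match the model configuration")
  invisible(TRUE)
}

model_accuracy <- function(params, cfg, state, x, y) {
  fwd <- model_forward(params, cfg, x, state, train = FALSE)
  mean(max.col(fwd$probs, ties.method = "first") == y)
}

#' Fit the multi-band graph convolution / style recalibration classifier
#'
#' Trains the full model — per-band simplifying graph convolutions over a
#' learnable electrode adjacency, style-recalibrated convolution stacks,
#' softmax band fusion, and a linear head — by Adam on the composite loss
#' (cross-entropy plus `a` times the L1 norm of the adjacency matrices).
#' The adjacency matrices are ordinary trainable parameters, so the
#' electrode graph is refined by backpropagation unless
#' `freeze_adjacency` is set in the configuration.
#'
#' @param x a [band_tensor()] of training features (already subject
#'   normalised; channels/bands must match `config`).
#' @param config an `sgcsrm_config` from [model_config()]; defaults to a
#'   configuration derived from `x`.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size (the last short batch is kept).
#' @param lr0 initial Adam learning rate.
#' @param lr_decay exponential decay factor applied per epoch.
#' @param seed integer seed controlling initialisation and batch order.
#' @param eval_data optional [band_tensor()] scored after every epoch
#'   (e.g. the held-out subject of a cross-validation fold).
#' @param verbose print one line per epoch.
#' @return An object of class `sgcsrm` with elements `params`, `state`,
#'   `config`, `history` (per-epoch loss components and accuracies),
#'   `n_params`, and the training settings.
#' @export
sgcsrm <- function(x, config = NULL, epochs = 50L, batch_size = 64L,
                   lr0 = 0.001, lr_decay = 0.96, seed = 1L,
                   eval_data = NULL, verbose = FALSE) {
  if (is.null(config))
    config <- model_config(channels = x$channel_names, bands = x$band_names,
                           D = dim(x$values)[4])
  check_tensor_matches(x, config)
  if (!is.null(eval_data)) check_tensor_matches(eval_data, config)
  set.seed(seed)
  params <- init_params(config)
  state <- init_state(config)
  m <- tree_zero(params)
  v <- tree_zero(params)
  y <- as.integer(x$labels)
  N <- dim(x$values)[1]
  t_step <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     cross_entropy = numeric(), l1 = numeric(),
                     train_accuracy = numeric(), eval_accuracy = numeric())
  for (epoch in seq_len(epochs) - 1L) {
    lr <- lr_schedule(lr0, lr_decay, epoch)
    ord <- sample.int(N)
    starts <- seq(1, N, by = batch_size)
    ep_loss <- ep_ce <- ep_l1 <- 0; ep_n <- 0L; ep_correct <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, N)]
      xb <- x$values[idx, , , , drop = FALSE]
      yb <- y[idx]
      fwd <- model_forward(params, config, xb, state, train = TRUE)
      state <- fwd$state
      loss <- composite_loss(fwd$probs, x$labels[idx],
                             lapply(params$bands, `[[`, "A"), config$a)
      grads <- model_backward(params, config, fwd, yb)
      t_step <- t_step + 1L
      upd <- adam_update(params, grads, m, v, t_step, lr)
      params <- upd$p; m <- upd$m; v <- upd$v
      nb <- length(idx)
      ep_loss <- ep_loss + loss$total * nb
      ep_ce <- ep_ce + loss$cross_entropy * nb
      ep_l1 <- ep_l1 + loss$l1 * nb
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") == yb)
      ep_n <- ep_n + nb
    }
    eval_acc <- if (!is.null(eval_data))
      model_accuracy(params, config, state, eval_data$values,
                     as.integer(eval_data$labels)) else NA_real_
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, loss = ep_loss / ep_n,
      cross_entropy = ep_ce / ep_n, l1 = ep_l1 / ep_n,
      train_accuracy = ep_correct / ep_n, eval_accuracy = eval_acc))
    if (verbose)
      message(sprintf(
        "epoch %2d lr %.5f loss %.4f ce %.4f l1 %.1f acc %.3f eval %.3f",
        epoch, lr, ep_loss / ep_n, ep_ce / ep_n, ep_l1 / ep_n,
        ep_correct / ep_n, eval_acc))
  }
  structure(list(params = params, state = state, config = config,
                 history = hist, n_params = param_count(params),
                 epochs = epochs, batch_size = batch_size, lr0 = lr0,
                 lr_decay = lr_decay, seed = seed),
            class = "sgcsrm")
}

#' @export
print.sgcsrm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sgcsrm> %d channels, bands %s, %d trainable parameters\n",
              length(cfg$channels), paste(cfg$bands, collapse = "/"),
              x$n_params))
  W <- fusion_weights(x$params$fusion_logits)
  cat("  fusion weights:",
      paste(sprintf("%s=%.3f", cfg$bands, W), collapse = " "), "\n")
  n <- nrow(x$history)
  cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.3f\n",
              n, x$history$loss[n], x$history$train_accuracy[n]))
  invisible(x)
}

#' @export
summary.sgcsrm <- function(object, ...) {
  print(object)
  cat("\nper-band adjacency L1 norms (initial graph is geometric):\n")
  for (bn in object$config$bands)
    cat(sprintf("  %-6s %.2f\n", bn, sum(abs(object$params$bands[[bn]]$A))))
  invisible(object)
}

#' Predict emotion classes or probabilities
#'
#' @param object a fitted [sgcsrm()] model.
#' @param newdata a [band_tensor()] matching the model configuration.
#' @param type `"class"` for labels, `"prob"` for the N x 3 probability
#'   matrix.
#' @param ... unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.sgcsrm <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  check_tensor_matches(newdata, object$config)
  fwd <- model_forward(object$params, object$config, newdata$values,
                       object$state, train = FALSE)
  if (type == "prob") {
    colnames(fwd$probs) <- emotion_levels
    return(fwd$probs)
  }
  factor(emotion_levels[max.col(fwd$probs, ties.method = "first")],
         levels = emotion_levels)
}

#' Extract the learned graph and fusion weights
#'
#' @param object a fitted [sgcsrm()] model.
#' @param ... unused.
#' @return List with `adjacency` (one named C x C matrix per band) and
#'   `fusion_weights` (simplex weights over bands).
#' @export
coef.sgcsrm <- function(object, ...) {
  adj <- lapply(object$params$bands, `[[`, "A")
  for (b in seq_along(adj))
    dimnames(adj[[b]]) <- list(object$config$channels,
                               object$config$channels)
  W <- fusion_weights(object$params$fusion_logits)
  names(W) <- object$config$bands
  list(adjacency = adj, fusion_weights = W)
}

#' Plot a learned adjacency matrix
#'
#' @param x a fitted [sgcsrm()] model.
#' @param band band name (default: first band).
#' @param ... passed to [graphics::image()].
#' @export
plot.sgcsrm <- function(x, band = x$config$bands[1], ...) {
  A <- coef(x)$adjacency[[band]]
  C <- nrow(A)
  graphics::image(seq_len(C), seq_len(C), t(A[C:1, ]), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("learned adjacency (%s band)", band), ...)
  graphics::axis(1, at = seq_len(C), labels = colnames(A), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(C), labels = rev(rownames(A)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
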