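#' Model configuration
#'
#' Architecture and regularisation settings for the multi-band graph
#' convolution / style recalibration classifier.
#'
#' Each band gets an independent branch: a two-step simplifying graph
#' convolution (widths `D -> h1 -> 64`) over a learnable adjacency matrix,
#' a reshape of the 64 node features to an 8 x 8 grid, and a three-layer
#' convolution stack with style recalibration gates after the first two
#' convolutions. Band outputs are fused with learnable softmax weights and
#' classified by a linear head.
#'
#' @param channels character vector of channel names (defines C and the
#'   electrode geometry), or `"all"` / `"seed12"` presets resolved against
#'   the bundled layout.
#' @param bands character vector of band names, or presets `"all"` /
#'   `"four"`.
#' @param D window-axis length of the input features.
#' @param h1 hidden width between the two graph convolution steps.
#' @param conv_out three convolution channel counts; defaults depend on the
#'   channel count (62: 128/256/8, 12: 32/64/8, otherwise 16/32/8).
#' @param a L1 regularisation strength on the adjacency matrices.
#' @param use_srm enable the style recalibration gates (ablation `-SRM`
#'   when `FALSE`).
#' @param use_global initialise symmetric left-right global connections
#'   (ablation `-global` when `FALSE`).
#' @param freeze_adjacency keep the adjacency matrices fixed at their
#'   geometric initialisation (the "NA" mode of the L1 sweep).
#' @param delta inverse-square distance scale of the initial adjacency.
#' @param global_value initial weight of global connections.
#' @param layout an [electrode_layout()]; defaults to the bundled layout
#'   restricted to `channels`.
#' @return An object of class `sgcsrm_config`.
#' @export
model_config <- function(channels = "seed12", bands = "four", D = 265L,
                         h1 = 128L, conv_out = NULL, a = 0.01,
                         use_srm = TRUE, use_global = TRUE,
                         freeze_adjacency = FALSE, delta = 5,
                         global_value = -1, layout = NULL) {
  if (length(channels) == 1L && channels %in% c("all", "seed12")) {
    channels <- if (channels == "seed12") seed12_channels()
                else seed_layout("all")$names
  }
  if (length(bands) == 1L && bands %in% c("all", "four")) {
    bands <- if (bands == "four") c("theta", "alpha", "beta", "gamma")
             else c("delta", "theta", "alpha", "beta", "gamma")
  }
  C <- length(channels)
  if (is.null(conv_out)) {
    conv_out <- if (C == 62) c(128L, 256L, 8L)
                else if (C == 12) c(32L, 64L, 8L)
                else c(16L, 32L, 8L)
  }
  stopifnot(length(conv_out) == 3, a >= 0, length(bands) >= 1, D >= 1,
            h1 >= 1)
  if (is.null(layout)) layout <- seed_layout(channels)
  if (!identical(layout$names, channels))
    stop("layout electrode names must match `channels`")
  structure(list(channels = channels, bands = bands, D = as.integer(D),
                 h1 = as.integer(h1), conv_out = as.integer(conv_out),
                 a = a, use_srm = isTRUE(use_srm),
                 use_global = isTRUE(use_global),
                 freeze_adjacency = isTRUE(freeze_adjacency),
                 delta = delta, global_value = global_value,
                 layout = layout),
            class = "sgcsrm_config")
}

#' @export
print.sgcsrm_config <- function(x, ...) {
  cat(sprintf("<sgcsrm_config> C=%d channels, bands: %s, D=%d, h1=%d, conv %s\n",
              length(x$channels), paste(x$bands, collapse = "/"), x$D, x$h1,
              paste(x$conv_out, collapse = "/")))
  cat(sprintf("  a=%g, srm=%s, global=%s, freeze_adjacency=%s\n", x$a,
              x$use_srm, x$use_global, x$freeze_adjacency))
  invisible(x)
}

unif_init <- function(n, fan_in) runif(n, -1, 1) / sqrt(fan_in)

init_conv <- function(cin, cout) {
  fan <- 4L * cin
  list(W = matrix(unif_init(fan * cout, fan), fan, cout),
       b = unif_init(cout, fan))
}

init_srm <- function(ch) {
  list(w = matrix(unif_init(2L * ch, 2), ch, 2),
       gamma = rep(1, ch), beta = rep(0, ch))
}

srm_state0 <- function(ch) list(rm = rep(0, ch), rv = rep(1, ch))

# Trainable parameters (nested lists of numeric arrays) and non-trainable
# batch-norm state. The caller is responsible for seeding the RNG.
init_params <- function(cfg) {
  C <- length(cfg$channels)
  A0 <- init_adjacency(electrode_distances(cfg$layout), cfg$delta)
  if (cfg$use_global)
    A0 <- apply_global_connections(A0, value = cfg$global_value)
  attr(A0, "applied_pairs") <- NULL
  co <- cfg$conv_out
  bands <- lapply(cfg$bands, function(bn) {
    list(A = A0,
         theta1 = matrix(unif_init(cfg$D * cfg$h1, cfg$D), cfg$D, cfg$h1),
         theta2 = matrix(unif_init(cfg$h1 * 64L, cfg$h1), cfg$h1, 64L),
         conv1 = init_conv(C, co[1]), srm1 = init_srm(co[1]),
         conv2 = init_conv(co[1], co[2]), srm2 = init_srm(co[2]),
         conv3 = init_conv(co[2], co[3]))
  })
  names(bands) <- cfg$bands
  list(bands = bands,
       fusion_logits = rep(0, length(cfg$bands)),
       head = list(W = matrix(unif_init(co[3] * 9L * 3L, co[3] * 9L),
                              co[3] * 9L, 3L),
                   b = rep(0, 3)))
}

init_state <- function(cfg) {
  st <- lapply(cfg$bands, function(bn)
    list(srm1 = srm_state0(cfg$conv_out[1]),
         srm2 = srm_state0(cfg$conv_out[2])))
  names(st) <- cfg$bands
  list(bands = st)
}

#' Fold node embeddings into an 8 x 8 grid
#'
#' Row-major reshape of each 64-wide node feature vector: grid element
#' (r, c) (1-based) holds embedding entry `8 * (r - 1) + c`. EEG channels
#' become the convolution input channels.
#'
#' @param emb numeric array of shape (trials, channels, 64).
#' @return Array of shape (trials, channels, 8, 8).
#' @export
reshape_to_grid <- function(emb) {
  d <- dim(emb)
  if (length(d) != 3 || d[3] != 64) stop("node-feature width must be 64")
  aperm(array(emb, c(d[1], d[2], 8, 8)), c(1, 2, 4, 3))
}

grid_backward <- function(dgrid) {
  d <- dim(dgrid)
  array(aperm(dgrid, c(1, 2, 4, 3)), c(d[1], d[2], 64))
}

fusion_weights <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Forward pass of one band branch; x_b is (N, C, D).
band_forward <- function(x_b, bp, bst, cfg, train) {
  S <- normalize_adjacency(bp$A)
  sgc <- sgc_forward(x_b, S, bp$theta1, bp$theta2)
  grid <- reshape_to_grid(sgc$out)
  c1 <- conv2d_forward(grid, bp$conv1$W, bp$conv1$b)
  h <- c1$out
  if (cfg$use_srm) {
    s1 <- srm_forward(h, bp$srm1$w, bp$srm1$gamma, bp$srm1$beta, bst$srm1,
                      train = train)
    h <- s1$out; bst$srm1 <- s1$state
  } else s1 <- NULL
  c2 <- conv2d_forward(h, bp$conv2$W, bp$conv2$b)
  h <- c2$out
  if (cfg$use_srm) {
    s2 <- srm_forward(h, bp$srm2$w, bp$srm2$gamma, bp$srm2$beta, bst$srm2,
                      train = train)
    h <- s2$out; bst$srm2 <- s2$state
  } else s2 <- NULL
  c3 <- conv2d_forward(h, bp$conv3$W, bp$conv3$b, pad = c(1L, 1L))
  mp <- maxpool2_forward(c3$out)
  d <- dim(mp$out)
  vec <- matrix(mp$out, nrow = d[1])   # (N, out3 * 3 * 3)
  list(vec = vec, state = bst,
       cache = list(sgc = sgc, c1 = c1, s1 = s1, c2 = c2, s2 = s2, c3 = c3,
                    mp = mp, pooled_dim = d))
}

band_backward <- function(dvec, cache, bp, cfg) {
  dpool <- array(dvec, cache$pooled_dim)
  dx <- maxpool2_backward(dpool, cache$mp$cache)
  c3b <- conv2d_backward(dx, cache$c3$cache)
  g <- list(conv3 = list(W = c3b$dW, b = c3b$db))
  dx <- c3b$dx
  if (cfg$use_srm) {
    s2b <- srm_backward(dx, cache$s2$cache)
    g$srm2 <- list(w = s2b$dw, gamma = s2b$dgamma, beta = s2b$dbeta)
    dx <- s2b$dx
  }
  c2b <- conv2d_backward(dx, cache$c2$cache)
  g$conv2 <- list(W = c2b$dW, b = c2b$db)
  dx <- c2b$dx
  if (cfg$use_srm) {
    s1b <- srm_backward(dx, cache$s1$cache)
    g$srm1 <- list(w = s1b$dw, gamma = s1b$dgamma, beta = s1b$dbeta)
    dx <- s1b$dx
  }
  c1b <- conv2d_backward(dx, cache$c1$cache)
  g$conv1 <- list(W = c1b$dW, b = c1b$db)
  demb <- grid_backward(c1b$dx)
  sg <- sgc_backward(demb, cache$sgc$cache)
  g$theta1 <- sg$dtheta1
  g$theta2 <- sg$dtheta2
  g$A <- normalize_adjacency_backward(sg$dS, bp$A)
  g
}

band_slice <- function(x, b) {
  xb <- x[, , b, , drop = FALSE]
  dim(xb) <- dim(xb)[c(1, 2, 4)]
  xb
}

# Full forward: x is (N, C, B, D) ordered as cfg$bands along the band axis.
model_forward <- function(params, cfg, x, state, train = FALSE) {
  B <- length(cfg$bands)
  W <- fusion_weights(params$fusion_logits)
  vecs <- vector("list", B)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    bf <- band_forward(band_slice(x, b), params$bands[[b]], state$bands[[b]],
                       cfg, train)
    vecs[[b]] <- bf$vec
    caches[[b]] <- bf$cache
    state$bands[[b]] <- bf$state
  }
  fused <- Reduce(`+`, Map(function(w, v) w * v, as.list(W), vecs))
  logits <- sweep(fused %*% params$head$W, 2, params$head$b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, state = state,
       cache = list(vecs = vecs, band_caches = caches, fused = fused,
                    W = W))
}

# y: integer class labels in 1..3. Returns gradients mirroring `params`.
model_backward <- function(params, cfg, fwd, y) {
  probs <- fwd$probs
  N <- nrow(probs)
  onehot <- matrix(0, N, 3)
  onehot[cbind(seq_len(N), y)] <- 1
  dlogits <- (probs - onehot) / N
  cache <- fwd$cache
  g <- list(head = list(W = crossprod(cache$fused, dlogits),
                        b = colSums(dlogits)))
  dfused <- tcrossprod(dlogits, params$head$W)
  B <- length(cfg$bands)
  W <- cache$W
  dW <- vapply(seq_len(B),
               function(b) sum(dfused * cache$vecs[[b]]), numeric(1))
  g$fusion_logits <- W * (dW - sum(W * dW))   # softmax Jacobian
  g$bands <- vector("list", B)
  names(g$bands) <- cfg$bands
  for (b in seq_len(B)) {
    gb <- band_backward(W[b] * dfused, cache$band_caches[[b]],
                        params$bands[[b]], cfg)
    # L1 penalty on the adjacency
    if (!cfg$freeze_adjacency) {
      gb$A <- gb$A + cfg$a * sign(params$bands[[b]]$A)
    } else {
      gb$A <- array(0, dim(gb$A))
    }
    g$bands[[b]] <- gb
  }
  g
}

#' Composite training loss
#'
#' Cross-entropy of the predicted class probabilities plus an L1 penalty on
#' the per-band adjacency matrices:
#' `total = cross_entropy + a * sum_b ||A_b||_1`.
#'
#' @param probs N x 3 matrix of predicted class probabilities.
#' @param labels class labels (factor/character/SEED numeric, length N).
#' @param A_list list of adjacency matrices, one per band.
#' @param a L1 strength.
#' @return List with `total`, `cross_entropy`, `l1`.
#' @export
composite_loss <- function(probs, labels, A_list, a) {
  y <- as.integer(as_emotion_label(labels))
  stopifnot(nrow(probs) == length(y), a >= 0)
  ce <- -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-300)))
  l1 <- sum(vapply(A_list, function(A) sum(abs(A)), numeric(1)))
  list(total = ce + a * l1, cross_entropy = ce, l1 = l1)
}

# Number of trainable scalars in a parameter tree.
param_count <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}
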