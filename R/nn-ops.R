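# Low-level differentiable operations. Every op comes as a forward that
# returns (out, cache) and a matching backward that consumes upstream
# gradients plus the cache. Arrays are batch-first: (N, channels, H, W).
# Convolutions use an im2col patch matrix so the heavy lifting is a single
# BLAS matrix product; backward scatters through col2im.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- im2col convolution, kernel 2x2, stride 1, optional right/bottom pad ----

# weights are stored as a (4 * Cin) x Cout matrix whose row blocks follow the
# kernel offsets (0,0),(1,0),(0,1),(1,1); `conv_offsets` fixes that order.
conv_offsets <- matrix(c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L), ncol = 2, byrow = TRUE)

im2col_k2 <- function(x, pad = c(0L, 0L)) {
  d <- dim(x)  # N, Cin, H, W
  oh <- d[3] + pad[1] - 1L; ow <- d[4] + pad[2] - 1L
  cols <- im2col_k2_cpp(x, as.integer(pad))
  list(cols = cols, n = d[1], cin = d[2], oh = oh, ow = ow,
       pad = as.integer(pad), in_dim = c(d[3], d[4]))
}

conv2d_forward <- function(x, W, b, pad = c(0L, 0L)) {
  ic <- im2col_k2(x, pad)
  ymat <- ic$cols %*% W
  ymat <- sweep(ymat, 2, b, "+")
  cout <- ncol(W)
  out <- aperm(array(ymat, c(ic$n, ic$oh, ic$ow, cout)), c(1, 4, 2, 3))
  list(out = out, cache = list(ic = ic, W = W))
}

conv2d_backward <- function(dout, cache) {
  ic <- cache$ic
  d <- dim(dout)  # N, Cout, OH, OW
  dymat <- matrix(aperm(dout, c(1, 3, 4, 2)), nrow = d[1] * d[3] * d[4])
  dW <- crossprod(ic$cols, dymat)
  db <- colSums(dymat)
  dcols <- tcrossprod(dymat, cache$W)
  dx <- col2im_k2_cpp(dcols, as.integer(c(ic$n, ic$cin, ic$in_dim)), ic$pad)
  list(dx = dx, dW = dW, db = db)
}

# ---- 2x2 max pooling, stride 2 ----

maxpool2_forward <- function(x) {
  d <- dim(x)
  oh <- d[3] %/% 2L; ow <- d[4] %/% 2L
  cand <- array(0, c(d[1], d[2], oh, ow, 4))
  for (o in seq_len(4)) {
    di <- conv_offsets[o, 1]; dj <- conv_offsets[o, 2]
    cand[, , , , o] <- x[, , seq(1, 2 * oh, 2) + di, seq(1, 2 * ow, 2) + dj,
                         drop = FALSE]
  }
  m <- matrix(cand, ncol = 4)
  wm <- max.col(m, ties.method = "first")
  out <- array(m[cbind(seq_len(nrow(m)), wm)], c(d[1], d[2], oh, ow))
  which_max <- array(wm, c(d[1], d[2], oh, ow))
  list(out = out, cache = list(which_max = which_max, in_dim = d))
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$in_dim
  oh <- d[3] %/% 2L; ow <- d[4] %/% 2L
  dx <- array(0, d)
  wm <- cache$which_max
  for (o in seq_len(4)) {
    di <- conv_offsets[o, 1]; dj <- conv_offsets[o, 2]
    sel <- (wm == o) * dout
    dx[, , seq(1, 2 * oh, 2) + di, seq(1, 2 * ow, 2) + dj] <-
      dx[, , seq(1, 2 * oh, 2) + di, seq(1, 2 * ow, 2) + dj] + sel
  }
  dx
}

# ---- batch normalisation over conv channels (input: N x Ch matrix) ----

bn_forward <- function(z, gamma, beta, state, train = TRUE,
                       momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    nb <- nrow(z)
    unbias <- if (nb > 1) nb / (nb - 1) else 1
    state$rv <- (1 - momentum) * state$rv + momentum * v * unbias
  } else {
    mu <- state$rm
    v <- state$rv
  }
  istd <- 1 / sqrt(v + eps)
  zhat <- sweep(sweep(z, 2, mu), 2, istd, "*")
  out <- sweep(sweep(zhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out,
       cache = list(zhat = zhat, istd = istd, gamma = gamma, train = train),
       state = state)
}

bn_backward <- function(dout, cache) {
  zhat <- cache$zhat; istd <- cache$istd
  n <- nrow(dout)
  dgamma <- colSums(dout * zhat)
  dbeta <- colSums(dout)
  dzhat <- sweep(dout, 2, cache$gamma, "*")
  if (cache$train) {
    # batch statistics depend on every sample
    dz <- sweep(dzhat - matrix(colMeans(dzhat), n, ncol(dout), byrow = TRUE) -
                  zhat * matrix(colMeans(dzhat * zhat), n, ncol(dout),
                                byrow = TRUE),
                2, istd, "*")
  } else {
    dz <- sweep(dzhat, 2, istd, "*")
  }
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# ---- style recalibration (SRM): style pool -> CFC -> BN -> sigmoid gate ----

srm_style_pool <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])      # rows (n, ch), cols (h, w)
  mu <- rowMeans(m)
  v <- rowMeans(m^2) - mu^2
  sig <- sqrt(pmax(v, 0) + eps)
  list(mu = matrix(mu, d[1], d[2]), sig = matrix(sig, d[1], d[2]),
       m = m, dims = d)
}

srm_forward <- function(x, w, gamma, beta, state, train = TRUE) {
  sp <- srm_style_pool(x)
  z <- sweep(sp$mu, 2, w[, 1], "*") + sweep(sp$sig, 2, w[, 2], "*")
  bn <- bn_forward(z, gamma, beta, state, train = train)
  g <- sigmoid(bn$out)
  out <- array(sp$m * as.vector(g), sp$dims)
  list(out = out, state = bn$state,
       cache = list(sp = sp, z = z, bn_cache = bn$cache, g = g, w = w))
}

srm_backward <- function(dout, cache) {
  sp <- cache$sp; g <- cache$g
  d <- sp$dims
  hw <- d[3] * d[4]
  dm_out <- matrix(dout, nrow = d[1] * d[2])
  # gate path
  dg <- matrix(rowSums(dm_out * sp$m), d[1], d[2])
  dbn <- dg * g * (1 - g)
  bnb <- bn_backward(dbn, cache$bn_cache)
  dz <- bnb$dz
  dw <- cbind(colSums(dz * sp$mu), colSums(dz * sp$sig))
  dmu <- sweep(dz, 2, cache$w[, 1], "*")
  dsig <- sweep(dz, 2, cache$w[, 2], "*")
  # feature path plus style-statistic paths
  dm <- dm_out * as.vector(g)
  dm <- dm + (as.vector(dmu) +
                as.vector(dsig) * (sp$m - as.vector(sp$mu)) /
                  as.vector(sp$sig)) / hw
  list(dx = array(dm, d), dw = dw, dgamma = bnb$dgamma, dbeta = bnb$dbeta)
}

# ---- simplifying graph convolution: out = act(S (S X T1) T2) ----

# X: (N, C, D); S: C x C shared by both propagation steps.
sgc_forward <- function(x, S, theta1, theta2) {
  d <- dim(x)
  N <- d[1]; C <- d[2]
  xm <- matrix(x, nrow = N * C)                 # rows (n, c)
  p <- array(xm %*% theta1, c(N, C, ncol(theta1)))
  pc <- matrix(aperm(p, c(2, 1, 3)), nrow = C)  # rows c, cols (n, h)
  h1c <- S %*% pc
  h1 <- aperm(array(h1c, c(C, N, ncol(theta1))), c(2, 1, 3))
  h1m <- matrix(h1, nrow = N * C)
  q <- array(h1m %*% theta2, c(N, C, ncol(theta2)))
  qc <- matrix(aperm(q, c(2, 1, 3)), nrow = C)
  h2c <- S %*% qc
  h2pre <- aperm(array(h2c, c(C, N, ncol(theta2))), c(2, 1, 3))
  act <- relu_forward(h2pre)
  list(out = act$out,
       cache = list(xm = xm, pc = pc, h1m = h1m, qc = qc, S = S,
                    theta1 = theta1, theta2 = theta2, mask = act$mask,
                    N = N, C = C))
}

sgc_backward <- function(dout, cache) {
  N <- cache$N; C <- cache$C
  h2w <- ncol(cache$theta2); h1w <- ncol(cache$theta1)
  dh2pre <- dout * cache$mask
  dh2c <- matrix(aperm(dh2pre, c(2, 1, 3)), nrow = C)
  dS <- tcrossprod(dh2c, cache$qc)
  dqc <- crossprod(cache$S, dh2c)
  dq <- aperm(array(dqc, c(C, N, h2w)), c(2, 1, 3))
  dqm <- matrix(dq, nrow = N * C)
  dtheta2 <- crossprod(cache$h1m, dqm)
  dh1m <- tcrossprod(dqm, cache$theta2)
  dh1 <- array(dh1m, c(N, C, h1w))
  dh1c <- matrix(aperm(dh1, c(2, 1, 3)), nrow = C)
  dS <- dS + tcrossprod(dh1c, cache$pc)
  dpc <- crossprod(cache$S, dh1c)
  dp <- aperm(array(dpc, c(C, N, h1w)), c(2, 1, 3))
  dtheta1 <- crossprod(cache$xm, matrix(dp, nrow = N * C))
  list(dS = dS, dtheta1 = dtheta1, dtheta2 = dtheta2)
}

# gradient of the normalised operator S(A) with respect to A, where
# S = R (A + I) R, R = diag(1/sqrt(rowSums(|A + I|)))
normalize_adjacency_backward <- function(dS, A) {
  At <- A + diag(nrow(A))
  deg <- rowSums(abs(At))
  r <- 1 / sqrt(deg)
  dAt <- dS * outer(r, r)
  gA <- dS * At
  dr <- as.vector(gA %*% r) + as.vector(crossprod(gA, r))
  ddeg <- dr * (-0.5) * deg^(-1.5)
  dAt <- dAt + ddeg * sign(At)   # row-wise recycling: ddeg[k] scales row k
  dAt
}
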