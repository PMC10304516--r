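# Minimal neural-network primitives (batch-first, base R).
# Forward functions return the output plus the cache needed by the matching
# backward function; backward functions return the input gradient and the
# parameter gradients. All matrices are batch x features.

#' @noRd
init_linear <- function(d_in, d_out) {
  r <- 1 / sqrt(d_in)                      # uniform fan-in scaling
  list(W = matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out),
       b = stats::runif(d_out, -r, r))
}

#' @noRd
linear_fwd <- function(X, W, b) sweep(X %*% W, 2, b, `+`)

#' @noRd
linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

#' @noRd
relu_fwd <- function(Z) pmax(Z, 0)

#' @noRd
relu_bwd <- function(dA, Z) dA * (Z > 0)

#' @noRd
sigmoid <- function(Z) 1 / (1 + exp(-Z))

# Batch normalization over the batch dimension, per feature.
# state carries running mean/var for inference; eps and momentum fixed.
#' @noRd
bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training && n > 1) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu, `-`)
    v <- colMeans(xc^2)                    # biased, as in batch-norm training
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(X, 2, mu, `-`)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(Y = Y, state = state, cache = list(xc = xc, inv = inv, xhat = xhat))
}

#' @noRd
bn_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  xc <- cache$xc; inv <- cache$inv; xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  dvar <- colSums(dxhat * xc) * (-0.5) * inv^3
  dmu <- colSums(dxhat) * (-inv) + dvar * colMeans(-2 * xc)
  dX <- sweep(dxhat, 2, inv, `*`) +
    sweep(xc, 2, dvar * 2 / n, `*`) +
    matrix(dmu / n, n, length(dmu), byrow = TRUE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout: scaling at train time, identity at inference.
#' @noRd
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - p), nrow(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

#' @noRd
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Max pooling, kernel 3, stride 1, no padding: L -> L - 2.
# Ties go to the earliest position.
#' @noRd
maxpool3_fwd <- function(X) {
  L <- ncol(X); L2 <- L - 2L
  A <- X[, 1:L2, drop = FALSE]
  B <- X[, 2:(L2 + 1L), drop = FALSE]
  C <- X[, 3:(L2 + 2L), drop = FALSE]
  M <- pmax(A, B, C)
  s1 <- (A == M); s2 <- (B == M) & !s1; s3 <- (C == M) & !s1 & !s2
  list(Y = M, cache = list(s1 = s1, s2 = s2, s3 = s3, L = L))
}

#' @noRd
maxpool3_bwd <- function(dY, cache) {
  L <- cache$L; L2 <- L - 2L
  dX <- matrix(0, nrow(dY), L)
  dX[, 1:L2] <- dX[, 1:L2] + dY * cache$s1
  dX[, 2:(L2 + 1L)] <- dX[, 2:(L2 + 1L)] + dY * cache$s2
  dX[, 3:(L2 + 2L)] <- dX[, 3:(L2 + 2L)] + dY * cache$s3
  dX
}

#' @noRd
init_conv1d <- function(k, c_in, c_out) {
  r <- 1 / sqrt(k * c_in)
  list(W = array(stats::runif(k * c_in * c_out, -r, r), c(k, c_in, c_out)),
       b = stats::runif(c_out, -r, r))
}

# 1-D convolution (cross-correlation), stride 1, no padding.
# X: n x L x C_in array; W: k x C_in x C_out; returns n x (L-k+1) x C_out.
#' @noRd
conv1d_fwd <- function(X, W, b) {
  n <- dim(X)[1]; L <- dim(X)[2]; c_in <- dim(X)[3]
  k <- dim(W)[1]; c_out <- dim(W)[3]
  Lout <- L - k + 1L
  Y <- array(0, c(n, Lout, c_out))
  for (o in seq_len(c_out)) {
    acc <- matrix(b[o], n, Lout)
    for (c in seq_len(c_in)) {
      Xc <- X[, , c, drop = TRUE]
      if (n == 1) Xc <- matrix(Xc, nrow = 1)
      for (j in seq_len(k)) {
        w <- W[j, c, o]
        if (w != 0 || TRUE) acc <- acc + Xc[, j:(j + Lout - 1L), drop = FALSE] * w
      }
    }
    Y[, , o] <- acc
  }
  Y
}

#' @noRd
conv1d_bwd <- function(dY, X, W) {
  n <- dim(X)[1]; L <- dim(X)[2]; c_in <- dim(X)[3]
  k <- dim(W)[1]; c_out <- dim(W)[3]
  Lout <- L - k + 1L
  dX <- array(0, dim(X))
  dW <- array(0, dim(W))
  db <- numeric(c_out)
  for (o in seq_len(c_out)) {
    dYo <- dY[, , o, drop = TRUE]
    if (n == 1) dYo <- matrix(dYo, nrow = 1)
    db[o] <- sum(dYo)
    for (c in seq_len(c_in)) {
      Xc <- X[, , c, drop = TRUE]
      if (n == 1) Xc <- matrix(Xc, nrow = 1)
      dXc <- matrix(0, n, L)
      for (j in seq_len(k)) {
        cols <- j:(j + Lout - 1L)
        dW[j, c, o] <- sum(Xc[, cols, drop = FALSE] * dYo)
        dXc[, cols] <- dXc[, cols] + dYo * W[j, c, o]
      }
      dX[, , c] <- dX[, , c] + dXc
    }
  }
  list(dX = dX, dW = dW, db = db)
}

# Softmax cross-entropy over integer labels 0..K-1.
# Returns mean loss and gradient w.r.t. the logits.
#' @noRd
softmax_xent <- function(logits, y) {
  n <- nrow(logits); K <- ncol(logits)
  m <- apply(logits, 1, max)
  Z <- logits - m
  lse <- log(rowSums(exp(Z)))
  iy <- cbind(seq_len(n), y + 1L)
  loss <- mean(lse - Z[iy])
  P <- exp(Z - lse)                        # softmax rows
  G <- P
  G[iy] <- G[iy] - 1
  list(loss = loss, grad = G / n, probs = P)
}

# --- parameter-tree helpers (nested named lists of arrays) -----------------

#' @noRd
tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else if (is.null(a)) NULL else f(a)
}

#' @noRd
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else if (is.null(a)) NULL else f(a, b)
}

# Adam step over a whole parameter tree; returns updated (params, m, v).
#' @noRd
adam_step <- function(params, grads, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- tree_map2(m, grads, function(m1, g) beta1 * m1 + (1 - beta1) * g)
  v <- tree_map2(v, grads, function(v1, g) beta2 * v1 + (1 - beta2) * g^2)
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  upd <- tree_map2(m, v, function(m1, v1) lr * (m1 / c1) / (sqrt(v1 / c2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, m = m, v = v)
}
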