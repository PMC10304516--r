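#' Attention-branch kernel sizes for an embedding length
#'
#' The feature-attention branch chains max-pool (kernel 3, stride 1) and two
#' valid 1-D convolutions, each output length following
#' `out = in - kernel + 1`. Kernel sizes are `k1 = L/2 - 1` and
#' `k2 = L/4 + 1`, which for the 128-long embedding gives the printed chain
#' 128 -> 126 -> 64 -> 32 and generalizes to any `L` divisible by 4
#' (e.g. 56 -> 54 -> 28 -> 14).
#'
#' @param L Embedding length; must be divisible by 4 and at least 8.
#' @return List with `k1`, `k2`, `flatten` (the flattened length `L/4`) and
#'   `chain` (the lengths `L, L-2, L/2, L/4, L` through the branch).
#' @export
fanet_kernels <- function(L) {
  if (L %% 4 != 0 || L < 8)
    stop_input("attention branch needs an embedding length divisible by 4 and >= 8 (got %d)", L)
  k1 <- L / 2 - 1
  k2 <- L / 4 + 1
  list(k1 = k1, k2 = k2, flatten = L / 4,
       chain = c(L, L - 2, L / 2, L / 4, L))
}

# Dense-stack spec: linear -> ReLU -> batch-norm -> dropout blocks, with
# batch-norm/dropout on all but the last layer; ReLU on every layer except
# optionally the last (relu_last).
#' @noRd
dense_spec <- function(dims, relu_last = TRUE) {
  k <- length(dims) - 1L
  list(dims = dims, n_layers = k,
       bn = c(rep(TRUE, k - 1L), FALSE),
       relu = c(rep(TRUE, k - 1L), relu_last))
}

#' @noRd
dense_init <- function(spec) {
  p <- list(); s <- list()
  for (l in seq_len(spec$n_layers)) {
    lin <- init_linear(spec$dims[l], spec$dims[l + 1L])
    p[[sprintf("W%d", l)]] <- lin$W
    p[[sprintf("b%d", l)]] <- lin$b
    if (spec$bn[l]) {
      d <- spec$dims[l + 1L]
      p[[sprintf("g%d", l)]] <- rep(1, d)
      p[[sprintf("be%d", l)]] <- rep(0, d)
      s[[sprintf("bn%d", l)]] <- list(mean = rep(0, d), var = rep(1, d))
    }
  }
  list(params = p, state = s)
}

# Forward through a dense stack. Returns final output, per-layer block
# outputs (the taps), updated batch-norm state and the backward cache.
#' @noRd
dense_fwd <- function(X, P, S, spec, training, dropout_p) {
  k <- spec$n_layers
  cache <- vector("list", k)
  taps <- vector("list", k)
  A <- X
  for (l in seq_len(k)) {
    Z <- linear_fwd(A, P[[sprintf("W%d", l)]], P[[sprintf("b%d", l)]])
    H <- if (spec$relu[l]) relu_fwd(Z) else Z
    cl <- list(X = A, Z = Z)
    if (spec$bn[l]) {
      bn <- bn_fwd(H, P[[sprintf("g%d", l)]], P[[sprintf("be%d", l)]],
                   S[[sprintf("bn%d", l)]], training)
      S[[sprintf("bn%d", l)]] <- bn$state
      cl$bn <- bn$cache
      H <- bn$Y
    }
    taps[[l]] <- H                          # tap = block output before dropout
    if (spec$bn[l]) {
      dr <- dropout_fwd(H, dropout_p, training)
      cl$mask <- dr$mask
      H <- dr$Y
    }
    cache[[l]] <- cl
    A <- H
  }
  list(out = A, taps = taps, state = S, cache = cache)
}

#' @noRd
dense_bwd <- function(dOut, cache, P, spec) {
  k <- spec$n_layers
  G <- list()
  d <- dOut
  for (l in rev(seq_len(k))) {
    cl <- cache[[l]]
    if (spec$bn[l]) {
      d <- dropout_bwd(d, cl$mask)
      bb <- bn_bwd(d, cl$bn, P[[sprintf("g%d", l)]])
      G[[sprintf("g%d", l)]] <- bb$dgamma
      G[[sprintf("be%d", l)]] <- bb$dbeta
      d <- bb$dX
    }
    if (spec$relu[l]) d <- relu_bwd(d, cl$Z)
    lb <- linear_bwd(d, cl$X, P[[sprintf("W%d", l)]])
    G[[sprintf("W%d", l)]] <- lb$dW
    G[[sprintf("b%d", l)]] <- lb$db
    d <- lb$dX
  }
  list(dX = d, grads = G[names(P)])
}

#' @noRd
fanet_init <- function(L) {
  kk <- fanet_kernels(L)
  c1 <- init_conv1d(kk$k1, 1L, 5L)
  c2 <- init_conv1d(kk$k2, 5L, 1L)
  lin <- init_linear(kk$flatten, L)
  list(cw1 = c1$W, cb1 = c1$b, cw2 = c2$W, cb2 = c2$b, lw = lin$W, lb = lin$b)
}

# Attention branch forward: gate = sigmoid(linear(flatten(conv2(relu(
# conv1(relu applied per conv)(maxpool(x))))))), output = x * gate.
#' @noRd
fanet_fwd <- function(X, P) {
  n <- nrow(X)
  mp <- maxpool3_fwd(X)
  X1 <- array(mp$Y, c(n, ncol(mp$Y), 1L))
  Z1 <- conv1d_fwd(X1, P$cw1, P$cb1)
  A1 <- relu_fwd(Z1)
  Z2 <- conv1d_fwd(A1, P$cw2, P$cb2)
  A2 <- matrix(relu_fwd(Z2), n)            # n x L/4 (single out channel)
  G <- linear_fwd(A2, P$lw, P$lb)
  gate <- sigmoid(G)
  list(out = X * gate, gate = gate,
       cache = list(X = X, mp = mp$cache, X1 = X1, Z1 = Z1, A1 = A1,
                    Z2 = Z2, A2 = A2, gate = gate))
}

#' @noRd
fanet_bwd <- function(dOut, cache, P) {
  n <- nrow(dOut)
  gate <- cache$gate
  dX_direct <- dOut * gate
  dgate <- dOut * cache$X
  dG <- dgate * gate * (1 - gate)
  lb <- linear_bwd(dG, cache$A2, P$lw)
  dA2 <- lb$dX
  dZ2 <- array(relu_bwd(dA2, matrix(cache$Z2, n)), dim(cache$Z2))
  cb2 <- conv1d_bwd(dZ2, cache$A1, P$cw2)
  dZ1 <- cb2$dX * (cache$Z1 > 0)
  cb1 <- conv1d_bwd(dZ1, cache$X1, P$cw1)
  dPool <- matrix(cb1$dX, n)
  dX <- dX_direct + maxpool3_bwd(dPool, cache$mp)
  list(dX = dX,
       grads = list(cw1 = cb1$dW, cb1 = cb1$db, cw2 = cb2$dW, cb2 = cb2$db,
                    lw = lb$dW, lb = lb$db))
}

# --- full model ------------------------------------------------------------

#' @noRd
fcan_arch <- function(in_dim_de, in_dim_psd, fusion, placement,
                      hidden = c(1024, 256), embed_dim = 128,
                      fcn2_dims = c(512, 1024, 256, 64, 4),
                      final_relu = TRUE) {
  fusion <- match.arg(fusion, c("concat", "add", "mult", "de", "psd"))
  placement <- match.arg(placement, c("before", "none", "after"))
  branches <- switch(fusion, de = "de", psd = "psd", c("de", "psd"))
  fused_len <- if (fusion == "concat") 2L * embed_dim else embed_dim
  list(fusion = fusion, placement = placement, branches = branches,
       embed_dim = embed_dim, fused_len = fused_len,
       fcn1_de = if ("de" %in% branches)
         dense_spec(c(in_dim_de, hidden, embed_dim)),
       fcn1_psd = if ("psd" %in% branches)
         dense_spec(c(in_dim_psd, hidden, embed_dim)),
       fcn2 = dense_spec(c(fused_len, fcn2_dims), relu_last = final_relu))
}

#' @noRd
fcan_init <- function(arch) {
  P <- list(); S <- list()
  for (br in arch$branches) {
    nm <- paste0("fcn1_", br)
    ini <- dense_init(arch[[nm]])
    P[[nm]] <- ini$params; S[[nm]] <- ini$state
    if (arch$placement == "before")
      P[[paste0("fanet_", br)]] <- fanet_init(arch$embed_dim)
  }
  if (arch$placement == "after")
    P$fanet_fused <- fanet_init(arch$fused_len)
  ini <- dense_init(arch$fcn2)
  P$fcn2 <- ini$params; S$fcn2 <- ini$state
  list(params = P, state = S)
}

#' @noRd
fcan_fwd <- function(Xde, Xpsd, P, S, arch, training, dropout_p) {
  cache <- list(); emb <- list()
  for (br in arch$branches) {
    nm <- paste0("fcn1_", br)
    X <- if (br == "de") Xde else Xpsd
    f1 <- dense_fwd(X, P[[nm]], S[[nm]], arch[[nm]], training, dropout_p)
    S[[nm]] <- f1$state
    cache[[nm]] <- f1$cache
    e <- f1$out
    if (arch$placement == "before") {
      fa <- fanet_fwd(e, P[[paste0("fanet_", br)]])
      cache[[paste0("fanet_", br)]] <- fa$cache
      e <- fa$out
    }
    emb[[br]] <- e
  }
  fused <- switch(arch$fusion,
    concat = cbind(emb$de, emb$psd),
    add = emb$de + emb$psd,
    mult = emb$de * emb$psd,
    de = emb$de, psd = emb$psd)
  cache$emb <- emb
  if (arch$placement == "after") {
    fa <- fanet_fwd(fused, P$fanet_fused)
    cache$fanet_fused <- fa$cache
    fused <- fa$out
  }
  cache$fused <- fused
  f2 <- dense_fwd(fused, P$fcn2, S$fcn2, arch$fcn2, training, dropout_p)
  S$fcn2 <- f2$state
  cache$fcn2 <- f2$cache
  list(out = f2$out, taps = f2$taps, fused = fused, state = S, cache = cache)
}

#' @noRd
fcan_bwd <- function(dOut, cache, P, arch) {
  G <- list()
  b2 <- dense_bwd(dOut, cache$fcn2, P$fcn2, arch$fcn2)
  G$fcn2 <- b2$grads
  dFused <- b2$dX
  if (arch$placement == "after") {
    fb <- fanet_bwd(dFused, cache$fanet_fused, P$fanet_fused)
    G$fanet_fused <- fb$grads
    dFused <- fb$dX
  }
  L <- arch$embed_dim
  dEmb <- switch(arch$fusion,
    concat = list(de = dFused[, 1:L, drop = FALSE],
                  psd = dFused[, (L + 1):(2 * L), drop = FALSE]),
    add = list(de = dFused, psd = dFused),
    mult = list(de = dFused * cache$emb$psd, psd = dFused * cache$emb$de),
    de = list(de = dFused), psd = list(psd = dFused))
  for (br in arch$branches) {
    d <- dEmb[[br]]
    if (arch$placement == "before") {
      fb <- fanet_bwd(d, cache[[paste0("fanet_", br)]], P[[paste0("fanet_", br)]])
      G[[paste0("fanet_", br)]] <- fb$grads
      d <- fb$dX
    }
    nm <- paste0("fcn1_", br)
    b1 <- dense_bwd(d, cache[[nm]], P[[nm]], arch[[nm]])
    G[[nm]] <- b1$grads
  }
  G[names(P)]
}

#' Training configuration for the feature-attention network
#'
#' Defaults follow the training protocol of the method: Adam at learning
#' rate 0.001, cross-entropy loss, batch size 128, dropout 0.5, up to 100
#' epochs with plateau-based learning-rate decay (factor 0.5 after 5 epochs
#' without validation improvement) and early stopping (patience 10, 10% of
#' the training set held out for validation). The final 4-unit layer carries
#' a ReLU before the softmax (per the architecture tables); set
#' `final_relu = FALSE` for raw logits.
#'
#' @param lr Initial Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param dropout Dropout probability after each batch-normalized block.
#' @param val_fraction Fraction of the training data held out for the
#'   validation loss driving lr decay and early stopping.
#' @param lr_patience,lr_factor Plateau decay: multiply lr by `lr_factor`
#'   after `lr_patience` epochs without validation improvement.
#' @param stop_patience Early stopping patience (epochs).
#' @param final_relu Keep the rectifier on the 4-unit output layer.
#' @param standardize Z-score input features (statistics fitted on the
#'   training data and stored in the model).
#' @param hidden Hidden widths of the embedding branches (default 1024, 256).
#' @param embed_dim Branch embedding width (default 128).
#' @param fcn2_dims Reduction-network widths (default 512, 1024, 256, 64, 4).
#' @param seed Integer seed; training is deterministic given data and seed.
#' @param verbose Print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, batch_size = 128, epochs = 100,
                         dropout = 0.5, val_fraction = 0.1,
                         lr_patience = 5, lr_factor = 0.5, stop_patience = 10,
                         final_relu = TRUE, standardize = TRUE,
                         hidden = c(1024, 256), embed_dim = 128,
                         fcn2_dims = c(512, 1024, 256, 64, 4),
                         seed = 1, verbose = FALSE) {
  if (lr <= 0) stop_input("learning rate must be positive")
  if (batch_size < 1) stop_input("batch size must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 val_fraction = val_fraction, lr_patience = lr_patience,
                 lr_factor = lr_factor, stop_patience = stop_patience,
                 final_relu = final_relu, standardize = standardize,
                 hidden = hidden, embed_dim = as.integer(embed_dim),
                 fcn2_dims = fcn2_dims, seed = as.integer(seed),
                 verbose = verbose), class = "train_config")
}

#' Train the feature-attention network
#'
#' Trains the full network end to end: two parallel fully connected
#' embedding branches (one for DE features, one for PSD), a convolutional
#' attention branch per embedding that produces multiplicative gates in
#' (0, 1), a fusion step (concatenation by default) and a five-layer
#' reduction network whose 4-unit output is the classification head,
#' optimized with Adam and softmax cross-entropy on the quadrant labels.
#'
#' @param features A `feature_samples` object (or list with `de`, `psd`
#'   matrices and integer `label` 0-3).
#' @param config A [train_config()].
#' @param fusion Fusion strategy: `"concat"` (default), `"add"`, `"mult"`,
#'   or single-branch `"de"` / `"psd"`.
#' @param placement Attention placement: `"before"` the fusion (default,
#'   one attention branch per embedding), `"none"` (gating removed), or
#'   `"after"` (a single attention branch on the fused vector).
#' @return An object of class `fcan_model` with the trained parameters,
#'   batch-norm statistics, per-epoch history (`train_loss`, `val_loss`,
#'   `lr`), and the architecture description.
#' @seealso [extract_deep_features()], [fcan_xgboost()]
#' @export
train_fcan <- function(features, config = train_config(),
                       fusion = "concat", placement = "before") {
  Xde <- features$de; Xpsd <- features$psd; y <- as.integer(features$label)
  n <- nrow(Xde)
  if (length(unique(y)) < 2) stop_input("training data must contain >= 2 classes")
  if (!is.null(Xpsd) && nrow(Xpsd) != n) stop_input("de/psd row mismatch")
  K <- 4L
  with_seed(config$seed, {
    std <- NULL
    if (config$standardize) {
      std <- list(
        de = list(mean = colMeans(Xde), sd = pmax(apply(Xde, 2, stats::sd), 1e-8)),
        psd = list(mean = colMeans(Xpsd), sd = pmax(apply(Xpsd, 2, stats::sd), 1e-8)))
      Xde <- scale(Xde, std$de$mean, std$de$sd)
      Xpsd <- scale(Xpsd, std$psd$mean, std$psd$sd)
    }
    arch <- fcan_arch(ncol(Xde), ncol(Xpsd), fusion, placement,
                      hidden = config$hidden, embed_dim = config$embed_dim,
                      fcn2_dims = config$fcn2_dims,
                      final_relu = config$final_relu)
    ini <- fcan_init(arch)
    P <- ini$params; S <- ini$state
    m <- tree_map(P, function(x) x * 0)
    v <- tree_map(P, function(x) x * 0)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    lr <- config$lr
    best_val <- Inf; best_P <- P; best_S <- S
    bad_lr <- 0L; bad_stop <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), lr = numeric(0))
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      losses <- c(); wts <- c()
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        if (length(bi) < 2) next            # batch-norm needs >= 2 samples
        fw <- fcan_fwd(Xde[bi, , drop = FALSE], Xpsd[bi, , drop = FALSE],
                       P, S, arch, training = TRUE, dropout_p = config$dropout)
        S <- fw$state
        ce <- softmax_xent(fw$out, y[bi])
        if (!is.finite(ce$loss))
          stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
        G <- fcan_bwd(ce$grad, fw$cache, P, arch)
        step <- step + 1L
        ad <- adam_step(P, G, m, v, step, lr)
        P <- ad$params; m <- ad$m; v <- ad$v
        losses <- c(losses, ce$loss); wts <- c(wts, length(bi))
      }
      train_loss <- sum(losses * wts) / sum(wts)
      val_loss <- if (length(val_idx) >= 2) {
        fv <- fcan_fwd(Xde[val_idx, , drop = FALSE], Xpsd[val_idx, , drop = FALSE],
                       P, S, arch, training = FALSE, dropout_p = 0)
        softmax_xent(fv$out, y[val_idx])$loss
      } else train_loss
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = train_loss,
                                     val_loss = val_loss, lr = lr))
      if (config$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                        ep, train_loss, val_loss, lr))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_P <- P; best_S <- S
        bad_lr <- 0L; bad_stop <- 0L
      } else {
        bad_lr <- bad_lr + 1L; bad_stop <- bad_stop + 1L
        if (bad_lr >= config$lr_patience) {
          lr <- lr * config$lr_factor; bad_lr <- 0L
        }
        if (bad_stop >= config$stop_patience) break
      }
    }
    structure(list(params = best_P, state = best_S, arch = arch,
                   standardize = std, classes = 0:(K - 1L), history = hist,
                   config = config, fusion = fusion, placement = placement),
              class = "fcan_model")
  })
}

#' @noRd
fcan_prepare_inputs <- function(model, features) {
  Xde <- features$de; Xpsd <- features$psd
  if (!is.null(model$standardize)) {
    Xde <- scale(Xde, model$standardize$de$mean, model$standardize$de$sd)
    Xpsd <- scale(Xpsd, model$standardize$psd$mean, model$standardize$psd$sd)
  }
  list(de = Xde, psd = Xpsd)
}

#' Forward pass of a trained network in inference mode
#'
#' Dropout is disabled and batch normalization uses its running statistics.
#'
#' @param model A trained `fcan_model`.
#' @param features `feature_samples` (or list with `de` and `psd` matrices).
#' @return List with `taps` (IFC1..IFC5 activation matrices), `fused` (the
#'   post-fusion vector, the `No_FC` tap) and `probs` (softmax of the head).
#' @export
fcan_forward <- function(model, features) {
  X <- fcan_prepare_inputs(model, features)
  fw <- fcan_fwd(X$de, X$psd, model$params, model$state, model$arch,
                 training = FALSE, dropout_p = 0)
  names(fw$taps) <- sprintf("IFC%d", seq_along(fw$taps))
  sm <- exp(fw$out - apply(fw$out, 1, max))
  list(taps = fw$taps, fused = fw$fused, probs = sm / rowSums(sm))
}

#' @export
predict.fcan_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fw <- fcan_forward(object, newdata)
  if (type == "prob") fw$probs else max.col(fw$probs, ties.method = "first") - 1L
}

#' @export
print.fcan_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<fcan_model> fusion=%s, attention=%s, embed=%d, fused=%d\n",
              a$fusion, x$placement, a$embed_dim, a$fused_len))
  cat(sprintf("  trained %d epochs, final val loss %.4f\n",
              nrow(x$history), x$history$val_loss[nrow(x$history)]))
  invisible(x)
}
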