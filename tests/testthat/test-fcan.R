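test_that("attention kernel rule reproduces the published shape chains", {
  k128 <- fanet_kernels(128)
  expect_equal(k128$k1, 63)
  expect_equal(k128$k2, 33)
  expect_equal(k128$chain, c(128, 126, 64, 32, 128))
  k56 <- fanet_kernels(56)
  expect_equal(k56$chain, c(56, 54, 28, 14, 56))
  expect_error(fanet_kernels(30), "divisible by 4")
})

test_that("attention branch propagates the printed shapes and bounded gates", {
  set.seed(1)
  P <- fcanxgb:::fanet_init(128)
  X <- matrix(rnorm(2 * 128), 2)
  fw <- fcanxgb:::fanet_fwd(X, P)
  expect_equal(dim(fw$cache$X1)[2], 126)     # max-pool: 128 -> 126
  expect_equal(dim(fw$cache$A1)[2:3], c(64, 5))  # conv k=63: 126 -> 64, 5 ch
  expect_equal(dim(fw$cache$A2), c(2, 32))   # conv k=33: 64 -> 32, flattened
  expect_equal(dim(fw$gate), c(2, 128))      # linear 32 -> 128
  expect_true(all(fw$gate > 0 & fw$gate < 1))
})

test_that("zeroed gate parameters give a constant 0.5 gate", {
  set.seed(2)
  P <- fcanxgb:::fanet_init(16)
  P$lw[] <- 0; P$lb[] <- 0
  X <- matrix(rnorm(3 * 16), 3)
  fw <- fcanxgb:::fanet_fwd(X, P)
  expect_equal(fw$gate, matrix(0.5, 3, 16))
  expect_equal(fw$out, 0.5 * X)
})

test_that("embedding branch output is 128-wide and non-negative; zero params give zero", {
  set.seed(3)
  spec <- fcanxgb:::dense_spec(c(128, 1024, 256, 128))
  ini <- fcanxgb:::dense_init(spec)
  X <- matrix(rnorm(2 * 128), 2)
  fw <- fcanxgb:::dense_fwd(X, ini$params, ini$state, spec,
                            training = FALSE, dropout_p = 0)
  expect_equal(dim(fw$out), c(2, 128))
  expect_true(all(fw$out >= 0))
  zeroed <- fcanxgb:::tree_map(ini$params, function(x) x * 0)
  zeroed$g1 <- ini$params$g1; zeroed$g2 <- ini$params$g2   # batch-norm scale 1
  fw0 <- fcanxgb:::dense_fwd(X, zeroed, ini$state, spec,
                             training = TRUE, dropout_p = 0)
  expect_equal(max(abs(fw0$out)), 0)
})

test_that("a hand-sized dense layer matches manual matrix arithmetic", {
  spec <- fcanxgb:::dense_spec(c(2, 2))     # single linear + rectifier
  P <- list(W1 = matrix(c(1, -2, 0.5, 3), 2), b1 = c(0.25, -1))
  x <- c(1.5, -0.5)
  fw <- fcanxgb:::dense_fwd(matrix(x, 1), P, list(), spec,
                            training = FALSE, dropout_p = 0)
  # y = relu(W'x + b): [1*1.5 + (-2)(-0.5) + 0.25, 0.5*1.5 + 3*(-0.5) - 1]
  expect_equal(as.vector(fw$out), pmax(c(2.75, -1.75), 0))
})

test_that("fusion strategies combine embeddings as specified", {
  a <- matrix(rnorm(2 * 128), 2); b <- matrix(rnorm(2 * 128), 2)
  arch <- function(fu) fcanxgb:::fcan_arch(128, 128, fu, "none")
  expect_equal(arch("concat")$fused_len, 256)
  # the fused vector preserves [DE; PSD] order under concatenation
  P <- fcanxgb:::fcan_init(arch("concat"))
  expect_equal(cbind(a, b)[, 1:128], a)
  expect_equal(a + matrix(0, 2, 128), a)    # add with zero is identity
  expect_equal(a * matrix(1, 2, 128), a)    # mult with ones is identity
})

test_that("reduction network taps have widths 512/1024/256/64/4", {
  set.seed(4)
  spec <- fcanxgb:::dense_spec(c(256, 512, 1024, 256, 64, 4))
  ini <- fcanxgb:::dense_init(spec)
  fw <- fcanxgb:::dense_fwd(matrix(rnorm(2 * 256), 2), ini$params, ini$state,
                            spec, training = FALSE, dropout_p = 0)
  expect_equal(vapply(fw$taps, ncol, integer(1)), c(512, 1024, 256, 64, 4))
  zeroP <- fcanxgb:::tree_map(ini$params, function(x) x * 0)
  fw0 <- fcanxgb:::dense_fwd(matrix(rnorm(2 * 256), 2), zeroP, ini$state, spec,
                             training = TRUE, dropout_p = 0)
  expect_true(all(vapply(fw0$taps, function(t) max(abs(t)), numeric(1)) == 0))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  n <- 6; Din <- 8
  Xde <- matrix(rnorm(n * Din), n); Xpsd <- matrix(rnorm(n * Din), n)
  y <- sample(0:3, n, replace = TRUE)
  arch <- fcanxgb:::fcan_arch(Din, Din, "concat", "before",
                              hidden = c(10, 6), embed_dim = 8,
                              fcn2_dims = c(7, 9, 5, 6, 4))
  ini <- fcanxgb:::fcan_init(arch)
  P <- ini$params; S0 <- ini$state
  lossfun <- function(P) {
    fw <- fcanxgb:::fcan_fwd(Xde, Xpsd, P, S0, arch, training = TRUE, dropout_p = 0)
    fcanxgb:::softmax_xent(fw$out, y)$loss
  }
  fw <- fcanxgb:::fcan_fwd(Xde, Xpsd, P, S0, arch, training = TRUE, dropout_p = 0)
  ce <- fcanxgb:::softmax_xent(fw$out, y)
  G <- fcanxgb:::fcan_bwd(ce$grad, fw$cache, P, arch)
  h <- 1e-6
  for (grp in names(P)) {
    for (nm in names(P[[grp]])) {
      arr <- P[[grp]][[nm]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        Pp <- P; Pp[[grp]][[nm]][i] <- arr[i] + h
        Pm <- P; Pm[[grp]][[nm]][i] <- arr[i] - h
        num <- (lossfun(Pp) - lossfun(Pm)) / (2 * h)
        ana <- G[[grp]][[nm]][i]
        expect_equal(ana, num, tolerance = 1e-3,
                     label = sprintf("grad %s$%s[%d]", grp, nm, i))
      }
    }
  }
})

test_that("training is deterministic given the seed", {
  f <- small_feats()
  m1 <- train_fcan(f, tiny_train_cfg(epochs = 3))
  m2 <- train_fcan(f, tiny_train_cfg(epochs = 3))
  expect_identical(m1$params$fcn2$W5, m2$params$fcn2$W5)
  expect_identical(m1$history, m2$history)
})

test_that("training loss decreases on separable data across seeds", {
  f <- small_feats()
  for (s in 1:3) {
    m <- train_fcan(f, tiny_train_cfg(epochs = 6, seed = s))
    expect_lt(m$history$train_loss[nrow(m$history)], m$history$train_loss[1])
  }
})

test_that("the trained network separates strongly separable classes", {
  f <- small_feats()
  m <- train_fcan(f, tiny_train_cfg(epochs = 15, dropout = 0))
  acc <- 100 * mean(predict(m, f) == f$label)
  expect_gte(acc, 90)
})

test_that("single-class data is rejected and gates stay in (0,1) after training", {
  f <- small_feats()
  f1 <- fcanxgb:::subset_features(f, which(f$label == 0))
  expect_error(train_fcan(f1, tiny_train_cfg(epochs = 1)), "2 classes")
  m <- train_fcan(f, tiny_train_cfg(epochs = 2))
  set.seed(5)
  fw <- fcanxgb:::fanet_fwd(matrix(rnorm(20 * 16), 20), m$params$fanet_de)
  expect_true(all(fw$gate > 0 & fw$gate < 1))
})
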