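# scale a window so its unbiased sample variance is exactly v
window_with_variance <- function(n, v, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- x - mean(x)
  x / sd(x) * sqrt(v)
}

test_that("differential entropy matches its Gaussian closed form", {
  w0 <- window_with_variance(64, 1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(w0), 0, tolerance = 1e-12)
  w1 <- window_with_variance(64, exp(1) / (2 * pi))
  expect_equal(differential_entropy(w1), 1, tolerance = 1e-12)
  set.seed(4)
  big <- rnorm(4096, sd = 2)
  expect_equal(differential_entropy(big), 0.5 * log(2 * pi * exp(1) * 4),
               tolerance = 0.05)
  # degenerate input hits the documented floor instead of -Inf
  expect_equal(differential_entropy(rep(3, 10)),
               0.5 * log(2 * pi * exp(1) * 1e-12))
  expect_error(differential_entropy(1), ">= 2 samples")
})

test_that("differential entropy agrees with numerical integration of the density", {
  de_integral <- function(s2) {
    f <- function(x) dnorm(x, 0, sqrt(s2))
    g <- function(x) ifelse(f(x) > 0, f(x) * log(f(x)), 0)
    -integrate(g, -20 * sqrt(s2), 20 * sqrt(s2), rel.tol = 1e-10)$value
  }
  set.seed(9)
  for (i in 1:20) {
    w <- rnorm(128, sd = runif(1, 0.2, 5))
    expect_equal(differential_entropy(w), de_integral(var(w)), tolerance = 1e-6)
  }
})

test_that("the periodogram equals the transform of the biased autocorrelation", {
  # brute-force Wiener-Khinchin oracle: P(w_k) = sum_tau gamma(tau) e^{-i w_k tau}
  wk_psd <- function(x) {
    M <- length(x)
    g <- vapply(0:(M - 1), function(tau)
      sum(x[seq_len(M - tau)] * x[seq_len(M - tau) + tau]) / M, numeric(1))
    vapply(0:(M - 1), function(k) {
      w <- 2 * pi * k / M
      g[1] + 2 * sum(g[-1] * cos(w * seq_len(M - 1)))
    }, numeric(1))
  }
  set.seed(2)
  for (M in c(64, 97, 128)) {
    x <- rnorm(M)
    impl <- Mod(fft(x))^2 / M          # the implementation's periodogram
    expect_equal(fcanxgb:::periodogram(x), impl, tolerance = 1e-12)
    expect_equal(wk_psd(x), impl, tolerance = 1e-8)
  }
})

test_that("band power isolates an in-band tone and handles edge cases", {
  fs <- 128
  t <- seq_len(256) / fs
  x <- sin(2 * pi * 10 * t)
  bands <- eeg_bands()
  vals <- vapply(seq_len(4), function(b) band_psd(x, fs, bands[b, ]), numeric(1))
  names(vals) <- bands$name
  expect_true(all(vals["alpha"] >= 100 * vals[c("theta", "beta", "gamma")]))
  expect_equal(band_psd(rep(0, 64), fs, bands[1, ]), 0)
  expect_error(band_psd(rnorm(4), fs, list(low = 8, high = 9)), "no frequency bin")
})

test_that("scaling covariance: PSD scales as c^2, DE shifts by log(c)", {
  set.seed(6)
  fs <- 128
  for (i in 1:10) {
    w <- rnorm(256)
    c0 <- runif(1, 0.1, 10)
    expect_equal(band_psd(c0 * w, fs, eeg_bands()[2, ]),
                 c0^2 * band_psd(w, fs, eeg_bands()[2, ]), tolerance = 1e-10)
    expect_equal(differential_entropy(c0 * w),
                 differential_entropy(w) + log(c0), tolerance = 1e-10)
  }
})

test_that("baseline correction is elementwise stimulus minus baseline", {
  expect_equal(baseline_correct(c(1.5, 2.0), c(0.5, 3.0)), c(1.0, -1.0))
  expect_equal(baseline_correct(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(baseline_correct(c(4, 5), c(0, 0)), c(4, 5))
  m <- matrix(1:6, 2)
  expect_equal(baseline_correct(m, c(1, 1, 1)), m - 1)
  expect_error(baseline_correct(m, c(1, 2)), "mismatch")
})

test_that("baseline features have one value per channel x band", {
  set.seed(8)
  base <- matrix(rnorm(3 * 256), 3)
  bf <- baseline_features(base, 128)
  expect_length(bf$de, 12)
  expect_length(bf$psd, 12)
  expect_error(baseline_features(matrix(rnorm(64), 2), 128), "at least 1 s")
})

test_that("assembled features have the protocol's shape and count", {
  f <- small_feats()                       # 32 trials x 4 windows, 4 channels
  expect_equal(dim(f$de), c(128, 16))
  expect_equal(dim(f$psd), c(128, 16))
  expect_length(f$label, 128)
  expect_true(all(f$label %in% 0:3))
  # count conservation: windows emitted by the segmenter, summed over trials
  expect_equal(nrow(f$de), 32 * (8 %/% 2))
  # 14 channels -> vectors of length 56
  cfg14 <- synth_config(n_subjects = 1, n_trials_per_subject = 2,
                        n_channels = 14, stimulus_s = 4,
                        rating_scale_max = 5, seed = 13)
  f14 <- assemble_features(generate_trials(cfg14))
  expect_equal(ncol(f14$de), 56)
})

test_that("a stimulus window identical to the baseline yields zero features", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 1, n_channels = 2,
                      baseline_s = 2, stimulus_s = 2, seed = 3)
  tr <- generate_trials(cfg)
  tr[[1]]$stimulus_signal <- tr[[1]]$baseline_signal   # stim == baseline
  f <- assemble_features(tr, window_s = 2)
  expect_equal(max(abs(f$de)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f$psd)), 0, tolerance = 1e-9)
})

test_that("feature samples survive the CSV round trip", {
  f <- small_feats()
  p <- withr::local_tempfile(fileext = ".csv")
  write_features(f, p)
  back <- read_features(p)
  expect_equal(back$de, f$de, tolerance = 1e-12)
  expect_equal(back$label, f$label)
})
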