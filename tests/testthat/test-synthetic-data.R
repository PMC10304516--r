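test_that("generation is bit-identical under a fixed seed and counts trials", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 4,
                      n_channels = 3, stimulus_s = 4, seed = 7)
  a <- generate_trials(cfg)
  b <- generate_trials(cfg)
  expect_length(a, 8)
  expect_identical(a[[5]]$stimulus_signal, b[[5]]$stimulus_signal)
  expect_identical(a[[8]]$baseline_signal, b[[8]]$baseline_signal)
  expect_identical(vapply(a, `[[`, numeric(1), "valence"),
                   vapply(b, `[[`, numeric(1), "valence"))
})

test_that("ratings fall in the half of the scale the quadrant requires", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 8,
                      n_channels = 2, stimulus_s = 4, seed = 3)
  for (tr in generate_trials(cfg)) {
    expect_gte(tr$valence, 1); expect_lte(tr$valence, 9)
    hv <- tr$class %in% c(0, 1); ha <- tr$class %in% c(0, 2)
    expect_identical(tr$valence >= 5, hv)
    expect_identical(tr$arousal >= 5, ha)
  }
  cfg5 <- synth_config(n_subjects = 1, n_trials_per_subject = 8,
                       n_channels = 2, stimulus_s = 4,
                       rating_scale_max = 5, seed = 3)
  for (tr in generate_trials(cfg5)) {
    expect_lte(tr$valence, 5)
    expect_identical(tr$valence >= 2.5, tr$class %in% c(0, 1))
  }
})

test_that("a 3x alpha gain raises alpha-band power, measured by an FFT oracle", {
  # independent periodogram oracle: mean |DFT|^2 / M over bins in 8-14 Hz
  alpha_power <- function(x, fs) {
    M <- length(x)
    P <- Mod(fft(x))^2 / M
    freqs <- (seq_len(M) - 1) * fs / M
    idx <- which(freqs >= 8 & freqs <= 14 & freqs <= fs / 2)
    mean(P[idx])
  }
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 8,
                      n_channels = 2, stimulus_s = 8, seed = 11)
  trials <- generate_trials(cfg)
  pow <- vapply(trials, function(tr) alpha_power(tr$stimulus_signal[1, ], tr$fs),
                numeric(1))
  cls <- vapply(trials, `[[`, numeric(1), "class")
  # LVHA (class 2) carries the 3x alpha gain by default
  expect_gt(mean(pow[cls == 2]), 2 * mean(pow[cls != 2]))
})

test_that("with equal band gains the classes are not separable", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 24,
                      n_channels = 4, stimulus_s = 10,
                      class_band_gains = default_band_gains(contrast = 1),
                      seed = 21)
  f <- assemble_features(generate_trials(cfg))
  sp <- split_train_test(nrow(f$de), 0.8, 1)
  bm <- train_boost(cbind(f$de, f$psd)[sp$train, ], tiny_boost_cfg(),
                    label = f$label[sp$train])
  acc <- compute_metrics(f$label[sp$test],
                         predict(bm, cbind(f$de, f$psd)[sp$test, ]))$accuracy
  expect_lt(acc, 45)   # chance is 25%; no class structure to learn
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(stimulus_s = 0), "positive")
  expect_error(synth_config(class_band_gains = matrix(1, 3, 4)), "4x4")
  bad <- default_band_gains(); rownames(bad)[1] <- "JOY"
  expect_error(synth_config(class_band_gains = bad), "quadrant")
})
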