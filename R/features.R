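#' Differential entropy of a band-limited window
#'
#' For a signal window that approximately follows a Gaussian distribution
#' the differential entropy has the closed form `0.5 * log(2 * pi * e * var)`
#' (natural log, nats). The sample variance uses the unbiased (n-1)
#' estimator. A constant window (zero variance) returns the documented floor
#' `0.5 * log(2 * pi * e * 1e-12)` rather than -Inf.
#'
#' @param window Numeric vector with at least 2 samples.
#' @return Differential entropy in nats.
#' @examples
#' differential_entropy(rnorm(4096, sd = 2))  # ~ 0.5 * log(2*pi*e*4)
#' @export
differential_entropy <- function(window) {
  if (length(window) < 2) stop_input("window must have >= 2 samples")
  v <- stats::var(window)
  0.5 * log(2 * pi * exp(1) * max(v, 1e-12))
}

# periodogram via FFT: I(w_k) = |sum_t x_t e^{-i w_k t}|^2 / M, which by
# Wiener-Khinchin equals the DFT of the biased autocorrelation
#' @noRd
periodogram <- function(x) Mod(stats::fft(x))^2 / length(x)

#' Band power from the periodogram
#'
#' Computes the window's power spectral density as the periodogram (the
#' discrete Fourier transform of the biased autocorrelation, per
#' Wiener-Khinchin) and summarizes the bins whose frequencies fall inside
#' `[band$low, band$high]`: the mean in-band bin power (default; invariant
#' to band width) or, with `mode = "integrate"`, the sum of in-band bin
#' powers times the bin width.
#'
#' @param window Numeric vector, length >= 2.
#' @param fs Sampling rate in Hz.
#' @param band One-row band definition (data.frame or list with `low`, `high`).
#' @param mode `"mean"` or `"integrate"`.
#' @return Non-negative scalar power.
#' @export
band_psd <- function(window, fs, band, mode = c("mean", "integrate")) {
  mode <- match.arg(mode)
  M <- length(window)
  if (M < 2) stop_input("window must have >= 2 samples")
  P <- periodogram(window)
  freqs <- (seq_len(M) - 1) * fs / M
  half <- seq_len(M %/% 2 + 1)            # non-negative frequencies
  idx <- half[freqs[half] >= band$low & freqs[half] <= band$high]
  if (length(idx) == 0)
    stop_input("band %g-%g Hz contains no frequency bin at M=%d, fs=%g",
               band$low, band$high, M, fs)
  if (mode == "mean") mean(P[idx]) else sum(P[idx]) * fs / M
}

#' Whole-baseline features per channel and band
#'
#' Band-decomposes the baseline segment and computes one differential
#' entropy and one band power value per channel x band over the entire
#' segment (the baseline is treated as a single block, not windowed).
#' Ordering is channel-major, band-minor.
#'
#' @param baseline Channels x samples matrix, at least 1 s long.
#' @param fs Sampling rate in Hz.
#' @param bands Band table ([eeg_bands()]).
#' @param psd_mode Passed to [band_psd()].
#' @return A list with numeric vectors `de` and `psd` of length
#'   `nrow(baseline) * nrow(bands)`.
#' @export
baseline_features <- function(baseline, fs, bands = eeg_bands(),
                              psd_mode = "mean") {
  if (!is.matrix(baseline)) baseline <- matrix(baseline, nrow = 1)
  if (ncol(baseline) < fs) stop_input("baseline must be at least 1 s long")
  validate_bands(bands)
  nch <- nrow(baseline); nb <- nrow(bands)
  de <- psd <- numeric(nch * nb)
  by_band <- decompose_bands(baseline, fs, bands)
  for (ch in seq_len(nch)) {
    for (b in seq_len(nb)) {
      w <- by_band[[b]][ch, ]
      k <- (ch - 1L) * nb + b
      de[k] <- differential_entropy(w)
      psd[k] <- band_psd(w, fs, bands[b, ], mode = psd_mode)
    }
  }
  list(de = de, psd = psd)
}

#' Subtract baseline features from stimulus features
#'
#' Elementwise stimulus minus baseline, applied identically to every window
#' of a trial. Accepts a window x feature matrix and a baseline vector, or
#' two equal-shape vectors/matrices.
#'
#' @param stim_features Numeric vector or windows x features matrix.
#' @param base_features Numeric vector (per-feature baseline) or an object
#'   of the same shape as `stim_features`.
#' @return Corrected features, same shape as `stim_features`.
#' @export
baseline_correct <- function(stim_features, base_features) {
  if (is.matrix(stim_features) && !is.matrix(base_features)) {
    if (ncol(stim_features) != length(base_features))
      stop_input("feature shape mismatch: %d columns vs baseline length %d",
                 ncol(stim_features), length(base_features))
    return(sweep(stim_features, 2, base_features, `-`))
  }
  if (!identical(dim(stim_features), dim(base_features)) ||
      length(stim_features) != length(base_features))
    stop_input("feature shape mismatch")
  stim_features - base_features
}

#' Extract baseline-corrected DE and PSD feature samples from trials
#'
#' The full feature-extraction stage: per trial, the stimulus is decomposed
#' into the four canonical bands per channel, cut into non-overlapping
#' windows, and each window contributes one differential-entropy and one
#' band-power value per channel x band. Whole-baseline features
#' ([baseline_features()]) are subtracted from every window of the trial.
#' Feature vectors are ordered channel-major, band-minor
#' (ch1: theta, alpha, beta, gamma; ch2: ...), so 32 channels give vectors
#' of length 128 and 14 channels vectors of length 56. Labels are quadrant
#' classes from the trial ratings at the scale's cutoff.
#'
#' @param trials An `eeg_trials` object (from [generate_trials()] or
#'   [read_trials()]).
#' @param window_s Window length in seconds (default 2).
#' @param bands Band table ([eeg_bands()]).
#' @param psd_mode `"mean"` (default) or `"integrate"`; see [band_psd()].
#' @param cutoff Rating cutoff; defaults to the scale's canonical cutoff
#'   (5 on 1-9, 2.5 on 1-5).
#' @return An object of class `feature_samples`: list with matrices `de`
#'   and `psd` (n_windows_total x n_channels*4), integer `label` (0-3),
#'   and `subject`, `trial`, `window` index vectors.
#' @export
assemble_features <- function(trials, window_s = 2, bands = eeg_bands(),
                              psd_mode = "mean", cutoff = NULL) {
  if (length(trials) == 0) stop_input("no trials")
  validate_bands(bands)
  fs <- trials[[1]]$fs
  if (is.null(cutoff)) {
    cfg <- attr(trials, "config")
    scale_max <- if (!is.null(cfg)) cfg$rating_scale_max
                 else attr(trials, "rating_scale_max") %||% 9
    cutoff <- rating_cutoff(scale_max)
  }
  nb <- nrow(bands)
  nch <- nrow(trials[[1]]$stimulus_signal)
  D <- nch * nb
  de_rows <- list(); psd_rows <- list()
  lab <- subj <- tri <- win <- integer(0)
  eps <- 1e-12
  for (tr in trials) {
    if (nrow(tr$stimulus_signal) != nch || nrow(tr$baseline_signal) != nch)
      stop_input("channel-count mismatch in trial (subject %s, trial %s)",
                 tr$subject_id, tr$trial_id)
    base <- baseline_features(tr$baseline_signal, fs, bands, psd_mode)
    stim_bands <- decompose_bands(tr$stimulus_signal, fs, bands)
    nw <- ncol(tr$stimulus_signal) %/% round(window_s * fs)
    if (nw < 1)
      stop_input("stimulus shorter than one window in trial (subject %s, trial %s)",
                 tr$subject_id, tr$trial_id)
    de_m <- matrix(0, nw, D); psd_m <- matrix(0, nw, D)
    for (ch in seq_len(nch)) {
      for (b in seq_len(nb)) {
        W <- segment_windows(stim_bands[[b]][ch, ], fs, window_s)  # nw x wlen
        M <- ncol(W)
        mu <- rowMeans(W)
        v <- rowSums((W - mu)^2) / (M - 1)
        k <- (ch - 1L) * nb + b
        de_m[, k] <- 0.5 * log(2 * pi * exp(1) * pmax(v, eps))
        # periodogram of every window at once (columns of mvfft)
        P <- Mod(stats::mvfft(t(W)))^2 / M
        freqs <- (seq_len(M) - 1) * fs / M
        half <- seq_len(M %/% 2 + 1)
        idx <- half[freqs[half] >= bands$low[b] & freqs[half] <= bands$high[b]]
        if (length(idx) == 0)
          stop_input("band %s contains no frequency bin at this window length",
                     bands$name[b])
        psd_m[, k] <- if (psd_mode == "mean") colMeans(P[idx, , drop = FALSE])
                      else colSums(P[idx, , drop = FALSE]) * fs / M
      }
    }
    de_rows[[length(de_rows) + 1L]] <- baseline_correct(de_m, base$de)
    psd_rows[[length(psd_rows) + 1L]] <- baseline_correct(psd_m, base$psd)
    lab <- c(lab, rep(quadrant_label(tr$valence, tr$arousal, cutoff), nw))
    subj <- c(subj, rep(tr$subject_id, nw))
    tri <- c(tri, rep(tr$trial_id, nw))
    win <- c(win, seq_len(nw))
  }
  structure(list(de = do.call(rbind, de_rows), psd = do.call(rbind, psd_rows),
                 label = as.integer(lab), subject = subj, trial = tri,
                 window = win, n_channels = nch, bands = bands, fs = fs,
                 window_s = window_s, cutoff = cutoff),
            class = "feature_samples")
}

#' @export
print.feature_samples <- function(x, ...) {
  cat(sprintf("<feature_samples> %d windows x %d features (%d channels x %d bands)\n",
              nrow(x$de), ncol(x$de), x$n_channels, nrow(x$bands)))
  cat("  class counts:", paste(sprintf("%s=%d", quadrant_classes(),
                                       tabulate(x$label + 1L, 4L)), collapse = " "), "\n")
  invisible(x)
}

#' Write / read feature samples as CSV
#'
#' Small plain-text serialization of a `feature_samples` object: one CSV with
#' the DE block, the PSD block, and the label/index columns.
#'
#' @param features A `feature_samples` object.
#' @param path CSV file path.
#' @return `path` invisibly; `read_features` returns a `feature_samples`.
#' @export
write_features <- function(features, path) {
  D <- ncol(features$de)
  df <- data.frame(subject = features$subject, trial = features$trial,
                   window = features$window, label = features$label)
  de <- as.data.frame(features$de); names(de) <- sprintf("de%03d", seq_len(D))
  ps <- as.data.frame(features$psd); names(ps) <- sprintf("psd%03d", seq_len(D))
  data.table::fwrite(cbind(df, de, ps), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path)
  de_cols <- grep("^de\\d+$", names(dt), value = TRUE)
  psd_cols <- grep("^psd\\d+$", names(dt), value = TRUE)
  structure(list(de = unname(as.matrix(dt[, de_cols, with = FALSE])),
                 psd = unname(as.matrix(dt[, psd_cols, with = FALSE])),
                 label = dt$label, subject = dt$subject, trial = dt$trial,
                 window = dt$window, n_channels = length(de_cols) %/% 4L,
                 bands = eeg_bands()),
            class = "feature_samples")
}
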