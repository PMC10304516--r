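#' Default class-dependent band-power gains
#'
#' Amplitude multipliers applied to the band-limited oscillations of the
#' stimulus segment, one row per quadrant class and one column per band.
#' Each class boosts one distinctive rhythm (HVHA: gamma, HVLA: beta,
#' LVHA: alpha, LVLA: theta) by `contrast`; all other gains are 1. With
#' `contrast = 1` the four classes are statistically indistinguishable and
#' downstream classification collapses to chance.
#'
#' @param contrast Amplitude multiplier of each class's distinctive band.
#' @return A 4x4 numeric matrix, rows named by quadrant class, columns by band.
#' @export
default_band_gains <- function(contrast = 3) {
  g <- matrix(1, 4, 4, dimnames = list(quadrant_classes(), eeg_bands()$name))
  g["HVHA", "gamma"] <- contrast
  g["HVLA", "beta"]  <- contrast
  g["LVHA", "alpha"] <- contrast
  g["LVLA", "theta"] <- contrast
  g
}

#' Configuration for the synthetic EEG generator
#'
#' Defines a synthetic affective-EEG study: per-trial baseline + stimulus
#' segments with class-dependent band-power structure, ratings on a 1-9
#' (DEAP-like, cutoff 5) or 1-5 (DREAMER-like, cutoff 2.5) scale. Defaults
#' describe a 32-channel study at 128 Hz with 3 s baseline and 60 s stimulus
#' per trial and 128 trials in total (8 subjects x 16 trials), i.e. about
#' 3840 two-second analysis windows.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_subject Trials per subject; classes are assigned by
#'   cycling over the four quadrants so the design is balanced.
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate in Hz.
#' @param baseline_s Baseline (pre-stimulus) duration in seconds.
#' @param stimulus_s Stimulus duration in seconds.
#' @param rating_scale_max Upper end of the self-assessment rating scale
#'   (9 or 5); the lower end is 1.
#' @param class_band_gains 4x4 matrix of per-class, per-band amplitude
#'   multipliers (rows: quadrant classes, columns: bands).
#' @param noise_sd Standard deviation of the additive Gaussian white noise.
#' @param seed Integer seed; generation is bit-reproducible given the config.
#' @return An object of class `synth_config`.
#' @seealso [generate_trials()]
#' @export
synth_config <- function(n_subjects = 8, n_trials_per_subject = 16,
                         n_channels = 32, fs = 128,
                         baseline_s = 3, stimulus_s = 60,
                         rating_scale_max = 9,
                         class_band_gains = default_band_gains(),
                         noise_sd = 0.5, seed = 1) {
  if (fs <= 0) stop_input("fs must be positive")
  if (baseline_s <= 0 || stimulus_s <= 0)
    stop_input("baseline_s and stimulus_s must be positive")
  if (n_channels < 1) stop_input("n_channels must be >= 1")
  if (!rating_scale_max %in% c(9, 5))
    stop_input("rating_scale_max must be 9 (DEAP-like) or 5 (DREAMER-like)")
  gains <- as.matrix(class_band_gains)
  if (!all(dim(gains) == c(4, 4)))
    stop_input("class_band_gains must be a 4x4 matrix (4 classes x 4 bands)")
  if (is.null(rownames(gains))) rownames(gains) <- quadrant_classes()
  if (is.null(colnames(gains))) colnames(gains) <- eeg_bands()$name
  if (!setequal(rownames(gains), quadrant_classes()))
    stop_input("class_band_gains rows must be the 4 quadrant classes, got: %s",
               paste(rownames(gains), collapse = ", "))
  if (!setequal(colnames(gains), eeg_bands()$name))
    stop_input("class_band_gains columns must be the 4 bands")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    n_channels = as.integer(n_channels), fs = fs,
    baseline_s = baseline_s, stimulus_s = stimulus_s,
    rating_scale_max = rating_scale_max,
    class_band_gains = gains[quadrant_classes(), eeg_bands()$name],
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Rating cutoff for a scale
#'
#' The high/low threshold used to binarize valence and arousal ratings:
#' 5 on the 1-9 scale, 2.5 on the 1-5 scale.
#'
#' @param rating_scale_max 9 or 5.
#' @return The cutoff rating.
#' @export
rating_cutoff <- function(rating_scale_max) {
  if (rating_scale_max == 9) 5 else if (rating_scale_max == 5) 2.5
  else stop_input("unsupported rating scale max: %s", rating_scale_max)
}

# one multichannel segment: sum over bands of fixed-frequency sinusoids at
# each band's geometric center, amplitude = gain, random phase per
# channel x band, plus white noise
#' @noRd
synth_segment <- function(n_channels, n_samples, fs, gains, noise_sd) {
  bands <- eeg_bands()
  f0 <- sqrt(bands$low * bands$high)   # geometric center frequencies
  tt <- seq_len(n_samples) / fs
  sig <- matrix(stats::rnorm(n_channels * n_samples, sd = noise_sd),
                nrow = n_channels)
  for (b in seq_len(nrow(bands))) {
    phase <- stats::runif(n_channels, 0, 2 * pi)
    # outer over channels: each channel gets its own phase
    sig <- sig + gains[b] * sin(outer(phase, 2 * pi * f0[b] * tt, `+`))
  }
  sig
}

#' Generate a synthetic affective-EEG dataset
#'
#' Produces one trial per subject x trial slot. Each stimulus segment is a
#' sum of four band-limited oscillations (one per canonical band, at the
#' band's geometric center frequency, random phase) whose amplitudes follow
#' the configured class gains for the trial's quadrant class, plus Gaussian
#' white noise. The baseline segment uses unit gains for every band (a
#' "resting" pre-stimulus state) so that baseline correction removes the
#' class-independent component. Valence/arousal ratings are drawn uniformly
#' from the high half (at or above the cutoff) or low half of the scale as
#' the quadrant requires. Output is bit-identical for equal configs.
#'
#' @param config A [synth_config()].
#' @return An object of class `eeg_trials`: a list of trials, each with
#'   `subject_id`, `trial_id`, `class` (0-3), `baseline_signal` and
#'   `stimulus_signal` (channels x samples matrices), `fs`, `valence`,
#'   `arousal`. The config is attached as attribute `config`.
#' @examples
#' trials <- generate_trials(synth_config(n_subjects = 1,
#'   n_trials_per_subject = 4, n_channels = 2, stimulus_s = 4))
#' length(trials)
#' @export
generate_trials <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_input("config must be a synth_config object")
  cutoff <- rating_cutoff(config$rating_scale_max)
  lo <- 1; hi <- config$rating_scale_max
  nb <- round(config$baseline_s * config$fs)
  ns <- round(config$stimulus_s * config$fs)
  trials <- with_seed(config$seed, {
    out <- vector("list", config$n_subjects * config$n_trials_per_subject)
    idx <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (tr in seq_len(config$n_trials_per_subject)) {
        idx <- idx + 1L
        cls <- (idx - 1L) %% 4L            # balanced cycling over quadrants
        gains <- config$class_band_gains[cls + 1L, ]
        base <- synth_segment(config$n_channels, nb, config$fs,
                              rep(1, 4), config$noise_sd)
        stim <- synth_segment(config$n_channels, ns, config$fs,
                              gains, config$noise_sd)
        hv <- cls %in% c(0L, 1L); ha <- cls %in% c(0L, 2L)
        valence <- if (hv) stats::runif(1, cutoff, hi) else stats::runif(1, lo, cutoff)
        arousal <- if (ha) stats::runif(1, cutoff, hi) else stats::runif(1, lo, cutoff)
        out[[idx]] <- list(subject_id = s, trial_id = tr, class = cls,
                           baseline_signal = base, stimulus_signal = stim,
                           fs = config$fs, valence = valence, arousal = arousal)
      }
    }
    out
  })
  structure(trials, class = "eeg_trials", config = config)
}

#' @export
print.eeg_trials <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<eeg_trials> %d trials, %d channels @ %g Hz, baseline %g s + stimulus %g s\n",
              length(x), nrow(x[[1]]$stimulus_signal), x[[1]]$fs,
              ncol(x[[1]]$baseline_signal) / x[[1]]$fs,
              ncol(x[[1]]$stimulus_signal) / x[[1]]$fs))
  if (!is.null(cfg))
    cat(sprintf("  rating scale 1-%g (cutoff %g), seed %d\n",
                cfg$rating_scale_max, rating_cutoff(cfg$rating_scale_max), cfg$seed))
  invisible(x)
}
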