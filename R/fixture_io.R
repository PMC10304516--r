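#' Write a trial dataset as an on-disk fixture
#'
#' Serializes a dataset in one of two container layouts mirroring the common
#' affective-EEG benchmarks:
#' \describe{
#'   \item{`deap_like`}{one continuous record per trial (baseline followed by
#'     stimulus, e.g. 3 s + 60 s = 63 s); the reader splits the first
#'     `baseline_s` seconds off as baseline.}
#'   \item{`dreamer_like`}{two records per trial, a separate baseline record
#'     (e.g. 61 s) and a stimulus record.}
#' }
#' The container is a directory holding a JSON manifest (layout, sampling
#' rate, per-trial ratings and file names), one full-precision TSV per
#' signal record (samples x channels), and, when the dataset was produced by
#' [generate_trials()], a JSON sidecar with the generating config for
#' provenance. The round trip through [read_trials()] is lossless.
#'
#' @param trials An `eeg_trials` object (or list of trial lists).
#' @param path Directory to create/write into.
#' @param layout `"deap_like"` or `"dreamer_like"`.
#' @return `path`, invisibly.
#' @seealso [read_trials()]
#' @export
write_trials <- function(trials, path, layout = c("deap_like", "dreamer_like")) {
  layout <- match.arg(layout)
  if (length(trials) == 0) stop_input("dataset is empty")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_input("cannot create fixture directory: %s", path)
  fs <- trials[[1]]$fs
  entries <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    stem <- sprintf("s%02d_t%03d", tr$subject_id, tr$trial_id)
    if (layout == "deap_like") {
      rec <- cbind(tr$baseline_signal, tr$stimulus_signal)  # channels x samples
      f <- paste0(stem, ".tsv")
      write_signal_tsv(t(rec), file.path(path, f))
      files <- list(record = f)
    } else {
      fb <- paste0(stem, "_baseline.tsv"); fsig <- paste0(stem, "_stimulus.tsv")
      write_signal_tsv(t(tr$baseline_signal), file.path(path, fb))
      write_signal_tsv(t(tr$stimulus_signal), file.path(path, fsig))
      files <- list(baseline = fb, stimulus = fsig)
    }
    # ratings as %.17g strings: doubles survive the JSON round trip exactly
    entries[[i]] <- c(list(subject_id = tr$subject_id, trial_id = tr$trial_id,
                           valence = sprintf("%.17g", tr$valence),
                           arousal = sprintf("%.17g", tr$arousal)), files)
  }
  cfg <- attr(trials, "config")
  manifest <- list(
    layout = layout, fs = fs,
    n_channels = nrow(trials[[1]]$stimulus_signal),
    baseline_s = ncol(trials[[1]]$baseline_signal) / fs,
    rating_scale_max = if (!is.null(cfg)) cfg$rating_scale_max else NULL,
    trials = entries
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cfg)) {
    side <- cfg
    side$class_band_gains <- as.data.frame(cfg$class_band_gains)
    jsonlite::write_json(unclass(side), file.path(path, "synth_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trial dataset from an on-disk fixture
#'
#' Counterpart of [write_trials()]. For `deap_like` containers the single
#' record per trial is split into the first `baseline_s` seconds of baseline
#' and the remaining stimulus; `dreamer_like` containers carry separate
#' baseline and stimulus records that are used as-is.
#'
#' @param path Fixture directory.
#' @param layout Expected layout; must match the manifest.
#' @return An `eeg_trials` object.
#' @export
read_trials <- function(path, layout = c("deap_like", "dreamer_like")) {
  layout <- match.arg(layout)
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_input("not a trial fixture (no manifest.json): %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(manifest$layout, layout))
    stop_input("fixture layout is '%s', expected '%s'", manifest$layout, layout)
  fs <- manifest$fs
  nb <- round(manifest$baseline_s * fs)
  n_channels <- manifest$n_channels
  trials <- vector("list", length(manifest$trials))
  for (i in seq_along(manifest$trials)) {
    e <- manifest$trials[[i]]
    who <- sprintf("trial (subject %s, trial %s)",
                   e$subject_id %||% "?", e$trial_id %||% "?")
    if (is.null(e$valence) || is.null(e$arousal))
      stop_input("format error: missing ratings for %s", who)
    if (layout == "deap_like") {
      rec <- t(read_signal_tsv(file.path(path, e$record)))  # channels x samples
      if (ncol(rec) <= nb)
        stop_input("format error: record shorter than baseline for %s", who)
      base <- rec[, seq_len(nb), drop = FALSE]
      stim <- rec[, (nb + 1):ncol(rec), drop = FALSE]
    } else {
      base <- t(read_signal_tsv(file.path(path, e$baseline)))
      stim <- t(read_signal_tsv(file.path(path, e$stimulus)))
    }
    if (nrow(base) != n_channels || nrow(stim) != n_channels)
      stop_input("format error: channel-count mismatch for %s (expected %d)",
                 who, n_channels)
    trials[[i]] <- list(subject_id = e$subject_id, trial_id = e$trial_id,
                        class = e$class %||% NULL,
                        baseline_signal = base, stimulus_signal = stim,
                        fs = fs, valence = as.numeric(e$valence),
                        arousal = as.numeric(e$arousal))
  }
  cfgf <- file.path(path, "synth_config.json")
  cfg <- NULL
  if (file.exists(cfgf)) {
    raw <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
    cfg <- synth_config(
      n_subjects = raw$n_subjects, n_trials_per_subject = raw$n_trials_per_subject,
      n_channels = raw$n_channels, fs = raw$fs, baseline_s = raw$baseline_s,
      stimulus_s = raw$stimulus_s, rating_scale_max = raw$rating_scale_max,
      class_band_gains = as.matrix(raw$class_band_gains),
      noise_sd = raw$noise_sd, seed = raw$seed)
  }
  structure(trials, class = "eeg_trials", config = cfg,
            rating_scale_max = manifest$rating_scale_max %||%
              (if (!is.null(cfg)) cfg$rating_scale_max else 9))
}
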