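#' Canonical EEG frequency bands
#'
#' The four rhythms used throughout the pipeline: theta (4-8 Hz),
#' alpha (8-14 Hz), beta (14-31 Hz) and gamma (31-45 Hz). Feature vectors
#' are ordered channel-major, band-minor in exactly this band order.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz), one row per
#'   band, ordered by lower edge.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    low  = c(4, 8, 14, 31),
    high = c(8, 14, 31, 45),
    stringsAsFactors = FALSE
  )
}

#' @noRd
validate_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands)))
    stop_input("bands must be a data.frame with columns name, low, high")
  if (any(bands$low >= bands$high))
    stop_input("each band must satisfy low < high")
  if (is.unsorted(bands$low))
    stop_input("bands must be ordered by their lower edge")
  bands
}

#' Quadrant class names
#'
#' Valence-arousal quadrant labels in their numeric encoding order:
#' 0 = HVHA, 1 = HVLA, 2 = LVHA, 3 = LVLA (H/L = high/low, V = valence,
#' A = arousal).
#'
#' @return Character vector of length 4.
#' @export
quadrant_classes <- function() c("HVHA", "HVLA", "LVHA", "LVLA")
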