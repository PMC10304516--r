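#' Valence-arousal quadrant label
#'
#' Maps ratings to the four quadrant classes: 0 = HVHA, 1 = HVLA, 2 = LVHA,
#' 3 = LVLA. A rating is "high" when it is at or above the cutoff (ratings
#' exactly at the cutoff go to the high half; the tie is measure-zero for
#' continuous ratings). Vectorized over ratings.
#'
#' @param valence,arousal Ratings in `[1, scale max]`.
#' @param cutoff High/low threshold (5 on the 1-9 scale, 2.5 on the 1-5
#'   scale; see [rating_cutoff()]).
#' @param scale_max Upper end of the rating scale, for validation.
#' @return Integer class labels in 0..3.
#' @examples
#' quadrant_label(7, 8, 5)   # 0 (HVHA)
#' quadrant_label(3, 2, 5)   # 3 (LVLA)
#' @export
quadrant_label <- function(valence, arousal, cutoff, scale_max = NULL) {
  if (is.null(scale_max)) scale_max <- if (cutoff >= 5) 9 else 5
  if (any(valence < 1 | valence > scale_max | arousal < 1 | arousal > scale_max))
    stop_input("ratings must lie in [1, %g]", scale_max)
  hv <- valence >= cutoff
  ha <- arousal >= cutoff
  as.integer(ifelse(hv, ifelse(ha, 0L, 1L), ifelse(ha, 2L, 3L)))
}

#' Random train/test split
#'
#' Uniform random partition into a training set of `floor(ratio * n)`
#' samples and a test set of the remaining `ceiling((1 - ratio) * n)`;
#' deterministic given the seed, disjoint and exhaustive.
#'
#' @param n Number of samples (or an object with a row count / length).
#' @param ratio Training fraction in (0, 1); default 0.8 (the 8:2 protocol).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, ratio = 0.8, seed = 1) {
  if (inherits(n, "feature_samples")) n <- nrow(n$de)
  n <- as.integer(n)
  if (n < 2) stop_input("need at least 2 samples to split")
  if (!(ratio > 0 && ratio < 1)) stop_input("ratio must be in (0, 1)")
  with_seed(seed, {
    tr <- sort(sample.int(n, floor(ratio * n)))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' @noRd
subset_features <- function(features, idx) {
  structure(list(de = features$de[idx, , drop = FALSE],
                 psd = features$psd[idx, , drop = FALSE],
                 label = features$label[idx],
                 subject = features$subject[idx], trial = features$trial[idx],
                 window = features$window[idx],
                 n_channels = features$n_channels, bands = features$bands,
                 fs = features$fs, window_s = features$window_s),
            class = "feature_samples")
}

#' Multiclass evaluation report
#'
#' Treats each of the four classes as a one-vs-rest binary problem and
#' reports per-class true/false positives/negatives, precision, recall and
#' F1 (in percent), the overall accuracy (the multiclass correct fraction),
#' macro averages over the classes, and the 4x4 confusion matrix (rows =
#' true class, columns = predicted). F1 is defined as 0 when
#' precision + recall = 0.
#'
#' @param y_true,y_pred Equal-length integer label vectors in 0..3.
#' @return An object of class `metrics_report`.
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop_input("empty input")
  if (length(y_true) != length(y_pred)) stop_input("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(c(y_true, y_pred) < 0 | c(y_true, y_pred) > 3))
    stop_input("labels must be in 0..3")
  K <- 4L; n <- length(y_true)
  lv <- factor(y_true, levels = 0:3)
  pv <- factor(y_pred, levels = 0:3)
  cm <- table(true = lv, pred = pv)
  per <- data.frame(class = quadrant_classes(), tp = NA_real_, fp = NA_real_,
                    tn = NA_real_, fn = NA_real_, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_)
  for (c in 0:(K - 1L)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[c + 1L, 2:8] <- c(tp, fp, tn, fn, 100 * prec, 100 * rec, 100 * f1)
  }
  structure(list(accuracy = 100 * mean(y_true == y_pred),
                 precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), per_class = per,
                 confusion = unclass(cm), n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.2f%%  macro P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`, where `var_i` are the
#' item (column) variances and `var_total` is the variance of the row sums.
#' Alpha is at most 1; negative values are possible for anti-correlated
#' items and are returned as-is.
#'
#' @param score_matrix Observations x items numeric matrix (>= 2 rows and
#'   >= 2 columns). By convention in the results tables, items are the
#'   metric columns and observations the model variants; transpose the
#'   input for the opposite orientation.
#' @return Scalar alpha.
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4)))  # 1: perfectly correlated
#' @export
cronbach_alpha <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_input("need >= 2 observations and >= 2 items")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop_input("zero total variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
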