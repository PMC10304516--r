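#' Configuration for the gradient-boosted classification head
#'
#' The head fits an additive tree ensemble: each round adds a tree
#' correcting the previous rounds' predictions, minimizing a regularized
#' softmax objective. The learning rate defaults to 0.25 per the training
#' protocol; the remaining hyperparameters are exposed with standard
#' defaults.
#'
#' @param eta Shrinkage (learning rate) in (0, 1].
#' @param nrounds Number of boosting rounds (>= 1).
#' @param max_depth Maximum tree depth.
#' @param lambda L2 regularization on leaf weights.
#' @param gamma Minimum loss reduction to split.
#' @param seed Integer seed.
#' @param nthread Threads; 1 (default) makes fitting fully deterministic.
#' @return A `boost_config` list.
#' @export
boost_config <- function(eta = 0.25, nrounds = 200, max_depth = 6,
                         lambda = 1, gamma = 0, seed = 1, nthread = 1) {
  if (!(eta > 0 && eta <= 1)) stop_input("eta must be in (0, 1]")
  if (nrounds < 1) stop_input("nrounds must be >= 1")
  structure(list(eta = eta, nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), lambda = lambda,
                 gamma = gamma, seed = as.integer(seed),
                 nthread = as.integer(nthread)), class = "boost_config")
}

#' Collect deep features at a named tap point
#'
#' Runs the trained network forward in inference mode (dropout off,
#' batch norm on running statistics) and collects, per sample, the
#' activations at the requested tap: `"No_FC"` is the fused feature vector
#' before the reduction network, `"IFC1"` to `"IFC5"` are the outputs of
#' its five fully connected blocks (widths 512, 1024, 256, 64, 4 at
#' default configuration).
#'
#' @param model A trained `fcan_model`.
#' @param features `feature_samples` (or list with `de`, `psd`, `label`).
#' @param tap One of `"No_FC"`, `"IFC1"` ... `"IFC5"`.
#' @return A `deep_features` object: list with matrix `x`, vector `label`,
#'   and the tap name.
#' @export
extract_deep_features <- function(model, features, tap = "IFC5") {
  if (!inherits(model, "fcan_model"))
    stop_input("model must be a trained fcan_model")
  tap <- match.arg(tap, c("No_FC", sprintf("IFC%d", 1:5)))
  fw <- fcan_forward(model, features)
  x <- if (tap == "No_FC") fw$fused else fw$taps[[tap]]
  structure(list(x = unname(as.matrix(x)), label = features$label, tap = tap),
            class = "deep_features")
}

#' Fit the boosted-tree head
#'
#' Multiclass softmax boosting on a feature matrix, via xgboost. With
#' `nthread = 1` the fit is deterministic given the seed.
#'
#' @param features A `deep_features` object, or a numeric matrix (then
#'   `label` must be given).
#' @param config A [boost_config()].
#' @param label Integer labels 0..K-1 when `features` is a bare matrix.
#' @return A `boost_model` wrapping the booster.
#' @export
train_boost <- function(features, config = boost_config(), label = NULL) {
  if (inherits(features, "deep_features")) {
    x <- features$x; y <- features$label
  } else {
    x <- as.matrix(features); y <- label
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop_input("boosting needs >= 2 classes")
  K <- max(4L, length(unique(y)))
  if (all(apply(x, 2, stats::sd) == 0))
    warning("all feature columns are constant; the booster cannot split")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = config$nthread)
  params <- list(objective = "multi:softprob", num_class = K,
                 eta = config$eta, max_depth = config$max_depth,
                 lambda = config$lambda, gamma = config$gamma,
                 nthread = config$nthread, seed = config$seed)
  booster <- with_seed(config$seed,
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = config$nrounds, verbose = 0))
  structure(list(booster = booster, n_features = ncol(x), num_class = K,
                 config = config), class = "boost_model")
}

#' @export
predict.boost_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "deep_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata)) || ncol(newdata) != object$n_features)
    stop_input("feature dimension mismatch: booster expects %d columns",
               object$n_features)
  p <- predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1))
  probs <- if (is.matrix(p)) p else matrix(p, ncol = object$num_class, byrow = TRUE)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf("<boost_model> %d-class softmax, %d rounds, depth %d, eta %g, %d features\n",
              x$num_class, x$config$nrounds, x$config$max_depth,
              x$config$eta, x$n_features))
  invisible(x)
}
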