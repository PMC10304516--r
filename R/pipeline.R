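#' Fit the full hybrid classifier
#'
#' The headline modelling function: splits the feature samples 8:2 into
#' train and test, trains the feature-attention network end to end
#' (cross-entropy, Adam), fits the boosted-tree head on the deep features
#' collected at the chosen tap, and evaluates on the held-out test set.
#'
#' @param features A `feature_samples` object (see [assemble_features()]).
#' @param fusion Fusion strategy (`"concat"` default; `"add"`, `"mult"`,
#'   `"de"`, `"psd"`).
#' @param placement Attention placement (`"before"`, `"none"`, `"after"`).
#' @param tap Tap whose activations feed the booster (default `"IFC5"`).
#' @param train_cfg A [train_config()].
#' @param boost_cfg A [boost_config()].
#' @param ratio Train fraction (default 0.8).
#' @param seed Split seed.
#' @return An object of class `fcan_xgboost` with components `fcan`
#'   (the trained network), `boost` (the booster), `split`, `metrics`
#'   (test-set `metrics_report`), and `history` (per-epoch losses).
#' @examples
#' \donttest{
#' cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 8,
#'                     n_channels = 4, stimulus_s = 10)
#' feats <- assemble_features(generate_trials(cfg))
#' fit <- fcan_xgboost(feats,
#'   train_cfg = train_config(epochs = 10, hidden = c(32, 16),
#'                            embed_dim = 16, fcn2_dims = c(32, 16, 8, 8, 4)),
#'   boost_cfg = boost_config(nrounds = 30))
#' fit$metrics$accuracy
#' }
#' @export
fcan_xgboost <- function(features, fusion = "concat", placement = "before",
                         tap = "IFC5", train_cfg = train_config(),
                         boost_cfg = boost_config(), ratio = 0.8, seed = 1) {
  sp <- split_train_test(nrow(features$de), ratio, seed)
  tr <- subset_features(features, sp$train)
  te <- subset_features(features, sp$test)
  fcan <- train_fcan(tr, train_cfg, fusion = fusion, placement = placement)
  boost <- train_boost(extract_deep_features(fcan, tr, tap), boost_cfg)
  pred <- predict(boost, extract_deep_features(fcan, te, tap))
  metrics <- compute_metrics(te$label, pred)
  structure(list(fcan = fcan, boost = boost, tap = tap, fusion = fusion,
                 placement = placement, split = sp, metrics = metrics,
                 history = fcan$history, n_features = ncol(features$de)),
            class = "fcan_xgboost")
}

#' @export
predict.fcan_xgboost <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  df <- extract_deep_features(object$fcan, newdata, object$tap)
  predict(object$boost, df, type = type)
}

#' @export
print.fcan_xgboost <- function(x, ...) {
  cat(sprintf("<fcan_xgboost> fusion=%s, attention=%s, tap=%s\n",
              x$fusion, x$placement, x$tap))
  cat(sprintf("  test accuracy %.2f%% (n=%d)\n", x$metrics$accuracy, x$metrics$n))
  invisible(x)
}

#' @export
summary.fcan_xgboost <- function(object, ...) {
  cat("Hybrid feature-attention + boosted-tree classifier\n")
  cat(sprintf("  fusion: %s   attention placement: %s   booster tap: %s\n",
              object$fusion, object$placement, object$tap))
  cat(sprintf("  network epochs trained: %d (final lr %.2g)\n",
              nrow(object$history), object$history$lr[nrow(object$history)]))
  cat(sprintf("  split: %d train / %d test\n",
              length(object$split$train), length(object$split$test)))
  cat("\nTest-set metrics:\n")
  print(object$metrics)
  invisible(object)
}

#' @export
plot.fcan_xgboost <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Aggregates every knob of an end-to-end run: the data source (a synthetic
#' generator config or a fixture path + layout), the analysis window, the
#' model variant, the training and boosting configs, the split and the seed.
#'
#' @param source A [synth_config()] or a list `list(path =, layout =)`.
#' @param window_s Analysis window in seconds (default 2).
#' @param fusion,placement,tap Model variant (see [fcan_xgboost()]).
#' @param train_cfg,boost_cfg Stage configs.
#' @param ratio Train fraction.
#' @param seed Split seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(source = synth_config(), window_s = 2,
                            fusion = "concat", placement = "before",
                            tap = "IFC5", train_cfg = train_config(),
                            boost_cfg = boost_config(), ratio = 0.8,
                            seed = 1) {
  if (window_s <= 0) stop_input("window_s must be positive")
  structure(list(source = source, window_s = window_s, fusion = fusion,
                 placement = placement, tap = tap, train_cfg = train_cfg,
                 boost_cfg = boost_cfg, ratio = ratio,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; nested `synth`, `train` and `boost`
#' blocks are passed to [synth_config()], [train_config()] and
#' [boost_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  source <- if (!is.null(y$fixture))
    list(path = y$fixture$path, layout = y$fixture$layout)
  else do.call(synth_config, y$synth %||% list())
  pipeline_config(
    source = source,
    window_s = y$window_s %||% 2,
    fusion = y$fusion %||% "concat",
    placement = y$placement %||% "before",
    tap = y$tap %||% "IFC5",
    train_cfg = do.call(train_config, y$train %||% list()),
    boost_cfg = do.call(boost_config, y$boost %||% list()),
    ratio = y$ratio %||% 0.8,
    seed = y$seed %||% 1)
}

#' @noRd
pipeline_features <- function(config) {
  trials <- if (inherits(config$source, "synth_config"))
    generate_trials(config$source)
  else read_trials(config$source$path, config$source$layout)
  assemble_features(trials, window_s = config$window_s)
}

#' @noRd
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full pipeline and write its artifacts
#'
#' Executes generate/read -> preprocess + feature extraction -> network
#' training -> deep-feature extraction -> boosting -> prediction -> metrics,
#' logging each stage, and writes to `out_dir`: `provenance.json` (full
#' config, seeds, package and R versions), `metrics.json`, `confusion.csv`,
#' `history.csv` and `features.csv`. Reruns with the same config are
#' identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing artifacts.
#' @return The fitted [fcan_xgboost()] object, invisibly; its `metrics`
#'   component is the evaluation report.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage("data", "source=%s",
            if (inherits(config$source, "synth_config")) "synthetic" else "fixture")
  feats <- pipeline_features(config)
  log_stage("features", "%d windows x %d features", nrow(feats$de), ncol(feats$de))
  fit <- fcan_xgboost(feats, fusion = config$fusion,
                      placement = config$placement, tap = config$tap,
                      train_cfg = config$train_cfg,
                      boost_cfg = config$boost_cfg,
                      ratio = config$ratio, seed = config$seed)
  log_stage("evaluate", "test accuracy %.2f%%", fit$metrics$accuracy)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(
      package = "fcanxgb",
      package_version = as.character(utils::packageVersion("fcanxgb")),
      r_version = R.version.string,
      config = rapply(unclass(config), function(x)
        if (is.matrix(x)) as.data.frame(x) else x, how = "replace"),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    m <- fit$metrics
    jsonlite::write_json(
      list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
           f1 = m$f1, n_test = m$n, per_class = m$per_class),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(m$confusion),
                     file.path(out_dir, "confusion.csv"), row.names = FALSE)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    write_features(feats, file.path(out_dir, "features.csv"))
    saveRDS(fit$fcan, file.path(out_dir, "fcan_model.rds"))
    xgboost::xgb.save(fit$boost$booster, file.path(out_dir, "booster.json"))
    log_stage("artifacts", "written to %s", out_dir)
  }
  invisible(fit)
}

#' Run an ablation experiment end to end
#'
#' Builds (or reads) the dataset from the pipeline config, extracts
#' features once, and delegates to [run_ablation()] with a shared split.
#'
#' @param config A [pipeline_config()].
#' @param experiment `"fusion"`, `"fanet"` or `"tap"` (also accepts the
#'   full names used by [run_ablation()]).
#' @param out_dir Optional directory; the table is written as
#'   `ablation_<experiment>.csv`.
#' @return The `ablation_table`.
#' @export
run_experiments <- function(config = pipeline_config(),
                            experiment = c("fusion", "fanet", "tap"),
                            out_dir = NULL) {
  experiment <- match.arg(experiment[1],
                          c("fusion", "fanet", "tap",
                            "fusion_strategies", "fanet_placement", "tap_depth"))
  key <- switch(experiment,
                fusion = , fusion_strategies = "fusion_strategies",
                fanet = , fanet_placement = "fanet_placement",
                tap = , tap_depth = "tap_depth")
  feats <- pipeline_features(config)
  tab <- run_ablation(key, feats, train_cfg = config$train_cfg,
                      boost_cfg = config$boost_cfg, ratio = config$ratio,
                      seed = config$seed, tap = config$tap)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, sprintf("ablation_%s.csv", key)),
                     row.names = FALSE)
  }
  tab
}
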