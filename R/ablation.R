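#' Ablation experiments
#'
#' Trains and evaluates a family of model variants on one shared train/test
#' split and tabulates accuracy, macro precision, recall and F1 (percent)
#' per variant, mirroring the method's three ablation studies:
#' \describe{
#'   \item{`fusion_strategies`}{rows `DE`, `PSD` (single-branch models),
#'     `Xadd`, `Xmult`, `Xcon` (elementwise sum, product, concatenation).}
#'   \item{`fanet_placement`}{rows `FCAN-XGBoost` (attention gating on each
#'     branch before fusion), `FCN-XGBoost` (gating removed), `AF` (one
#'     gating branch after fusion).}
#'   \item{`tap_depth`}{rows `No_FC`, `IFC1` ... `IFC5`: one trained
#'     concatenation model, with the booster fitted on the fused features or
#'     on each reduction-network block output in turn.}
#' }
#' Cronbach's alpha across the table's metric columns (items = metrics,
#' observations = variants) is attached as attribute `"alpha"`.
#'
#' @param experiment `"fusion_strategies"`, `"fanet_placement"` or
#'   `"tap_depth"`.
#' @param features A `feature_samples` object.
#' @param train_cfg A [train_config()].
#' @param boost_cfg A [boost_config()].
#' @param ratio,seed Train/test split fraction and seed (shared by all
#'   variants).
#' @param tap Tap fed to the booster for the fusion/placement experiments.
#' @return A data.frame of class `ablation_table` with columns `variant`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
run_ablation <- function(experiment = c("fusion_strategies", "fanet_placement",
                                        "tap_depth"),
                         features, train_cfg = train_config(),
                         boost_cfg = boost_config(), ratio = 0.8, seed = 1,
                         tap = "IFC5") {
  experiment <- match.arg(experiment)
  sp <- split_train_test(nrow(features$de), ratio, seed)
  tr <- subset_features(features, sp$train)
  te <- subset_features(features, sp$test)
  eval_variant <- function(model, tap) {
    bm <- train_boost(extract_deep_features(model, tr, tap), boost_cfg)
    pred <- predict(bm, extract_deep_features(model, te, tap))
    compute_metrics(te$label, pred)
  }
  rows <- switch(experiment,
    fusion_strategies = {
      variants <- c(DE = "de", PSD = "psd", Xadd = "add", Xmult = "mult",
                    Xcon = "concat")
      lapply(variants, function(fu) {
        eval_variant(train_fcan(tr, train_cfg, fusion = fu,
                                placement = "before"), tap)
      })
    },
    fanet_placement = {
      variants <- c(`FCAN-XGBoost` = "before", `FCN-XGBoost` = "none",
                    AF = "after")
      lapply(variants, function(pl) {
        eval_variant(train_fcan(tr, train_cfg, fusion = "concat",
                                placement = pl), tap)
      })
    },
    tap_depth = {
      model <- train_fcan(tr, train_cfg, fusion = "concat",
                          placement = "before")
      taps <- c("No_FC", sprintf("IFC%d", 1:5))
      names(taps) <- taps
      lapply(taps, function(tp) eval_variant(model, tp))
    })
  tab <- data.frame(
    variant = names(rows),
    accuracy = vapply(rows, `[[`, numeric(1), "accuracy"),
    precision = vapply(rows, `[[`, numeric(1), "precision"),
    recall = vapply(rows, `[[`, numeric(1), "recall"),
    f1 = vapply(rows, `[[`, numeric(1), "f1"),
    row.names = NULL)
  alpha <- tryCatch(
    cronbach_alpha(as.matrix(tab[, c("accuracy", "precision", "recall", "f1")])),
    error = function(e) NA_real_)
  structure(tab, class = c("ablation_table", "data.frame"),
            experiment = experiment, alpha = alpha)
}

#' @export
print.ablation_table <- function(x, ...) {
  cat(sprintf("Ablation: %s (Cronbach's alpha over metric columns: %s)\n",
              attr(x, "experiment"),
              ifelse(is.na(attr(x, "alpha")), "NA",
                     sprintf("%.3f", attr(x, "alpha")))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
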