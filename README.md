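# fcanxgb

Four-quadrant emotion recognition from multichannel EEG: band-power
feature extraction, a feature-attention network, and a gradient-boosted
classification head, with a synthetic-EEG harness so the whole pipeline is
testable without access to license-gated recordings.

## The problem and the model

Affective-EEG studies rate each stimulus trial on valence and arousal;
thresholding both ratings at a cutoff (5 on a 1–9 scale, 2.5 on a 1–5
scale) partitions trials into four quadrant classes — HVHA, HVLA, LVHA,
LVLA, encoded 0–3. The classifier works on two spectral features computed
per 2 s window, channel, and canonical band (theta 4–8, alpha 8–14, beta
14–31, gamma 31–45 Hz), after zero-phase Butterworth band-pass filtering
and trial-wise baseline correction:

* **differential entropy** — for an approximately Gaussian band-limited
  window, `DE = ½ log(2πe σ²)` (nats), computed from the window's sample
  variance;
* **band power** — the mean periodogram power `|DFT|²/M` over the
  frequency bins inside the band (the periodogram is the transform of the
  biased autocorrelation, per Wiener–Khinchin).

With 32 channels each window yields one 128-long DE vector and one
128-long PSD vector. Both pass through parallel fully connected embedding
branches (`in → 1024 → 256 → 128`, ReLU/batch-norm/dropout), each
embedding is re-weighted by a convolutional attention branch (max-pool →
two valid 1-D convolutions → logistic-squashed linear layer producing
per-feature gates in (0,1); shape chain 128 → 126 → 64 → 32 → 128), the
gated embeddings are fused (concatenation, length 256), and a reduction
network `256 → 512 → 1024 → 256 → 64 → 4` produces tapped deep features
(IFC1…IFC5). A gradient-boosted tree ensemble (learning rate 0.25)
classifies the activations at a chosen tap, IFC5 by default. The network
trains with Adam (lr 0.001), cross-entropy, plateau lr decay and early
stopping on an 8:2 subject-mixed split.

The neural network, features and evaluation harness are implemented in
base R (with hand-written backprop, verified against finite differences in
the tests); boosting uses the xgboost package.

## Worked example

Synthetic data emulates the benchmark protocols: per-trial baseline +
stimulus segments whose band-limited oscillations carry class-dependent
amplitudes (by default each quadrant class boosts one distinctive rhythm
3×), plus white noise.

```r
library(fcanxgb)

cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 16,
                    n_channels = 8, stimulus_s = 20, seed = 5)
feats <- assemble_features(generate_trials(cfg))
feats
#> <feature_samples> 320 windows x 32 features (8 channels x 4 bands)
#>   class counts: HVHA=80 HVLA=80 LVHA=80 LVLA=80

fit <- fcan_xgboost(feats,
  train_cfg = train_config(epochs = 20, hidden = c(64, 32), embed_dim = 16,
                           fcn2_dims = c(32, 32, 16, 8, 4), batch_size = 64,
                           seed = 2),
  boost_cfg = boost_config(nrounds = 50))
summary(fit)
#> Hybrid feature-attention + boosted-tree classifier
#>   fusion: concat   attention placement: before   booster tap: IFC5
#>   network epochs trained: 20 (final lr 0.001)
#>   split: 256 train / 64 test
#>
#> Test-set metrics:
#> <metrics_report> n=64  accuracy 100.00%  macro P 100.00%  R 100.00%  F1 100.00%
#>     pred
#> true  0  1  2  3
#>    0 13  0  0  0
#>    1  0 16  0  0
#>    2  0  0 18  0
#>    3  0  0  0 17
```

The accuracy/precision/recall/F1 lines are test-set percentages (macro
averages over the four one-vs-rest problems); the confusion matrix rows
are true classes. On this strongly separable synthetic study the hybrid
recovers the classes perfectly; with `default_band_gains(contrast = 1)` or
shuffled labels it collapses to chance (~25%), which is the designed
behavior, not a bug.

Ablations over fusion strategies, attention placement, or booster tap
depth run on one shared split:

```r
run_ablation("fusion_strategies", feats,
  train_cfg = train_config(epochs = 8, hidden = c(32, 16), embed_dim = 16,
                           fcn2_dims = c(24, 16, 12, 8, 4), batch_size = 32,
                           dropout = 0.2, seed = 7),
  boost_cfg = boost_config(nrounds = 30), seed = 2)
#> Ablation: fusion_strategies (Cronbach's alpha over metric columns: 0.994)
#>  variant accuracy precision recall    f1
#>       DE    98.44     98.33  98.33 98.28
#>      PSD    93.75     94.44  93.79 93.61
#>     Xadd    98.44     98.44  98.44 98.39
#>    Xmult    96.88     97.22  97.37 97.14
#>     Xcon    95.31     96.05  94.64 94.86
```

(At this toy scale the fusion variants are statistically indistinguishable
— every strategy is near ceiling.)

A thin command-line wrapper with verbs `synth`, `features`, `train`,
`evaluate`, `ablate` lives at `inst/cli/fcanxgb.R`; see
`vignettes/methods.Rmd` for the modelling choices, tunable parameters and
limitations.

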