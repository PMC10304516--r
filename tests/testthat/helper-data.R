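# Shared small fixtures, built once per test run.

# 32 trials x 4 windows = 128 windows of 16 features (4 channels x 4 bands),
# strongly separable classes.
small_feats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 16,
                          n_channels = 4, stimulus_s = 8, seed = 42)
      cache <<- assemble_features(generate_trials(cfg))
    }
    cache
  }
})

# A reduced-width training config that converges in seconds on small_feats().
tiny_train_cfg <- function(epochs = 8, seed = 7, dropout = 0.2, ...) {
  train_config(epochs = epochs, hidden = c(32, 16), embed_dim = 16,
               fcn2_dims = c(24, 16, 12, 8, 4), batch_size = 32,
               dropout = dropout, seed = seed, ...)
}

tiny_boost_cfg <- function(...) boost_config(nrounds = 30, max_depth = 4, ...)
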