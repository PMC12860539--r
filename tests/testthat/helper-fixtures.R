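# Shared fixtures. The reference-scale study (1000 training / 2000
# validation trajectories, three training seeds) is expensive, so it is
# built lazily once per test session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# Small dataset for unit tests of the surrogate layer.
small_dataset <- function() {
  # 140 training trajectories keep the 127-column OLS design full rank
  if (is.null(.fixtures$small_ds))
    .fixtures$small_ds <- generate_dataset(n_train = 140, n_val = 60,
                                           seed = 4242)
  .fixtures$small_ds
}

# The reduced-scale reproduction study: dataset and all trained models.
study_dataset <- function() {
  if (is.null(.fixtures$study_ds))
    .fixtures$study_ds <- generate_dataset(n_train = 1000, n_val = 2000,
                                           seed = 20260101)
  .fixtures$study_ds
}

study_ols <- function() {
  if (is.null(.fixtures$study_ols))
    .fixtures$study_ols <- train_ols(study_dataset())
  .fixtures$study_ols
}

study_mlp <- function(seed) {
  key <- paste0("study_mlp_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- train_mlp(study_dataset(), seed = seed)
  .fixtures[[key]]
}

study_ffnn <- function(seed) {
  key <- paste0("study_ffnn_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- train_ffnn(study_dataset(), lr = 0.005, scale = 0.2,
                                   epochs = 500, seed = seed)
  .fixtures[[key]]
}
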