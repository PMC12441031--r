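# Small synthetic tables and short training configs shared across tests.

tiny_table <- function(n = 12, seed = 42) {
  simulate_feature_table(n = n, seed = seed)
}

short_train <- function(epochs = 5L, seed = 1L, ...) {
  train_config(epochs_stage1 = epochs, epochs_stage2 = epochs,
               seed = seed, ...)
}
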