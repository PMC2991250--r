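# Heavy end-to-end runs are shared across test files.
.ow_test_cache <- new.env(parent = emptyenv())

cached_experiment <- function(seed) {
  key <- paste0("ex", seed)
  if (is.null(.ow_test_cache[[key]])) {
    .ow_test_cache[[key]] <- run_reconciliation_experiment(synth_config(),
                                                           seed = seed)
  }
  .ow_test_cache[[key]]
}

small_cfg <- function(...) {
  synth_config(n_genes = 120, pos_rate = 0.02, ...)
}

cached_small_experiment <- function(seed) {
  key <- paste0("sm", seed)
  if (is.null(.ow_test_cache[[key]])) {
    .ow_test_cache[[key]] <- run_reconciliation_experiment(small_cfg(),
                                                           seed = seed)
  }
  .ow_test_cache[[key]]
}
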