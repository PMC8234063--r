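# Shared test fixtures, built in code and memoised per test run.

.cache <- new.env(parent = emptyenv())

# Small full-range database (lengths 5..30): same structure as the real one,
# cheap to enumerate, with a restricted-limit attribute of its own.
small_db <- function(backbone = "DNA") {
  key <- paste0("db_", backbone)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- build_oligo_db(backbone, 5, 30)
  }
  .cache[[key]]
}

# Quick low-order model over the small database, for prediction/scoring
# tests that need a fitted model but not the full-scale fit.
small_model <- function(backbone = "DNA", order = 6) {
  key <- paste0("model_", backbone, "_", order)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- train_oligo_model(small_db(backbone), order = order,
                                       subsample = 5000, seed = 42)
  }
  .cache[[key]]
}

# Random small elemental formulas for oracle-equivalence property tests.
random_formulas <- function(n, max_atoms = 500, seed = 99) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      els <- sample(c("C", "H", "N", "O", "P", "S", "F"),
                    size = sample(2:5, 1))
      counts <- sample(1:floor(max_atoms / length(els)), length(els),
                       replace = TRUE)
      stats::setNames(counts, els)
    })
  })
}
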