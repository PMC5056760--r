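# Shared fixtures, built in code. The heavier ones are memoized so several
# test files can reuse one computation.

memoize <- function(fn) {
  cache <- new.env(parent = emptyenv())
  function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (!exists(key, cache)) assign(key, fn(...), cache)
    get(key, cache)
  }
}

# a small strong-signal synthetic world plus 75/25 sets, in full mode
small_full_bundle <- memoize(function(seed = 11L) {
  cfg <- synthetic_config(n_transcripts = 60L, seed = seed)
  b <- generate_dataset(cfg)
  b$trans$mode <- "full"
  sp <- split_dataset(b$positives, seed = derive_seed_fx(seed, 1))
  negpool <- sample_negatives(b$trans, b$positives, 500L,
                              seed = derive_seed_fx(seed, 2))
  b$train <- build_training_set(sp$train, negpool,
                                seed = derive_seed_fx(seed, 3))
  b$test <- build_test_set(sp$test, negpool, ratio = 5L, exclude = b$train,
                           seed = derive_seed_fx(seed, 4))
  b
})

# compact grid keeps the SMO work in unit tests to seconds
test_config <- function(...) {
  pipeline_config(C_grid = c(1, 32), gamma_grid = 2^c(-12, -9), grid_folds = 3L,
                  n_shuffles = 20L, ...)
}

small_full_predictor <- memoize(function(seed = 11L) {
  b <- small_full_bundle(seed)
  train_predictor(b$train, b$trans, mode = "full", config = test_config(),
                  seed = 99L)
})

# a tiny mature-mode world: fewer sites because every feature vector folds
# 101-nt windows (20 shuffles each here, scaled down from the default 100
# purely for runtime)
small_mature_bundle <- memoize(function(seed = 21L) {
  cfg <- synthetic_config(n_transcripts = 30L, n_positive = 45L, seed = seed)
  b <- generate_dataset(cfg)
  sp <- split_dataset(b$positives, seed = derive_seed_fx(seed, 1))
  negpool <- sample_negatives(b$trans, b$positives, 150L,
                              seed = derive_seed_fx(seed, 2))
  b$train <- build_training_set(sp$train, negpool,
                                seed = derive_seed_fx(seed, 3))
  b$test <- build_test_set(sp$test, negpool, ratio = 3L, exclude = b$train,
                           seed = derive_seed_fx(seed, 4))
  b
})

# calibrated on the held-out split so the stringency thresholds are
# meaningful for unseen sequence (see the methods vignette)
small_mature_predictor <- memoize(function(seed = 21L) {
  b <- small_mature_bundle(seed)
  train_predictor(b$train, b$trans, mode = "mature",
                  config = test_config(), calibration_sites = b$test,
                  seed = 77L)
})

# tests cannot reach the package-internal helper under load_package =
# "installed", so mirror the arithmetic here
derive_seed_fx <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 10007) %% 2147483629)
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(mapply(function(id, s) c(paste0(">", id), s),
                           names(records), records, SIMPLIFY = FALSE)),
             path)
  path
}
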