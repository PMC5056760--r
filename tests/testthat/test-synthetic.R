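test_that("background transcripts respect lengths and base frequencies", {
  cfg <- synthetic_config(n_transcripts = 120L, length_range = c(600L, 1200L),
                          background_freq = c(A = 0.3, C = 0.2, G = 0.2,
                                              T = 0.3), seed = 5L)
  tr <- generate_background(cfg)
  lens <- nchar(tr$seq)
  expect_true(all(lens >= 600 & lens <= 1200))
  expect_gt(sum(lens), 100000)   # enough sequence for a tight LLN check
  freq <- table(strsplit(paste(tr$seq, collapse = ""), "")[[1]])
  freq <- as.numeric(freq / sum(freq))
  expect_true(all(abs(freq - c(0.3, 0.2, 0.2, 0.3)) < 0.02))
  expect_identical(tr, generate_background(cfg))  # seed determinism
})

test_that("planted sites are DRACH-conformant, spaced, and 3'-biased", {
  cfg <- synthetic_config(n_transcripts = 80L, seed = 17L)
  b <- generate_dataset(cfg)
  expect_equal(nrow(b$positives), cfg$n_positive)

  # every planted site is recovered by the scanner
  hits <- scan_drach(b$trans)
  keys <- paste(hits$transcript_id, hits$pos)
  expect_true(all(paste(b$positives$transcript_id, b$positives$pos) %in% keys))

  # pairwise spacing >= 50 within each transcript
  by_tr <- split(b$positives$pos, b$positives$transcript_id)
  gaps <- unlist(lapply(by_tr, function(p) diff(sort(p))))
  expect_true(all(gaps >= cfg$min_spacing))

  # 3' bias: mean relative position beyond the midpoint
  lens <- nchar(b$trans$seq[match(b$positives$transcript_id, b$trans$id)])
  expect_gt(mean(b$positives$pos / (lens - 1)), 0.55)

  # and no bias when it is turned off
  cfg0 <- synthetic_config(n_transcripts = 80L, three_prime_bias = 0,
                           seed = 18L)
  b0 <- generate_dataset(cfg0)
  lens0 <- nchar(b0$trans$seq[match(b0$positives$transcript_id, b0$trans$id)])
  expect_lt(abs(mean(b0$positives$pos / (lens0 - 1)) - 0.5), 0.06)
})

test_that("zero-strength planting leaves flanks at background composition", {
  cfg <- synthetic_config(n_transcripts = 100L, profile_strength = 0,
                          three_prime_bias = 0, seed = 19L)
  b <- generate_dataset(cfg)
  flanks <- unlist(lapply(seq_len(nrow(b$positives)), function(i) {
    tr <- b$trans$seq[b$trans$id == b$positives$transcript_id[i]]
    w <- extract_window(tr, b$positives$pos[i], 5L)
    strsplit(paste0(substring(w, 1, 3), substring(w, 9, 11)), "")[[1]]
  }))
  freq <- table(flanks)[c("A", "C", "G", "T")] / length(flanks)
  expect_true(all(abs(freq - 0.25) < 0.04))
})

test_that("the manifest regenerates the bundle bit-identically", {
  cfg <- synthetic_config(n_transcripts = 25L, seed = 31L)
  dir <- tempfile()
  b <- generate_dataset(cfg, dir = dir)
  expect_true(all(file.exists(unlist(b$paths))))
  m <- jsonlite::read_json(b$paths$manifest, simplifyVector = TRUE)
  cfg2 <- synthetic_config(n_transcripts = m$n_transcripts,
                           length_range = m$length_range,
                           background_freq = unlist(m$background_freq),
                           n_positive = m$n_positive,
                           profile_strength = m$profile_strength,
                           three_prime_bias = m$three_prime_bias,
                           structure_signal = m$structure_signal,
                           structure_fraction = m$structure_fraction,
                           min_spacing = m$min_spacing,
                           seed = m$seed)
  b2 <- generate_dataset(cfg2)
  expect_identical(b$trans, b2$trans)
  expect_identical(b$positives, b2$positives)

  # round-trip through the files reproduces the records
  tr_back <- read_fasta(b$paths$fasta)
  expect_equal(tr_back$seq, b$trans$seq)
  sites_back <- read_sites_tsv(b$paths$sites)
  expect_equal(nrow(sites_back), nrow(b$positives))
})

test_that("structure signal makes planted windows fold more stably", {
  cfg <- synthetic_config(n_transcripts = 30L, n_positive = 24L,
                          structure_signal = TRUE, structure_fraction = 1,
                          seed = 41L)
  b <- generate_dataset(cfg)
  cfg_plain <- synthetic_config(n_transcripts = 30L, n_positive = 24L,
                                structure_signal = FALSE, seed = 41L)
  bp <- generate_dataset(cfg_plain)
  z_stem <- vapply(1:8, function(i) {
    tr <- b$trans$seq[b$trans$id == b$positives$transcript_id[i]]
    mfe_zscore(extract_window(tr, b$positives$pos[i], 50L),
               n_shuffles = 25, seed = i)
  }, 0)
  z_plain <- vapply(1:8, function(i) {
    tr <- bp$trans$seq[bp$trans$id == bp$positives$transcript_id[i]]
    mfe_zscore(extract_window(tr, bp$positives$pos[i], 50L),
               n_shuffles = 25, seed = i)
  }, 0)
  expect_lt(mean(z_stem), mean(z_plain))
})

test_that("held-out AUROC rises with planted signal strength", {
  aucs <- vapply(c(0, 0.5, 1), function(s) {
    cfg <- synthetic_config(n_transcripts = 40L, n_positive = 80L,
                            profile_strength = s, three_prime_bias = 0,
                            seed = 51L)
    b <- generate_dataset(cfg)
    b$trans$mode <- "full"
    sp <- split_dataset(b$positives, seed = 52L)
    negpool <- sample_negatives(b$trans, b$positives, 260L, seed = 53L)
    trs <- build_training_set(sp$train, negpool, seed = 54L)
    tes <- build_test_set(sp$test, negpool, ratio = 3L, exclude = trs,
                          seed = 55L)
    pred <- train_predictor(trs, b$trans, mode = "full",
                            config = pipeline_config(C = 8, gamma = 2^-10),
                            seed = 56L)
    evaluate_independent(pred, tes, b$trans)$auroc
  }, 0)
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.70)
  expect_gt(aucs[3], 0.85)
})
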