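test_that("peak windows center on the summit with truncation and fallback", {
  tr <- transcripts("t", random_seq_fixed(2000), mode = "mature")
  pk <- data.frame(chrom = "t", start = 900L, end = 1100L, summit = 1000L)
  w <- peak_window(pk, tr)
  expect_equal(w$offset, 900L)
  expect_equal(nchar(w$seq), 200L)
  expect_equal(w$seq, substring(tr$seq, 901, 1100))

  # summit near the 5' end: window truncates to [0, 150) is re-anchored to
  # keep the full width when possible
  pk2 <- data.frame(chrom = "t", start = 0L, end = 120L, summit = 50L)
  w2 <- peak_window(pk2, tr)
  expect_equal(w2$offset, 0L)
  expect_equal(nchar(w2$seq), 200L)

  # no summit column: midpoint fallback
  pk3 <- data.frame(chrom = "t", start = 400L, end = 600L)
  w3 <- peak_window(pk3, tr)
  expect_equal(w3$center, 500L)

  expect_error(peak_window(data.frame(chrom = "t", start = 10L, end = 20L,
                                      summit = 50L), tr), "outside")
  expect_error(peak_window(data.frame(chrom = "nope", start = 1L, end = 9L),
                           tr), "unknown transcript")
})

test_that("peaks without a DRACH candidate are filtered out", {
  seqs <- c(paste0(strrep("A", 95), "GGACT", strrep("A", 100)),
            strrep("A", 200))
  tr <- transcripts(c("with", "without"), seqs, mode = "mature")
  peaks <- data.frame(chrom = c("with", "without"),
                      start = c(0L, 0L), end = c(200L, 200L))
  fl <- filter_drach_peaks(peaks, tr)
  expect_equal(fl$kept$chrom, "with")
  expect_equal(fl$removed$chrom, "without")
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(peaks))
  # idempotent on the kept set
  fl2 <- filter_drach_peaks(fl$kept, tr)
  expect_equal(fl2$kept, fl$kept)
  expect_equal(nrow(fl2$removed), 0L)
})

test_that("assigned peak sites stay inside their windows and summarize sanely", {
  b <- small_mature_bundle()
  pred <- small_mature_predictor()
  # peaks centered on planted sites (the MeRIP mimic)
  pos <- b$positives[1:8, ]
  lens <- nchar(b$trans$seq[match(pos$transcript_id, b$trans$id)])
  peaks <- data.frame(chrom = pos$transcript_id,
                      start = pmax(0L, pos$pos - 75L),
                      end = pmin(lens, pos$pos + 75L),
                      summit = pos$pos)
  res <- assign_peak_sites(peaks, b$trans, pred, level = "moderate",
                           seed = 31)
  expect_equal(res$summary$n_peaks_in, 8L)
  expect_gte(res$summary$frac_ge1, 0)
  expect_lte(res$summary$frac_ge1, 1)
  expect_lte(res$summary$frac_ge2, res$summary$frac_ge1)
  # every reported site lies inside its peak window (the window re-anchors
  # at sequence ends, so bounds come from peak_window itself)
  kept <- filter_drach_peaks(peaks, b$trans)$kept
  for (i in seq_len(nrow(res$sites))) {
    s <- res$sites[i, ]
    w <- peak_window(kept[s$peak_index, , drop = FALSE], b$trans)
    expect_gte(s$pos, w$offset)
    expect_lt(s$pos, w$offset + nchar(w$seq))
    expect_equal(s$context, "peak_window")
  }
  # counts reproducible from the same inputs
  res2 <- assign_peak_sites(peaks, b$trans, pred, level = "moderate",
                            seed = 31)
  expect_identical(res$summary, res2$summary)
})

test_that("planted-signal peaks recover more sites than shuffled peaks", {
  b <- small_mature_bundle()
  pred <- small_mature_predictor()
  pos <- b$positives[1:10, ]
  lens <- nchar(b$trans$seq[match(pos$transcript_id, b$trans$id)])
  peaks <- data.frame(chrom = pos$transcript_id,
                      start = pmax(0L, pos$pos - 60L),
                      end = pmin(lens, pos$pos + 60L),
                      summit = pos$pos)
  real <- assign_peak_sites(peaks, b$trans, pred, seed = 32)

  # paired control: same peaks on composition-shuffled transcripts
  sh_trans <- b$trans
  set.seed(33)
  sh_trans$seq <- vapply(sh_trans$seq, shuffle_sequence, "")
  sh <- assign_peak_sites(peaks, sh_trans, pred, seed = 32)
  expect_gt(real$summary$frac_ge1, sh$summary$frac_ge1)
})

test_that("a non-mature model draws a warning for peak assignment", {
  b <- small_mature_bundle()
  fullpred <- small_full_predictor()
  pos <- b$positives[1, ]
  peaks <- data.frame(chrom = pos$transcript_id, start = pos$pos - 20L,
                      end = pos$pos + 20L)
  expect_warning(assign_peak_sites(peaks, b$trans, fullpred, seed = 3),
                 "mature")
})
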