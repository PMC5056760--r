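# small separable 2-D fixture for direct SVM behavior checks
separable_xy <- function(n = 40, gap = 4, seed = 123) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, -gap / 2, 0.5), ncol = 2),
             matrix(rnorm(2 * n, gap / 2, 0.5), ncol = 2))
  list(X = X, y = rep(c(0L, 1L), each = n))
}

test_that("scaler standardizes, passes constant columns, and inverts", {
  set.seed(801)
  X <- cbind(rnorm(50, 10, 3), runif(50), rep(7, 50))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(sc, X)
  expect_lt(max(abs(colMeans(Xs[, 1:2]))), 1e-9)
  expect_equal(apply(Xs[, 1:2], 2, sd), c(1, 1))
  expect_equal(Xs[, 3], rep(7, 50))          # sd == 0: untouched
  expect_equal(apply_scaler(sc, Xs, inverse = TRUE), X)
  expect_error(apply_scaler(sc, X[, 1:2]), "dimension")
  expect_error(fit_scaler(X[1, , drop = FALSE]), ">= 2 rows")
})

test_that("grid search maximizes CV AUROC with min-C/min-gamma tie-break", {
  d <- separable_xy()
  one <- grid_search(d$X, d$y, C_grid = 2, gamma_grid = 0.5, k_folds = 3,
                     seed = 1)
  expect_equal(c(one$C, one$gamma), c(2, 0.5))

  # widely separated classes: every cell is perfect, tie-break applies
  gs <- grid_search(d$X, d$y, C_grid = c(4, 1), gamma_grid = c(1, 0.25),
                    k_folds = 3, seed = 2)
  expect_true(all(gs$table == 1))
  expect_equal(gs$C, 1)
  expect_equal(gs$gamma, 0.25)

  gs2 <- grid_search(d$X, d$y, C_grid = c(4, 1), gamma_grid = c(1, 0.25),
                     k_folds = 3, seed = 2)
  expect_identical(gs, gs2)
  expect_error(grid_search(d$X, d$y, C_grid = numeric(), gamma_grid = 1),
               "empty")
})

test_that("SVM separates planted structure and refuses single-class input", {
  d <- separable_xy()
  sc <- fit_scaler(d$X)
  fit <- m6Ascan:::svm_fit_scaled(apply_scaler(sc, d$X), d$y, C = 1,
                                  gamma = 0.5)
  s <- m6Ascan:::svm_decision_scaled(fit, apply_scaler(sc, d$X))
  expect_equal(auroc(s, d$y), 1)
  expect_true(all(is.finite(s)))
  expect_true(mean(s[d$y == 1]) > mean(s[d$y == 0]))
  expect_error(m6Ascan:::svm_fit_scaled(apply_scaler(sc, d$X),
                                        rep(1L, nrow(d$X)), 1, 0.5),
               "single class")
})

test_that("decision scores are invariant to training row order", {
  # the dual optimum is unique in the decision function; row order only
  # changes the SMO path, so agreement tightens with the stopping eps
  d <- separable_xy(n = 25)
  perm <- sample(length(d$y))
  sc <- fit_scaler(d$X)
  f1 <- m6Ascan:::svm_fit_scaled(apply_scaler(sc, d$X), d$y, 1, 0.5,
                                 eps = 1e-8)
  f2 <- m6Ascan:::svm_fit_scaled(apply_scaler(sc, d$X[perm, ]), d$y[perm],
                                 1, 0.5, eps = 1e-8)
  probe <- apply_scaler(sc, matrix(rnorm(20), ncol = 2))
  s1 <- m6Ascan:::svm_decision_scaled(f1, probe)
  s2 <- m6Ascan:::svm_decision_scaled(f2, probe)
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("threshold calibration follows the order statistics of negatives", {
  thr <- calibrate_thresholds(1:100, c(high = 0.90, moderate = 0.85,
                                       low = 0.80))
  expect_gt(thr$high$threshold, 90)
  expect_lte(thr$high$threshold, 91)
  expect_gte(thr$high$specificity, 0.90)
  expect_gte(thr$moderate$specificity, 0.85)
  expect_gte(thr$low$specificity, 0.80)
  # thresholds strictly decreasing from high to low stringency
  expect_true(thr$high$threshold > thr$moderate$threshold)
  expect_true(thr$moderate$threshold > thr$low$threshold)

  # target 100%: threshold above the maximum negative
  t100 <- calibrate_thresholds(1:100, c(all = 1.0))
  expect_gt(t100$all$threshold, 100)
  expect_equal(t100$all$specificity, 1)

  # achieved specificity non-decreasing in target
  targets <- seq(0.99, 0.50, by = -0.07)
  names(targets) <- paste0("l", seq_along(targets))
  specs <- vapply(calibrate_thresholds(rnorm(500), targets),
                  function(x) x$specificity, 0)
  expect_true(all(diff(specs) <= 0))

  expect_error(calibrate_thresholds(numeric(), c(high = 0.9)), "no negatives")
  expect_error(calibrate_thresholds(1:10, c(a = 0.8, b = 0.9)), "decreasing")
})

test_that("trained predictor meets the synthetic benchmark and is reproducible", {
  b <- small_full_bundle()
  pred <- small_full_predictor()
  expect_s3_class(pred, "m6a_predictor")
  rep <- evaluate_independent(pred, b$test, b$trans, seed = 5)
  expect_gt(rep$auroc, 0.85)

  # same seed retrains to bit-identical scores
  pred2 <- train_predictor(b$train, b$trans, mode = "full",
                           config = test_config(), seed = 99L)
  X <- build_feature_matrix(b$test[1:10, ], b$trans, mode = "full")
  expect_identical(predict_scores(pred, X), predict_scores(pred2, X))
})

test_that("held-out calibration recovers the target specificities", {
  b <- small_full_bundle()
  # calibrate on the independent negatives, then measure on those same
  # negatives: achieved specificity must be >= each target
  pred <- train_predictor(b$train, b$trans, mode = "full",
                          config = test_config(),
                          calibration_sites = b$test, seed = 99L)
  rep <- evaluate_independent(pred, b$test, b$trans, seed = 5)
  for (lev in c("high", "moderate", "low")) {
    expect_gte(rep$by_level[[lev]]$specificity,
               pred$thresholds[[lev]]$target - 1e-9)
  }
  expect_true(rep$by_level$high$specificity >=
                rep$by_level$low$specificity)
})

test_that("predict_sites scores all candidates with nested stringency", {
  pred <- small_full_predictor()
  b <- small_full_bundle()
  hits <- predict_sites(pred, b$trans[1:4, ], seed = 1)
  expect_true(all(is_drach(hits$motif)))
  expect_true(all(hits$pass_high <= hits$pass_moderate))
  expect_true(all(hits$pass_moderate <= hits$pass_low))

  none <- predict_sites(pred, transcripts("e", strrep("A", 200), mode = "full"))
  expect_equal(nrow(none), 0L)
  expect_true(all(c("score", "pass_high", "pass_moderate", "pass_low")
                  %in% names(none)))

  expect_error(predict_sites(pred, transcripts("x", strrep("GGACT", 50),
                                               mode = "mature")),
               "mode")
})

test_that("model files round-trip bit-identically and self-describe", {
  pred <- small_full_predictor()
  b <- small_full_bundle()
  path <- tempfile(fileext = ".json")
  save_model(pred, path)
  back <- load_model(path)
  expect_equal(back$mode, "full")
  X <- build_feature_matrix(b$test[1:15, ], b$trans, mode = "full")
  expect_identical(predict_scores(pred, X), predict_scores(back, X))

  expect_error(load_model(tempfile()), "not found")
  junk <- tempfile()
  writeLines("{\"format\": \"something-else\"}", junk)
  expect_error(load_model(junk), "not a")
  writeLines("not json at all {{", junk)
  expect_error(load_model(junk), "corrupt")
})
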