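MODEL_FORMAT <- "m6Ascan-svm"
MODEL_VERSION <- 1L

#' Default decision-score grids and pipeline settings
#'
#' `C_grid` spans 2^-5..2^15 and `gamma_grid` 2^-15..2^3, both in steps of
#' x4 (the usual coarse RBF grid). Supplying fixed `C` and `gamma` skips
#' the grid search.
#'
#' @param C,gamma fixed SVM hyperparameters (NULL = choose by grid search).
#' @param C_grid,gamma_grid candidate grids for the search.
#' @param grid_folds folds for the internal grid-search CV (default 3).
#' @param n_shuffles shuffles per structure Z-score (default 100).
#' @param eps SMO stopping tolerance.
#' @param max_iter SMO iteration cap.
#' @return a configuration list for [train_predictor()] and [kfold_cv()].
#' @export
pipeline_config <- function(C = NULL, gamma = NULL,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            grid_folds = 3L, n_shuffles = 100L,
                            eps = 1e-3, max_iter = 1000000L) {
  list(C = C, gamma = gamma, C_grid = C_grid, gamma_grid = gamma_grid,
       grid_folds = grid_folds, n_shuffles = n_shuffles,
       eps = eps, max_iter = max_iter)
}

#' Fit per-feature standardization parameters
#'
#' Mean/sd per column on training data; constant columns (sd = 0) pass
#' through unscaled.
#'
#' @param X numeric training matrix (>= 2 rows).
#' @return list with `mean` and `sd` vectors (class `m6a_scaler`).
#' @export
fit_scaler <- function(X) {
  if (nrow(X) < 2L) stopf("need >= 2 rows to fit a scaler")
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  keep <- !is.na(sd) & sd > 0
  mu[!keep] <- 0
  sd[!keep] <- 1
  structure(list(mean = mu, sd = sd), class = "m6a_scaler")
}

#' Apply (or invert) a fitted scaler
#' @param scaler from [fit_scaler()].
#' @param X matrix or vector with matching feature dimension.
#' @param inverse undo the scaling instead.
#' @return scaled matrix.
#' @export
apply_scaler <- function(scaler, X, inverse = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(scaler$mean))
    stopf("feature dimension %d does not match scaler (%d)",
          ncol(X), length(scaler$mean))
  if (inverse) sweep(sweep(X, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
  else sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

# Train the RBF SVM on an already-scaled matrix; y01 in {0,1}
svm_fit_scaled <- function(Xs, y01, C, gamma, eps = 1e-3, max_iter = 1000000L) {
  if (length(unique(y01)) < 2L) stopf("training data contain a single class")
  y <- ifelse(y01 == 1L, 1L, -1L)
  fit <- cpp_svm_train(Xs, as.integer(y), C, gamma, eps, as.integer(max_iter))
  fit$C <- C
  fit$gamma <- gamma
  fit
}

svm_decision_scaled <- function(fit, Xs) {
  cpp_svm_decision(fit$sv, fit$coef, fit$rho, fit$gamma, Xs)
}

#' Grid search for (C, gamma) by cross-validated AUROC
#'
#' Evaluates every grid cell with stratified `k_folds` CV on the training
#' matrix (scaler refit inside each fold) and returns the cell with the
#' highest mean out-of-fold AUROC; ties break toward smaller C, then
#' smaller gamma. Folds that end up single-class are skipped with a
#' warning.
#'
#' @param X training feature matrix (unscaled).
#' @param y01 0/1 labels.
#' @param C_grid,gamma_grid candidate values.
#' @param k_folds CV folds (default 3).
#' @param seed optional integer seed fixing the fold assignment.
#' @param eps,max_iter SMO settings.
#' @return list with `C`, `gamma`, and the full `table` of mean AUROCs.
#' @export
grid_search <- function(X, y01, C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2), k_folds = 3L,
                        seed = NULL, eps = 1e-3, max_iter = 1000000L) {
  if (!length(C_grid) || !length(gamma_grid)) stopf("empty hyperparameter grid")
  C_grid <- sort(C_grid)
  gamma_grid <- sort(gamma_grid)
  fold <- stratified_folds(y01, k_folds, seed = seed)
  tab <- matrix(NA_real_, length(C_grid), length(gamma_grid),
                dimnames = list(paste0("C=", C_grid),
                                paste0("gamma=", gamma_grid)))
  for (ci in seq_along(C_grid)) {
    for (gi in seq_along(gamma_grid)) {
      aucs <- c()
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        if (length(unique(y01[tr])) < 2L || length(unique(y01[!tr])) < 2L) {
          warning(sprintf("fold %d is single-class; skipped", f))
          next
        }
        sc <- fit_scaler(X[tr, , drop = FALSE])
        fit <- svm_fit_scaled(apply_scaler(sc, X[tr, , drop = FALSE]),
                              y01[tr], C_grid[ci], gamma_grid[gi],
                              eps = eps, max_iter = max_iter)
        s <- svm_decision_scaled(fit, apply_scaler(sc, X[!tr, , drop = FALSE]))
        aucs <- c(aucs, auroc(s, y01[!tr]))
      }
      if (!length(aucs)) stopf("all grid-search folds were degenerate")
      tab[ci, gi] <- mean(aucs)
    }
  }
  best <- which(tab == max(tab), arr.ind = TRUE)
  # ties: smallest C, then smallest gamma (grids are sorted ascending)
  best <- best[order(best[, 1L], best[, 2L])[1L], , drop = FALSE]
  list(C = C_grid[best[1L, 1L]], gamma = gamma_grid[best[1L, 2L]], table = tab)
}

# scaler + (optional grid search) + SVM, from an unscaled matrix
fit_svm_pipeline <- function(X, y01, config = pipeline_config(), seed = NULL) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  C <- config$C
  gamma <- config$gamma
  gs <- NULL
  if (is.null(C) || is.null(gamma)) {
    gs <- grid_search(X, y01, C_grid = config$C_grid,
                      gamma_grid = config$gamma_grid,
                      k_folds = config$grid_folds, seed = seed,
                      eps = config$eps, max_iter = config$max_iter)
    C <- C %||% gs$C
    gamma <- gamma %||% gs$gamma
  }
  fit <- svm_fit_scaled(Xs, y01, C, gamma, eps = config$eps,
                        max_iter = config$max_iter)
  list(scaler = scaler, fit = fit, C = C, gamma = gamma, grid = gs)
}

svm_pipeline_scores <- function(pipe, X) {
  svm_decision_scaled(pipe$fit, apply_scaler(pipe$scaler, X))
}

#' Default target specificities per mode
#'
#' Stringency levels are calibrated to 90.0/85.2/80.0% specificity in
#' mature mode and 93.0/88.0/83.0% in full-transcript mode.
#'
#' @param mode `"mature"` or `"full"`.
#' @return named numeric vector (high, moderate, low).
#' @export
default_target_specificities <- function(mode = c("mature", "full")) {
  mode <- match.arg(mode)
  if (mode == "mature") c(high = 0.900, moderate = 0.852, low = 0.800)
  else c(high = 0.930, moderate = 0.880, low = 0.830)
}

#' Calibrate stringency thresholds at target specificities
#'
#' For each target specificity s, picks the smallest decision threshold
#' whose empirical specificity on the calibration negatives (fraction of
#' negatives scoring below the threshold, under the rule "predict positive
#' when score >= threshold") is at least s, and reports the achieved
#' specificity.
#'
#' @param neg_scores decision scores of the calibration negatives.
#' @param targets named, strictly decreasing target specificities in
#'   (0, 1\]; names become the stringency levels.
#' @return named list per level: `list(threshold, specificity, target)`.
#' @export
calibrate_thresholds <- function(neg_scores,
                                 targets = default_target_specificities("mature")) {
  if (!length(neg_scores)) stopf("calibration set contains no negatives")
  if (is.unsorted(rev(targets), strictly = TRUE))
    stopf("targets must be strictly decreasing (high to low)")
  s <- sort(neg_scores)
  n <- length(s)
  out <- lapply(targets, function(target) {
    k <- ceiling(target * n)
    t0 <- s[k]
    above <- s[s > t0]
    thr <- if (length(above)) (t0 + min(above)) / 2
    else t0 + 1e-6 * (diff(range(s)) + 1)
    list(threshold = thr, specificity = mean(s < thr), target = target)
  })
  names(out) <- names(targets)
  out
}

#' Train an m6A site predictor
#'
#' Fits the standardization, optionally runs the (C, gamma) grid search,
#' trains the RBF-kernel SVM on the labeled training sites, and calibrates
#' the stringency thresholds on the calibration negatives (the training
#' negatives by default, or a held-out calibration set).
#'
#' @param train_sites labeled-site `data.frame` (balanced 1:1 recommended).
#' @param trans transcript `data.frame`.
#' @param mode `"mature"` or `"full"`.
#' @param taxon metadata tag, e.g. `"human"`, `"mouse"`, `"mammal"`.
#' @param config pipeline settings from [pipeline_config()].
#' @param calibration_sites optional labeled sites whose negatives fix the
#'   thresholds (default: the training set itself).
#' @param target_specificities see [calibrate_thresholds()]; defaults are
#'   mode-specific.
#' @param seed integer seed covering feature shuffles, grid-search folds
#'   and any sampling.
#' @param positional_flank see [feature_layout()].
#' @return a `TrainedPredictor` (class `m6a_predictor`).
#' @export
train_predictor <- function(train_sites, trans, mode = c("mature", "full"),
                            taxon = "mammal", config = pipeline_config(),
                            calibration_sites = NULL,
                            target_specificities = NULL, seed = NULL,
                            positional_flank = NULL) {
  mode <- match.arg(mode)
  y01 <- as.integer(train_sites$label == "positive")
  if (length(unique(y01)) < 2L) stopf("training set must contain both classes")
  X <- build_feature_matrix(train_sites, trans, mode = mode,
                            n_shuffles = config$n_shuffles,
                            seed = derive_seed(seed, 1L),
                            positional_flank = positional_flank)
  pipe <- fit_svm_pipeline(X, y01, config, seed = derive_seed(seed, 2L))
  if (is.null(calibration_sites)) {
    cal_scores <- svm_pipeline_scores(pipe, X)
    neg_scores <- cal_scores[y01 == 0L]
  } else {
    Xc <- build_feature_matrix(calibration_sites, trans, mode = mode,
                               n_shuffles = config$n_shuffles,
                               seed = derive_seed(seed, 3L),
                               positional_flank = positional_flank)
    sc <- svm_pipeline_scores(pipe, Xc)
    neg_scores <- sc[calibration_sites$label == "negative"]
  }
  targets <- target_specificities %||% default_target_specificities(mode)
  thresholds <- calibrate_thresholds(neg_scores, targets)
  structure(list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    mode = mode, taxon = taxon,
    layout = feature_layout(mode, positional_flank = positional_flank),
    positional_flank = positional_flank,
    scaler = pipe$scaler,
    C = pipe$C, gamma = pipe$gamma,
    sv = pipe$fit$sv, coef = as.numeric(pipe$fit$coef), rho = pipe$fit$rho,
    thresholds = thresholds,
    config = config,
    provenance = list(seed = seed, n_train = nrow(train_sites),
                      n_pos = sum(y01), n_neg = sum(y01 == 0L),
                      fold_backend = "builtin",
                      trained = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "m6a_predictor")
}

#' @export
print.m6a_predictor <- function(x, ...) {
  cat(sprintf("m6A site predictor (%s mode, taxon %s)\n", x$mode, x$taxon))
  cat(sprintf("  features: %d   support vectors: %d   C = %g, gamma = %g\n",
              length(x$layout), nrow(x$sv), x$C, x$gamma))
  for (lev in names(x$thresholds)) {
    t <- x$thresholds[[lev]]
    cat(sprintf("  %-8s threshold %8.4f  (specificity %.3f, target %.3f)\n",
                lev, t$threshold, t$specificity, t$target))
  }
  invisible(x)
}

#' Decision scores for a feature matrix
#' @param predictor trained predictor.
#' @param X unscaled feature matrix in the predictor's layout.
#' @return numeric decision values (larger = more likely methylated).
#' @export
predict_scores <- function(predictor, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(predictor$layout))
    stopf("feature matrix has %d columns; %s-mode model expects %d",
          ncol(X), predictor$mode, length(predictor$layout))
  Xs <- apply_scaler(predictor$scaler, X)
  cpp_svm_decision(predictor$sv, predictor$coef, predictor$rho,
                   predictor$gamma, Xs)
}

#' Scan transcripts and score every DRACH candidate
#'
#' All DRACH-centered adenosines are scored; a site is "predicted" at a
#' stringency level when its decision score is at least that level's
#' threshold, so high-stringency calls are a subset of moderate, which are
#' a subset of low.
#'
#' @param predictor trained predictor.
#' @param trans transcript `data.frame`; its mode must match the model.
#' @param seed optional seed for the structure-feature shuffles.
#' @return `data.frame` with `transcript_id`, `pos`, `motif`, `score`, and
#'   one logical `pass_<level>` column per stringency level.
#' @export
predict_sites <- function(predictor, trans, seed = NULL) {
  if (!all(trans$mode == predictor$mode))
    stopf("transcripts are in %s mode but the model is %s mode",
          trans$mode[1L], predictor$mode)
  sites <- scan_drach(trans)
  if (nrow(sites) == 0L) {
    sites$score <- numeric()
    for (lev in names(predictor$thresholds)) sites[[paste0("pass_", lev)]] <- logical()
    return(sites)
  }
  X <- build_feature_matrix(sites, trans, mode = predictor$mode,
                            n_shuffles = predictor$config$n_shuffles,
                            seed = seed,
                            positional_flank = predictor$positional_flank)
  sites$score <- predict_scores(predictor, X)
  for (lev in names(predictor$thresholds)) {
    sites[[paste0("pass_", lev)]] <-
      sites$score >= predictor$thresholds[[lev]]$threshold
  }
  sites
}

#' Save a trained predictor to a self-describing JSON file
#'
#' The file carries a format name and version, the mode/taxon metadata,
#' the feature layout, scaling parameters, SVM state (support vectors,
#' coefficients, offset, C, gamma), threshold table and provenance.
#' Numbers are written at full precision so a round-trip reproduces scores
#' bit-identically.
#'
#' @param predictor trained predictor.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(predictor, path) {
  num <- function(x) sprintf("%.17g", as.numeric(x))  # exact double round-trip
  obj <- unclass(predictor)
  sv <- unname(as.matrix(obj$sv))
  obj$sv <- list(dim = dim(sv), values = num(sv))     # column-major
  obj$coef <- num(obj$coef)
  obj$rho <- num(obj$rho)
  obj$gamma <- num(obj$gamma)
  obj$scaler <- list(mean = num(obj$scaler$mean), sd = num(obj$scaler$sd))
  obj$thresholds <- lapply(obj$thresholds, function(t)
    list(threshold = num(t$threshold), specificity = t$specificity,
         target = t$target))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a predictor saved by [save_model()]
#' @param path model file path.
#' @return the restored predictor (class `m6a_predictor`).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("corrupted model file %s: %s",
                                            path, conditionMessage(e)))
  if (!identical(obj$format, MODEL_FORMAT))
    stopf("not a %s model file: %s", MODEL_FORMAT, path)
  if (!identical(as.integer(obj$version), MODEL_VERSION))
    stopf("model format version %s unsupported (expected %d)",
          obj$version, MODEL_VERSION)
  obj$sv <- matrix(as.numeric(obj$sv$values), nrow = obj$sv$dim[1L])
  obj$coef <- as.numeric(obj$coef)
  obj$rho <- as.numeric(obj$rho)
  obj$gamma <- as.numeric(obj$gamma)
  obj$scaler <- structure(list(mean = as.numeric(obj$scaler$mean),
                               sd = as.numeric(obj$scaler$sd)),
                          class = "m6a_scaler")
  obj$thresholds <- lapply(obj$thresholds, function(t)
    list(threshold = as.numeric(t$threshold),
         specificity = as.numeric(t$specificity),
         target = as.numeric(t$target)))
  if (length(obj$positional_flank) == 0L) obj$positional_flank <- NULL
  if (length(obj$layout) != ncol(obj$sv))
    stopf("model file layout (%d) does not match SV dimension (%d)",
          length(obj$layout), ncol(obj$sv))
  class(obj) <- "m6a_predictor"
  obj
}
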