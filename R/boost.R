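#' Configuration for stability-selected gradient boosting
#'
#' @param train_fraction fraction of samples in the training set (default 0.7).
#' @param n_resamples number of resampled model fits used for stability
#'   selection (default 100); each resample holds out one cross-validation
#'   fold, so `n_resamples` spans `ceiling(n_resamples / cv_folds)` repeats of
#'   the fold assignment.
#' @param cv_folds number of stratified cross-validation folds (default 5).
#' @param nrounds,max_depth,eta,subsample gradient-boosting hyperparameters
#'   (defaults: 200 trees, depth 3, learning rate 0.1, row subsampling 0.8).
#' @param noise_probe distribution of the noise feature appended to every
#'   resample: `"gaussian"` (a fresh standard-normal column, default) or
#'   `"permuted"` (a randomly chosen real feature with its values permuted).
#' @param aggregation_alpha BH-adjusted significance level for panel
#'   membership in [aggregate_pairwise()] (default 0.05).
#' @param n_permutations sign-flip permutations for the feature-vs-noise test
#'   (default 1000).
#' @param seed integer seed; every resample is reproducible from
#'   (seed, resample index).
#' @return object of class `boost_config`.
#' @export
boost_config <- function(train_fraction = 0.7, n_resamples = 100L,
                         cv_folds = 5L, nrounds = 200L, max_depth = 3L,
                         eta = 0.1, subsample = 0.8,
                         noise_probe = c("gaussian", "permuted"),
                         aggregation_alpha = 0.05, n_permutations = 1000L,
                         seed = 1L) {
  cfg <- list(train_fraction = train_fraction,
              n_resamples = as.integer(n_resamples),
              cv_folds = as.integer(cv_folds),
              cv_repeats = as.integer(ceiling(n_resamples / cv_folds)),
              nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
              eta = eta, subsample = subsample,
              noise_probe = match.arg(noise_probe),
              aggregation_alpha = aggregation_alpha,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed))
  .assert(cfg$train_fraction > 0 && cfg$train_fraction < 1,
          "train_fraction must lie in (0,1)")
  .assert(cfg$n_resamples >= 2, "n_resamples must be at least 2")
  .assert(cfg$cv_folds >= 2, "cv_folds must be at least 2")
  .assert(cfg$nrounds >= 1 && cfg$max_depth >= 1 && cfg$n_permutations >= 1,
          "all counts must be positive")
  class(cfg) <- "boost_config"
  cfg
}

#' Stratified train/test split
#'
#' Splits samples into a training and a test set preserving the class balance
#' within one sample per class: each class contributes `round(fraction * n_c)`
#' training samples.
#'
#' @param labels binary labels (0/1, logical, or two-level factor/character).
#' @param fraction training fraction in (0,1), default 0.7.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(labels, fraction = 0.7, seed = 1L) {
  y <- .as01(labels)
  .assert(fraction > 0 && fraction < 1, "fraction must lie in (0,1)")
  .assert(min(table(y)) >= 2, "each class needs at least 2 samples")
  set.seed(seed)
  train <- integer(0)
  for (cl in c(0, 1)) {
    idx <- which(y == cl)
    n_tr <- as.integer(round(fraction * length(idx)))
    .assert(n_tr >= 1 && n_tr < length(idx),
            "split leaves a class empty in train or test; adjust fraction")
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

.as01 <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    .assert(length(lv) == 2, "labels must have exactly two classes")
    # "responder" is the positive class when present
    pos <- if ("responder" %in% lv) "responder" else lv[2]
    as.numeric(as.character(labels) == pos)
  } else {
    y <- as.numeric(labels)
    .assert(all(y %in% c(0, 1)), "numeric labels must be 0/1")
    y
  }
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.xgb_fit <- function(x, y, config, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "binary:logistic",
                 max_depth = config$max_depth, eta = config$eta,
                 subsample = config$subsample, nthread = 1,
                 seed = seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

# gain importance for all feature names (0 for unused features)
.gain_vector <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  g <- setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0) {
    hit <- intersect(imp$Feature, feature_names)
    g[hit] <- imp$Gain[match(hit, imp$Feature)]
  }
  g
}

#' Stability selection by gradient boosting against a noise probe
#'
#' Runs `n_resamples` boosted-tree fits on the training data. Each resample
#' draws a stratified cross-validation fold assignment, holds one fold out,
#' appends a freshly drawn noise feature to the remaining samples, fits the
#' model, and reads gain-based feature importances. A feature counts as
#' selected in a resample when its importance strictly exceeds the noise
#' feature's. The full importance ordering of every resample is accumulated
#' into a pairwise win matrix `W` (`W[i,j]` = resamples where feature i
#' outranks j), and the held-out fold provides a per-resample
#' cross-validation AUROC.
#'
#' Resamples whose fit fails are recorded and skipped; the run aborts unless
#' at least 90% succeed.
#'
#' @param x training feature matrix (samples x features, e.g. M-values with
#'   samples as rows), with column names.
#' @param labels training labels (see [split_train_test()]).
#' @param config a [boost_config()].
#' @return object of class `stability_result`: `selection_count`,
#'   `importance` (features x resamples gain matrix), `noise_importance`,
#'   `win_matrix`, `cv_auroc`, `n_success`, `failed_resamples`,
#'   `feature_ids`, `config`.
#' @export
run_stability_selection <- function(x, labels, config = boost_config()) {
  .assert(is.matrix(x) && !is.null(colnames(x)),
          "x must be a matrix with feature column names")
  y <- .as01(labels)
  .assert(length(y) == nrow(x), "one label per row of x required")
  .assert(length(unique(y)) == 2 && min(table(y)) >= config$cv_folds,
          "each class needs at least cv_folds training samples")
  p <- ncol(x)
  feats <- colnames(x)
  noise_name <- ".noise."
  .assert(!noise_name %in% feats, "feature name '.noise.' is reserved")

  sel <- setNames(numeric(p), feats)
  imp_mat <- matrix(NA_real_, p, config$n_resamples,
                    dimnames = list(feats, NULL))
  noise_imp <- rep(NA_real_, config$n_resamples)
  W <- matrix(0, p, p, dimnames = list(feats, feats))
  cv_auroc <- rep(NA_real_, config$n_resamples)
  failed <- integer(0)

  folds_for_repeat <- function(rep_i) {
    set.seed(config$seed + 7919L * rep_i)
    .stratified_folds(y, config$cv_folds)
  }
  fold_cache <- list()

  for (r in seq_len(config$n_resamples)) {
    rep_i <- (r - 1L) %/% config$cv_folds + 1L
    key <- as.character(rep_i)
    if (is.null(fold_cache[[key]])) fold_cache[[key]] <- folds_for_repeat(rep_i)
    fold <- fold_cache[[key]]
    hold <- (r - 1L) %% config$cv_folds + 1L
    tr <- fold != hold

    set.seed(config$seed + 104729L + r)
    noise <- if (config$noise_probe == "gaussian") {
      rnorm(nrow(x))
    } else {
      sample(x[, sample.int(p, 1)])
    }
    xr <- cbind(x, noise)
    colnames(xr)[p + 1L] <- noise_name

    fit <- tryCatch(
      .xgb_fit(xr[tr, , drop = FALSE], y[tr], config,
               seed = config$seed + r),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, r)
      next
    }
    g_all <- .gain_vector(fit, colnames(xr))
    g <- g_all[feats]
    noise_imp[r] <- g_all[noise_name]
    imp_mat[, r] <- g
    sel <- sel + (g > noise_imp[r])
    W <- W + outer(g, g, ">")
    pred <- predict(fit, xgboost::xgb.DMatrix(xr[!tr, , drop = FALSE]))
    cv_auroc[r] <- if (length(unique(y[!tr])) == 2) {
      auroc(pred, y[!tr])
    } else NA_real_
  }
  n_success <- config$n_resamples - length(failed)
  if (n_success < 0.9 * config$n_resamples) {
    stop(sprintf("only %d of %d resamples succeeded (>= 90%% required)",
                 n_success, config$n_resamples), call. = FALSE)
  }
  structure(list(selection_count = sel, importance = imp_mat,
                 noise_importance = noise_imp, win_matrix = W,
                 cv_auroc = cv_auroc, n_success = n_success,
                 failed_resamples = failed, feature_ids = feats,
                 config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability selection: %d features, %d/%d resamples, mean CV AUROC %.3f\n",
              length(x$feature_ids), x$n_success, x$config$n_resamples,
              mean(x$cv_auroc, na.rm = TRUE)))
  invisible(x)
}

#' Aggregate resampled rankings into a consensus feature panel
#'
#' Consensus order: Copeland score over the pairwise win matrix (feature i
#' beats j when it outranks j in more resamples than vice versa), ties broken
#' by mean importance, then feature id. Panel membership: a paired one-sided
#' sign-flip permutation test of the per-resample importance margin over the
#' noise feature, Benjamini-Hochberg adjusted across features; features with
#' adjusted p at or below `aggregation_alpha` and a positive mean margin
#' enter the panel. Features never retained by the noise-threshold rule
#' (selection count zero) are discarded before multiplicity control: the BH
#' family is the set of features that beat the noise probe in at least one
#' resample. An empty panel is a valid outcome.
#'
#' Caveat: the sign-flip test treats the per-resample margins as independent,
#' but every resample reuses the same training samples. A feature that is
#' in-sample-predictive by chance therefore beats the (usually unused) noise
#' column in most resamples, its margins are consistently positive, and its
#' permutation p-value collapses to the floor `1/(n_permutations+1)`. On
#' high-dimensional null data the panel is consequently anti-conservative:
#' treat membership as a ranking-plus-screening heuristic, and validate any
#' panel on held-out data (see [evaluate_model()]), not by the q-values alone.
#'
#' @param result a `stability_result`.
#' @param config a [boost_config()]; defaults to the one inside `result`.
#' @return data.frame of class `panel`, ordered by consensus rank:
#'   `feature`, `consensus_rank`, `copeland`, `selection_freq`,
#'   `mean_importance`, `mean_margin`, `perm_p`, `q_value`, `in_panel`;
#'   the panel is the subset with `in_panel`.
#' @export
aggregate_pairwise <- function(result, config = result$config) {
  .assert(inherits(result, "stability_result"), "need a stability_result")
  ok <- which(!is.na(result$noise_importance))
  .assert(length(ok) >= 2, "at least 2 successful resamples required")
  D <- result$importance[, ok, drop = FALSE] -
    matrix(result$noise_importance[ok], nrow(result$importance),
           length(ok), byrow = TRUE)
  obs <- rowMeans(D)
  R <- length(ok)
  set.seed(config$seed + 333667L)
  S <- matrix(sample(c(-1, 1), R * config$n_permutations, replace = TRUE),
              R, config$n_permutations)
  perm_means <- (D %*% S) / R
  perm_p <- (1 + rowSums(perm_means >= obs)) / (config$n_permutations + 1)
  # only features the noise-threshold rule ever retained are candidates; they
  # form the BH family, everything else is discarded a priori
  cand <- result$selection_count > 0
  qv <- rep(NA_real_, length(perm_p))
  qv[cand] <- p.adjust(perm_p[cand], method = "BH")

  W <- result$win_matrix
  copeland <- rowSums(W > t(W))
  mean_imp <- rowMeans(result$importance[, ok, drop = FALSE])
  feats <- result$feature_ids
  o <- order(-copeland, -mean_imp, feats)
  out <- data.frame(
    feature = feats[o],
    consensus_rank = seq_along(feats),
    copeland = copeland[o],
    selection_freq = (result$selection_count / result$n_success)[o],
    mean_importance = mean_imp[o],
    mean_margin = obs[o],
    perm_p = perm_p[o],
    q_value = qv[o],
    in_panel = !is.na(qv[o]) & (qv[o] <= config$aggregation_alpha) &
      (obs[o] > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("panel", "data.frame")
  out
}

#' Panel feature ids from an aggregation result
#' @param panel result of [aggregate_pairwise()].
#' @export
panel_features <- function(panel) panel$feature[panel$in_panel]

#' Fit the final classifier on the selected panel and evaluate it
#'
#' Retrains a boosted-tree model on the full training set restricted to the
#' panel features, then scores the untouched test set.
#'
#' @param x_train,x_test samples x features matrices.
#' @param y_train,y_test labels.
#' @param features panel feature ids; must be non-empty for training.
#' @param config a [boost_config()].
#' @return for `train_final`, an xgboost model handle; for `evaluate_model`,
#'   a list with `auroc` and `roc` (data.frame fpr/tpr/threshold).
#' @export
train_final <- function(x_train, y_train, features, config = boost_config()) {
  .assert(length(features) > 0, "panel is empty; no model can be trained")
  .assert(all(features %in% colnames(x_train)),
          "panel features missing from training matrix")
  booster <- .xgb_fit(x_train[, features, drop = FALSE], .as01(y_train),
                      config, seed = config$seed)
  structure(list(booster = booster, features = features, config = config),
            class = "methresp_model")
}

#' @rdname train_final
#' @param model fitted model from [train_final()].
#' @export
evaluate_model <- function(model, x_test, y_test) {
  .assert(inherits(model, "methresp_model"), "need a train_final() model")
  scores <- predict(model$booster, xgboost::xgb.DMatrix(
    x_test[, model$features, drop = FALSE]))
  y <- .as01(y_test)
  list(auroc = auroc(scores, y), roc = roc_points(scores, y),
       scores = scores)
}

#' Area under the ROC curve by pair counting
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted one half: equivalent to the normalized Mann-Whitney U
#' statistic, computed via midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels; both classes must be present.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  y <- .as01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auroc
#' @return for `roc_points`, a data.frame with monotone `fpr`, `tpr` and the
#'   score `threshold` at each step.
#' @export
roc_points <- function(scores, labels) {
  y <- .as01(labels)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(diff(ss) != 0, TRUE)   # one point per distinct threshold
  data.frame(
    threshold = c(Inf, ss[keep]),
    tpr = c(0, tp[keep] / sum(y)),
    fpr = c(0, fp[keep] / sum(1 - y))
  )
}

#' End-to-end stability-selected classifier
#'
#' Convenience wrapper running the full prognostic-classifier workflow:
#' stratified 70/30 split, stability selection on the training set only,
#' pairwise aggregation into a panel, final training on panel features, and
#' held-out evaluation. The test set never influences selection.
#'
#' @param x samples x features matrix (e.g. transposed M-value matrix).
#' @param labels response labels.
#' @param config a [boost_config()].
#' @return list: `split`, `stability`, `panel`, `model` (NULL when the panel
#'   is empty), `test_auroc` (NA when no model), `mean_cv_auroc`, `roc`.
#' @export
stability_classify <- function(x, labels, config = boost_config()) {
  sp <- split_train_test(labels, config$train_fraction, config$seed)
  y <- .as01(labels)
  st <- run_stability_selection(x[sp$train, , drop = FALSE], y[sp$train],
                                config)
  pan <- aggregate_pairwise(st, config)
  feats <- panel_features(pan)
  model <- NULL; ev <- list(auroc = NA_real_, roc = NULL)
  if (length(feats) > 0) {
    model <- train_final(x[sp$train, , drop = FALSE], y[sp$train], feats,
                         config)
    ev <- evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
  }
  list(split = sp, stability = st, panel = pan, model = model,
       test_auroc = ev$auroc, mean_cv_auroc = mean(st$cv_auroc, na.rm = TRUE),
       roc = ev$roc)
}
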