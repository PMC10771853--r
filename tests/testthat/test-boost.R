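# small labelled dataset with two strongly informative features
toy_data <- function(n = 60, p = 8, shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  x[, 1] <- x[, 1] + shift * y
  x[, 2] <- x[, 2] - shift * y
  list(x = x, y = y)
}

fast_config <- function(...) {
  boost_config(n_resamples = 10, cv_folds = 5, nrounds = 30,
               n_permutations = 200, ...)
}

test_that("the stratified split follows per-class rounding arithmetic", {
  labels <- rep(c("responder", "non_responder"), c(49, 43))
  sp <- split_train_test(labels, fraction = 0.7, seed = 2)
  # round(0.7*49) = 34 responders, round(0.7*43) = 30 non-responders
  expect_length(sp$train, 64)
  expect_length(sp$test, 28)
  expect_equal(sum(labels[sp$train] == "responder"), 34)
  expect_equal(sum(labels[sp$train] == "non_responder"), 30)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # deterministic in the seed
  expect_identical(sp, split_train_test(labels, 0.7, seed = 2))
  expect_false(identical(sp$train, split_train_test(labels, 0.7, 3)$train))
  expect_error(split_train_test(labels, fraction = 1.2), "\\(0,1\\)")
  expect_error(split_train_test(rep(c(0, 1), c(2, 90)), fraction = 0.9),
               "leaves a class empty")
  expect_error(split_train_test(rep("responder", 10)), "two classes")
})

test_that("auroc matches the brute-force pair-counting oracle", {
  pair_auroc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    # mix continuous scores with heavy ties
    s <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)
    expect_equal(auroc(s, y), pair_auroc(s, y), tolerance = 1e-12)
  }
  # cross-check against pROC on one continuous instance
  set.seed(42)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60) + y
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  # symmetry, degeneracy, errors
  expect_equal(auroc(-s, y), 1 - auroc(s, y), tolerance = 1e-12)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
})

test_that("roc curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(43)
  y <- sample(c(0, 1), 50, replace = TRUE)
  y[1:2] <- c(0, 1)
  s <- round(rnorm(50), 1)    # forces ties
  rc <- roc_points(s, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$threshold) < 0))
})

test_that("stability selection is deterministic and keeps honest books", {
  d <- toy_data(seed = 44)
  cfg <- fast_config(seed = 7)
  r1 <- run_stability_selection(d$x, d$y, cfg)
  r2 <- run_stability_selection(d$x, d$y, cfg)
  expect_equal(r1, r2)
  r3 <- run_stability_selection(d$x, d$y, fast_config(seed = 8))
  expect_false(identical(r1$importance, r3$importance))

  expect_equal(r1$n_success, 10)
  expect_length(r1$failed_resamples, 0)
  expect_true(all(diag(r1$win_matrix) == 0))
  # each resample contributes at most one win per ordered pair
  off <- r1$win_matrix + t(r1$win_matrix)
  expect_true(all(off[upper.tri(off)] <= r1$n_success))
  expect_true(all(r1$selection_count >= 0 &
                    r1$selection_count <= r1$n_success))
  expect_true(all(r1$cv_auroc >= 0 & r1$cv_auroc <= 1, na.rm = TRUE))
  # every resample's gains are a simplex (sum 1) when any split was used
  sums <- colSums(r1$importance) + r1$noise_importance
  expect_true(all(abs(sums - 1) < 1e-6 | sums == 0))
  # informative features dominate the selection counts
  expect_true(all(r1$selection_count[c("f01", "f02")] >=
                    max(r1$selection_count[-(1:2)])))
})

test_that("stability selection validates its inputs", {
  d <- toy_data(seed = 45)
  x_bad <- d$x; colnames(x_bad) <- NULL
  expect_error(run_stability_selection(x_bad, d$y, fast_config()),
               "column names")
  x_res <- d$x; colnames(x_res)[3] <- ".noise."
  expect_error(run_stability_selection(x_res, d$y, fast_config()),
               "reserved")
  few <- c(1:3, 31:33)   # three samples per class, fewer than cv_folds
  expect_error(run_stability_selection(d$x[few, ], d$y[few], fast_config()),
               "cv_folds training samples")
  expect_error(run_stability_selection(d$x[1:10, ], d$y[1:10], fast_config()),
               "cv_folds training samples")   # a single class present
  expect_error(run_stability_selection(d$x, d$y[1:10], fast_config()),
               "one label per row")
})

test_that("pairwise aggregation ranks a dominant feature first", {
  # fabricated resample history: feature a always outranks b outranks c;
  # a and b beat the noise probe, c never does
  R <- 8
  imp <- rbind(a = rep(0.6, R), b = rep(0.3, R), c = rep(0.08, R))
  noise <- rep(0.2, R)
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["a", "c"] <- W["b", "c"] <- R
  res <- structure(list(
    selection_count = setNames(c(R, R, 0), c("a", "b", "c")),
    importance = imp, noise_importance = noise, win_matrix = W,
    cv_auroc = rep(0.8, R), n_success = R, failed_resamples = integer(0),
    feature_ids = c("a", "b", "c"),
    config = boost_config(n_resamples = R, n_permutations = 2000, seed = 5)
  ), class = "stability_result")
  pan <- aggregate_pairwise(res)
  expect_identical(pan$feature, c("a", "b", "c"))
  expect_equal(pan$copeland, c(2, 1, 0))
  expect_equal(pan$selection_freq, c(1, 1, 0))
  expect_equal(pan$mean_margin, c(0.4, 0.1, -0.12), tolerance = 1e-12)
  # constant positive margins: the sign-flip p equals the all-plus orbit
  # probability, bounded below by the permutation floor
  expect_true(all(pan$perm_p[1:2] >= 1 / 2001))
  expect_true(all(pan$perm_p[1:2] < 0.05))
  expect_identical(panel_features(pan), c("a", "b"))
  # never-selected features are excluded from the BH family a priori
  expect_true(is.na(pan$q_value[3]))
  expect_false(pan$in_panel[3])
  expect_gt(pan$perm_p[3], 0.5)
})

test_that("panel membership is monotone in the aggregation level", {
  d <- toy_data(seed = 46)
  cfg <- fast_config(seed = 9)
  res <- run_stability_selection(d$x, d$y, cfg)
  strict <- aggregate_pairwise(res, fast_config(seed = 9,
                                                aggregation_alpha = 0.01))
  loose <- aggregate_pairwise(res, fast_config(seed = 9,
                                               aggregation_alpha = 0.25))
  expect_true(all(panel_features(strict) %in% panel_features(loose)))
})

test_that("the final model trains on the panel and separates the classes", {
  d <- toy_data(n = 80, seed = 47)
  sp <- split_train_test(d$y, 0.7, seed = 1)
  cfg <- fast_config(seed = 3)
  model <- train_final(d$x[sp$train, ], d$y[sp$train], c("f01", "f02"), cfg)
  expect_s3_class(model, "methresp_model")
  ev <- evaluate_model(model, d$x[sp$test, ], d$y[sp$test])
  expect_gt(ev$auroc, 0.9)
  expect_length(ev$scores, length(sp$test))
  expect_error(train_final(d$x, d$y, character(0), cfg), "empty")
  expect_error(train_final(d$x, d$y, "nope", cfg), "missing from training")
})

test_that("held-out samples cannot influence selection or the panel", {
  d <- toy_data(n = 80, seed = 48)
  labels <- ifelse(d$y == 1, "responder", "non_responder")
  cfg <- fast_config(seed = 11)
  full <- stability_classify(d$x, labels, cfg)
  # corrupt every test-set row: selection and panel must be bit-identical
  x2 <- d$x
  x2[full$split$test, ] <- matrix(rnorm(length(full$split$test) * ncol(d$x),
                                        sd = 50),
                                  length(full$split$test))
  again <- stability_classify(x2, labels, cfg)
  expect_identical(again$split, full$split)
  expect_equal(again$stability$importance, full$stability$importance)
  expect_equal(again$panel, full$panel)
  # only the held-out evaluation may change
  expect_false(isTRUE(all.equal(again$test_auroc, full$test_auroc)))
})

test_that("the end-to-end classifier recovers the informative features", {
  d <- toy_data(n = 80, seed = 49)
  labels <- ifelse(d$y == 1, "responder", "non_responder")
  res <- stability_classify(d$x, labels, fast_config(seed = 13))
  expect_true(all(c("f01", "f02") %in% res$panel$feature[1:3]))
  expect_true(all(c("f01", "f02") %in% panel_features(res$panel)))
  expect_gt(res$test_auroc, 0.8)
  expect_gt(res$mean_cv_auroc, 0.8)
  expect_true(!is.null(res$roc))
})
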