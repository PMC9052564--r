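test_that("AUC equals the concordant-pair probability with tie handling", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_mann_whitney(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoid ROC area equals Mann-Whitney U on arbitrary scores", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
    roc <- roc_curve(scores, labels)
    expect_equal(auc_trapezoid(roc), auc_mann_whitney(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc$sensitivity[1], 0)
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$sensitivity[nrow(roc)], 1)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_true(all(diff(roc$sensitivity) >= 0), all(diff(roc$fpr) >= 0))
  }
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mann_whitney(scores, labels), ref, tolerance = 1e-12)
})

test_that("knn scoring is deterministic with row-order tie breaking", {
  x <- matrix(c(0, 0, 0, 0, 0, 0, 5, 5), ncol = 2, byrow = TRUE)
  y <- c(1, 1, 0, 0)
  # query at the origin: three zero-distance ties, broken by row order
  expect_equal(knn_predict_score(x, y, c(0, 0), k = 3), 2 / 3)
  # k = n gives the training prevalence for any query
  expect_equal(knn_predict_score(x, y, c(100, -3), k = 4), 0.5)
  expect_error(knn_predict_score(x, y, c(0, 0), k = 0), "positive")
  expect_error(knn_predict_score(x, y, c(0, 0), k = 9), "exceeds")
  # coincident query whose 5 nearest are all positive
  set.seed(47)
  xp <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 8, 0.1), 5))
  expect_equal(knn_predict_score(xp, rep(c(1, 0), each = 5), xp[1, ], k = 5), 1)
})

test_that("knn separates well-separated Gaussian blobs", {
  set.seed(53)
  xtr <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
               matrix(rnorm(60, 6, 1), ncol = 2))
  ytr <- rep(c(0, 1), each = 30)
  xte <- rbind(matrix(rnorm(40, 0, 1), ncol = 2),
               matrix(rnorm(40, 6, 1), ncol = 2))
  yte <- rep(c(0, 1), each = 20)
  acc <- mean((knn_predict_score(xtr, ytr, xte, k = 5) > 0.5) == yte)
  expect_gt(acc, 0.9)
})

test_that("stratified folds keep both classes in every fold, deterministically", {
  y <- rep(c(0, 1), c(30, 20))
  f1 <- stratified_folds(y, 5, seed = 9)
  f2 <- stratified_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  for (k in 1:5) expect_setequal(unique(y[f1 == k]), c(0, 1))
  expect_error(stratified_folds(rep(c(0, 1), c(48, 2)), 5), "stratification")
})

test_that("cross-validated AUC hits the separable and null regimes", {
  set.seed(59)
  y <- rep(c(0, 1), each = 25)
  x_sep <- matrix(y * 10 + rnorm(50, sd = 0.1), ncol = 1)
  aucs <- cv_auc(x_sep, y, model_spec("knn", k = 5), seed = 1)
  expect_length(aucs, 5)
  expect_equal(unname(aucs), rep(1, 5))
  expect_identical(cv_auc(x_sep, y, model_spec("knn", k = 5), seed = 1), aucs)
  # permutation null: grand mean over 20 label shuffles stays near 0.5
  x <- matrix(rnorm(50 * 2), ncol = 2)
  grand <- vapply(1:20, function(s) {
    set.seed(s)
    mean(cv_auc(x, sample(y), model_spec("knn", k = 5), seed = s))
  }, numeric(1))
  expect_gt(mean(grand), 0.4)
  expect_lt(mean(grand), 0.6)
})

test_that("every model family in the grid produces valid CV scores", {
  set.seed(61)
  y <- rep(c(0, 1), each = 20)
  x <- matrix(rnorm(40 * 3, mean = y), ncol = 3)
  for (spec in default_model_grid()) {
    aucs <- cv_auc(x, y, spec, seed = 2)
    expect_length(aucs, 5)
    expect_true(all(aucs >= 0 & aucs <= 1), info = spec$label)
    expect_gt(mean(aucs), 0.6) # all families detect a 1-sd mean shift
  }
})

test_that("forward selection recovers an informative feature among noise", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 21), n, dimnames = list(NULL, c("signal", sprintf("noise%02d", 1:20))))
    X[, "signal"] <- X[, "signal"] + 2.2 * y
    sig <- select_signature(X, y, grid = default_model_grid("knn"),
                            signature_size = 2, seed = s)
    if (sig$features[1] == "signal") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("a grid restricted to 5-NN is honoured and sizes the signature exactly", {
  set.seed(67)
  y <- rep(c(0, 1), each = 25)
  X <- matrix(rnorm(50 * 8, mean = 0.5 * y), 50,
              dimnames = list(NULL, paste0("mf", 1:8)))
  sig <- select_signature(X, y, grid = list(model_spec("knn", k = 5)),
                          signature_size = 3, seed = 3)
  expect_equal(sig$spec$label, "knn_5")
  expect_length(sig$features, 3)
  expect_length(sig$fold_aucs, 5)
  expect_error(select_signature(X, rep(1, 50)), "single-class")
  expect_error(select_signature(X, y, signature_size = 99), "exceeds")
})

test_that("external validation uses the frozen model and checks AUC internally", {
  set.seed(71)
  y <- rep(c(0, 1), each = 25)
  X <- matrix(rnorm(50 * 6, mean = 1.2 * y), 50,
              dimnames = list(NULL, paste0("mf", 1:6)))
  sig <- select_signature(X, y, grid = default_model_grid("knn"),
                          signature_size = 2, seed = 5)
  hash_before <- jsonlite::serializeJSON(sig$model$fit)
  Xv <- matrix(rnorm(30 * 6, mean = 1.2 * rep(c(0, 1), each = 15)), 30,
               dimnames = list(NULL, paste0("mf", 1:6)))
  rep1 <- validate_external(sig, Xv, rep(c(0, 1), each = 15))
  expect_identical(jsonlite::serializeJSON(sig$model$fit), hash_before)
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  expect_gt(rep1$auc, 0.7) # strong injected effect carries over
  expect_error(validate_external(sig, Xv[, 3:6, drop = FALSE],
                                 rep(c(0, 1), each = 15)), "lacks")
})
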