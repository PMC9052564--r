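# Signature selection and validation: stratified fivefold cross-validated
# ROC-AUC, sequential forward selection over a candidate model grid, a
# deterministic k-NN scorer, and frozen external validation.

#' ROC-AUC via the normalised Mann-Whitney U statistic
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted 1/2 (so a constant scorer gets exactly 0.5).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Step function from (0, 0) to (1, 1) over the observed score thresholds
#' (descending); ties move diagonally, so the trapezoid area equals the
#' Mann-Whitney AUC with the 1/2 tie convention.
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame with `threshold`, `sensitivity` (TPR), `specificity`,
#'   and `fpr` columns; attribute `auc` holds the trapezoid area.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  thr <- unique(s)
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(1L - l)
  last <- cumsum(rle(s)$lengths) # last index of each tied block
  tpr <- c(0, cum_tp[last] / n1)
  fpr <- c(0, cum_fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- data.frame(threshold = c(Inf, thr), sensitivity = tpr,
                    specificity = 1 - fpr, fpr = fpr)
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @param roc a `roc_curve()` result.
#' @return `auc_trapezoid`: the trapezoid area under the ROC.
#' @export
auc_trapezoid <- function(roc) attr(roc, "auc")

#' Deterministic k-nearest-neighbour positive-class score
#'
#' Euclidean distances in meta-feature space; the score of a query is the
#' fraction of positives among its k nearest training points. Distance ties
#' are broken by training-row order, making the scorer fully deterministic.
#'
#' @param train_x numeric training matrix (rows = cases).
#' @param train_y binary 0/1 training labels.
#' @param query_x numeric query matrix (or vector for one query).
#' @param k neighbourhood size, `1 <= k <= nrow(train_x)`.
#' @return numeric vector of scores in `[0, 1]`, one per query row.
#' @export
knn_predict_score <- function(train_x, train_y, query_x, k = 5L) {
  train_x <- as.matrix(train_x)
  if (is.null(dim(query_x))) query_x <- matrix(query_x, nrow = 1)
  query_x <- as.matrix(query_x)
  if (k <= 0L) stop("k must be positive")
  if (k > nrow(train_x)) stop("k exceeds the number of training points")
  d2 <- knn_dist2(train_x, query_x)
  apply_knn_score(d2, as.integer(train_y), k)
}

# squared distances, training rows x query rows
knn_dist2 <- function(train_x, query_x) {
  st <- rowSums(train_x^2)
  sq <- rowSums(query_x^2)
  outer(st, sq, `+`) - 2 * tcrossprod(train_x, query_x)
}

# columns of d2 are queries; stable ties via order(d, index)
apply_knn_score <- function(d2, train_y, k) {
  vapply(seq_len(ncol(d2)), function(q) {
    ord <- order(d2[, q], seq_len(nrow(d2)))[seq_len(k)]
    mean(train_y[ord])
  }, numeric(1))
}

#' Candidate model specifications
#'
#' @param family one of `"knn"`, `"gnb"`, `"svm"`, `"rf"`.
#' @param ... family hyper-parameters (`k` for knn; `cost` for the RBF SVM;
#'   `num_trees` for the random forest).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("knn", "gnb", "svm", "rf"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  # complexity rank used only for deterministic tie-breaking in selection
  complexity <- switch(family,
                       gnb = 1,
                       knn = 2 + (100 - (pars$k %||% 5)) * 1e-4,
                       svm = 3,
                       rf = 4)
  structure(list(family = family, pars = pars, complexity = complexity,
                 label = paste0(family, if (length(pars))
                   paste0("_", paste(unlist(pars), collapse = "_")) else "")),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default candidate model grid
#'
#' k-nearest neighbours (k in 3, 5, 7, 9), Gaussian naive Bayes, an RBF
#' support-vector machine, and a random forest, searched jointly with the
#' forward feature selection.
#'
#' @param families subset of families to include.
#' @return list of [model_spec()]s.
#' @export
default_model_grid <- function(families = c("knn", "gnb", "svm", "rf")) {
  grid <- list()
  if ("knn" %in% families)
    grid <- c(grid, lapply(c(3L, 5L, 7L, 9L), function(k) model_spec("knn", k = k)))
  if ("gnb" %in% families) grid <- c(grid, list(model_spec("gnb")))
  if ("svm" %in% families) grid <- c(grid, list(model_spec("svm", cost = 1)))
  if ("rf" %in% families) grid <- c(grid, list(model_spec("rf", num_trees = 128L)))
  grid
}

fit_classifier <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fit <- switch(spec$family,
    knn = list(x = x, y = y, k = spec$pars$k %||% 5L),
    gnb = e1071::naiveBayes(x, factor(y, levels = c(0L, 1L))),
    svm = e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                     cost = spec$pars$cost %||% 1, scale = FALSE),
    rf = ranger::ranger(y = factor(y, levels = c(0L, 1L)), x = as.data.frame(x),
                        probability = TRUE,
                        num.trees = spec$pars$num_trees %||% 128L,
                        seed = seed, num.threads = 1L))
  structure(list(spec = spec, fit = fit, seed = seed),
            class = "fitted_classifier")
}

predict_score <- function(model, newx) {
  newx <- as.matrix(newx)
  spec <- model$spec
  switch(spec$family,
    knn = knn_predict_score(model$fit$x, model$fit$y, newx, model$fit$k),
    gnb = unname(stats::predict(model$fit, newx, type = "raw")[, "1"]),
    svm = {
      dv <- attr(stats::predict(model$fit, newx, decision.values = TRUE),
                 "decision.values")
      # decision values are signed towards the first factor level ("0")
      sgn <- if (grepl("^0/", colnames(dv)[1])) -1 else 1
      sgn * drop(dv)
    },
    rf = unname(stats::predict(model$fit, data = as.data.frame(newx),
                               num.threads = 1L)$predictions[, "1"]))
}

#' Stratified cross-validation folds
#'
#' @param labels binary 0/1 labels.
#' @param folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids (1..folds), one per case.
#' @export
stratified_folds <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  rng <- local({
    set.seed(seed)
    lapply(c(0L, 1L), function(cl) sample(which(labels == cl)))
  })
  for (idx in rng)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  if (any(vapply(seq_len(folds), function(f)
    length(unique(labels[fold == f])) < 2L, logical(1))))
    stop("stratification error: a fold contains a single class")
  fold
}

#' Cross-validated ROC-AUC of one model on one feature set
#'
#' Stratified fivefold split; per fold, fit on the remaining folds and score
#' the held-out cases.
#'
#' @param x reduced feature matrix (rows = training cases).
#' @param y binary labels.
#' @param spec a [model_spec()].
#' @param folds number of folds (default 5) or a precomputed fold-id vector.
#' @param seed seed for the fold split and any stochastic learner.
#' @return numeric vector of per-fold AUCs.
#' @export
cv_auc <- function(x, y, spec, folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fold <- if (length(folds) == length(y)) folds else
    stratified_folds(y, folds, seed)
  vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    model <- fit_classifier(spec, x[tr, , drop = FALSE], y[tr], seed = seed)
    auc_mann_whitney(predict_score(model, x[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
}

# fast path: per-fold mean CV AUC of all knn k values at once, with the
# neighbour search (same row-order tie-breaking as knn_predict_score) in C++
cv_auc_knn_multi <- function(x, y, ks, fold) {
  scores <- cpp_knn_cv_scores(as.matrix(x), as.integer(y), as.integer(fold),
                              as.integer(ks))
  folds <- sort(unique(fold))
  aucs <- vapply(folds, function(f) {
    sel <- fold == f
    vapply(seq_along(ks), function(j)
      auc_mann_whitney(scores[sel, j], y[sel]), numeric(1))
  }, numeric(length(ks)))
  rowMeans(matrix(aucs, nrow = length(ks)))
}

#' Select a fixed-size signature by sequential forward selection
#'
#' Greedy forward selection to `signature_size` meta-features, scoring each
#' candidate set by mean stratified fivefold cross-validated ROC-AUC jointly
#' over the candidate model grid: at every step the (feature, model) pair
#' with the best mean CV AUC wins; ties are broken by lower model complexity,
#' then lexicographic feature name. The final classifier is refitted on the
#' full training cohort.
#'
#' @param x reduced training matrix (meta-feature columns).
#' @param y binary training labels.
#' @param grid list of [model_spec()]s (default [default_model_grid()]).
#' @param signature_size number of meta-features to select (default 5).
#' @param folds CV folds (default 5).
#' @param seed seed for fold assignment and stochastic learners.
#' @return object of class `radiomic_signature`: selected feature names (in
#'   selection order), winning model spec, fitted classifier, per-fold AUCs
#'   and their mean/sd.
#' @export
select_signature <- function(x, y, grid = default_model_grid(),
                             signature_size = 5L, folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training labels")
  if (!length(grid)) stop("empty model grid")
  if (signature_size > ncol(x))
    stop("signature_size exceeds the number of available meta-features")
  if (length(y) < 2L * folds) stop("too few cases for the requested folds")
  fold <- stratified_folds(y, folds, seed)
  knn_specs <- Filter(function(s) s$family == "knn", grid)
  other_specs <- Filter(function(s) s$family != "knn", grid)
  ks <- as.integer(vapply(knn_specs, function(s) s$pars$k %||% 5L,
                          numeric(1)))
  selected <- character(0)
  history <- list()
  for (step in seq_len(signature_size)) {
    pool <- setdiff(colnames(x), selected)
    best <- NULL
    for (f in sort(pool)) {
      cols <- c(selected, f)
      xs <- x[, cols, drop = FALSE]
      cand <- list()
      if (length(ks)) {
        mk <- cv_auc_knn_multi(xs, y, ks, fold)
        cand <- c(cand, lapply(seq_along(ks), function(j)
          list(spec = knn_specs[[j]], mean_auc = mk[j])))
      }
      cand <- c(cand, lapply(other_specs, function(sp)
        list(spec = sp, mean_auc = mean(cv_auc(xs, y, sp, fold, seed)))))
      for (cd in cand) {
        better <- is.null(best) ||
          cd$mean_auc > best$mean_auc + 1e-12 ||
          (abs(cd$mean_auc - best$mean_auc) <= 1e-12 &&
             (cd$spec$complexity < best$spec$complexity ||
                (cd$spec$complexity == best$spec$complexity && f < best$feature)))
        if (better) best <- list(feature = f, spec = cd$spec,
                                 mean_auc = cd$mean_auc)
      }
    }
    selected <- c(selected, best$feature)
    history[[step]] <- best
  }
  final_spec <- history[[signature_size]]$spec
  fold_aucs <- cv_auc(x[, selected, drop = FALSE], y, final_spec, fold, seed)
  model <- fit_classifier(final_spec, x[, selected, drop = FALSE], y,
                          seed = seed)
  structure(list(features = selected, spec = final_spec, model = model,
                 fold_aucs = fold_aucs, mean_cv_auc = mean(fold_aucs),
                 sd_cv_auc = stats::sd(fold_aucs), folds = folds,
                 seed = seed,
                 history = lapply(history, function(h)
                   list(feature = h$feature, model = h$spec$label,
                        mean_auc = h$mean_auc))),
            class = "radiomic_signature")
}

#' Validate a frozen signature on an external cohort
#'
#' Scores every validation case with the already-fitted classifier (nothing
#' is refitted), sweeps the ROC over the observed scores, and cross-checks
#' the trapezoid AUC against the Mann-Whitney U statistic on every call.
#'
#' @param signature a [select_signature()] result.
#' @param x_val reduced validation matrix produced by the frozen training
#'   reducer.
#' @param y_val binary validation labels.
#' @return object of class `validation_report`: `scores`, `roc`, `auc`.
#' @export
validate_external <- function(signature, x_val, y_val) {
  x_val <- as.matrix(x_val)
  missing <- setdiff(signature$features, colnames(x_val))
  if (length(missing))
    stop("validation table lacks signature meta-feature(s): ",
         paste(missing, collapse = ", "))
  scores <- predict_score(signature$model,
                          x_val[, signature$features, drop = FALSE])
  roc <- roc_curve(scores, y_val)
  auc <- auc_trapezoid(roc)
  mw <- auc_mann_whitney(scores, y_val)
  stopifnot(abs(auc - mw) < 1e-10) # internal consistency contract
  structure(list(scores = scores, roc = roc, auc = auc, n = length(y_val)),
            class = "validation_report")
}
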