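# Train-only feature reduction: robust IQR scaling, hierarchical clustering
# of correlated features, one first-principal-component meta-feature per
# cluster, then a variance filter. Everything is fitted on the training
# cohort and applied frozen to validation rows (no-leakage contract).

feature_matrix <- function(table, features = NULL) {
  df <- as.data.frame(table)
  if (is.null(features))
    features <- setdiff(names(df), meta_columns())
  missing <- setdiff(features, names(df))
  if (length(missing))
    stop("table is missing feature column(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  as.matrix(df[features])
}

#' Fit a robust (median/IQR) scaler on training rows
#'
#' Scaled value = `(x - median) / IQR` with `IQR = Q3 - Q1` learned per
#' feature from the training rows only. Features with zero IQR are flagged
#' and passed through with divisor 1; being constant on the training data,
#' they are removed later by the variance filter.
#'
#' @param train_table training feature table (data.frame; non-feature columns
#'   in [meta_columns()] are ignored).
#' @return object of class `robust_scaler` with `median`, `iqr`,
#'   `zero_iqr` and `features`.
#' @export
fit_scaler <- function(train_table) {
  X <- feature_matrix(train_table)
  if (nrow(X) < 3L) stop("need >= 3 training rows to fit the scaler")
  med <- apply(X, 2, stats::median)
  q <- apply(X, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- q[2, ] - q[1, ]
  zero <- iqr == 0
  structure(list(median = med, iqr = ifelse(zero, 1, iqr), zero_iqr = zero,
                 features = colnames(X)),
            class = "robust_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param table feature table; must contain every fitted feature column.
#' @return numeric matrix of scaled features (rows as in `table`).
#' @export
apply_scaler <- function(scaler, table) {
  X <- feature_matrix(table, scaler$features)
  scale(X, center = scaler$median, scale = scaler$iqr)[, , drop = FALSE]
}

#' Cluster correlated features hierarchically
#'
#' Agglomerative clustering with distance `1 - |r|` (Pearson) and complete
#' linkage, cut at the distance corresponding to the correlation threshold.
#' Complete linkage makes the cut semantics exact: every pair inside a
#' cluster correlates above the threshold. `absolute = TRUE` (default)
#' treats anti-correlated features as redundant. Zero-variance features get
#' singleton clusters (their correlation is undefined).
#'
#' @param scaled_train scaled training matrix from [apply_scaler()].
#' @param threshold correlation cut, default 0.95.
#' @param linkage hclust linkage, default `"complete"`.
#' @param absolute cluster on `|r|` rather than `r`.
#' @return object of class `feature_clustering`: list with `clusters` (named
#'   list of member character vectors), `threshold`, `linkage`, `absolute`.
#' @export
cluster_features <- function(scaled_train, threshold = 0.95,
                             linkage = "complete", absolute = TRUE) {
  X <- as.matrix(scaled_train)
  if (nrow(X) < 3L) stop("need >= 3 rows to estimate correlations")
  if (!all(is.finite(X))) stop("non-finite values in scaled features")
  sds <- apply(X, 2, stats::sd)
  live <- sds > 0
  members <- list()
  if (sum(live) >= 2L) {
    r <- stats::cor(X[, live, drop = FALSE])
    if (absolute) r <- abs(r)
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = linkage)
    grp <- stats::cutree(hc, h = 1 - threshold)
    members <- split(colnames(X)[live], grp)
  } else if (sum(live) == 1L) {
    members <- list(colnames(X)[live])
  }
  members <- c(members, as.list(colnames(X)[!live]))
  names(members) <- sprintf("cluster_%04d", seq_along(members))
  structure(list(clusters = members, threshold = threshold,
                 linkage = linkage, absolute = absolute),
            class = "feature_clustering")
}

#' Collapse clusters to first-principal-component meta-features
#'
#' Each multi-member cluster becomes the first principal-component score of
#' its (train-centred) member columns — the single direction conserving the
#' maximum variance inside the cluster. Loadings are unit-norm with the sign
#' fixed so the largest-magnitude loading is positive; singleton clusters
#' pass through unchanged. Meta-features whose training variance is lower
#' than `variance_threshold` (default 0.3) are then dropped, and the
#' surviving set and order are frozen for validation application.
#'
#' @param scaled_train scaled training matrix.
#' @param clustering a [cluster_features()] result.
#' @param variance_threshold strict lower bound on the training variance.
#' @return object of class `metafeature_projector`.
#' @export
fit_metafeatures <- function(scaled_train, clustering,
                             variance_threshold = 0.3) {
  X <- as.matrix(scaled_train)
  comps <- lapply(seq_along(clustering$clusters), function(k) {
    memb <- clustering$clusters[[k]]
    M <- X[, memb, drop = FALSE]
    centre <- colMeans(M)
    if (length(memb) == 1L) {
      loading <- 1
      score <- M[, 1]
      centre <- 0 # identity passthrough, not centred
      name <- memb
    } else {
      Mc <- sweep(M, 2, centre)
      sv <- svd(Mc, nu = 0, nv = 1)
      loading <- sv$v[, 1]
      if (loading[which.max(abs(loading))] < 0) loading <- -loading
      score <- drop(Mc %*% loading)
      name <- sprintf("mf%04d_%s", k, memb[which.max(abs(loading))])
    }
    list(name = name, members = memb, centre = centre, loading = loading,
         variance = stats::var(score), explained = NULL, score = score)
  })
  vars <- vapply(comps, `[[`, numeric(1), "variance")
  keep <- vars >= variance_threshold
  if (!any(keep))
    stop("empty meta-feature set: no meta-feature reaches the variance threshold")
  structure(list(components = lapply(comps[keep], function(cp)
    cp[c("name", "members", "centre", "loading")]),
    names = vapply(comps[keep], `[[`, character(1), "name"),
    variances = vars[keep],
    dropped = vapply(comps[!keep], `[[`, character(1), "name"),
    variance_threshold = variance_threshold,
    clustering = clustering[c("threshold", "linkage", "absolute")]),
    class = "metafeature_projector")
}

#' Apply a fitted meta-feature projector
#'
#' @param projector a [fit_metafeatures()] result.
#' @param scaled scaled feature matrix (training or validation rows).
#' @return numeric matrix of meta-feature columns, in the frozen order.
#' @export
apply_metafeatures <- function(projector, scaled) {
  X <- as.matrix(scaled)
  if (!all(is.finite(X))) stop("non-finite values in scaled features")
  out <- vapply(projector$components, function(cp) {
    M <- X[, cp$members, drop = FALSE]
    drop(sweep(M, 2, cp$centre) %*% cp$loading)
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X), projector$names))
  out
}

#' Fit the full reduction (scaler + clustering + meta-features) on training rows
#'
#' @param train_table training feature table.
#' @param correlation_threshold cluster cut, default 0.95.
#' @param variance_threshold meta-feature variance filter, default 0.3.
#' @param linkage,absolute passed to [cluster_features()].
#' @return object of class `feature_reducer` bundling the frozen scaler,
#'   clustering and projector.
#' @export
fit_reducer <- function(train_table, correlation_threshold = 0.95,
                        variance_threshold = 0.3, linkage = "complete",
                        absolute = TRUE) {
  scaler <- fit_scaler(train_table)
  Xs <- apply_scaler(scaler, train_table)
  clustering <- cluster_features(Xs, threshold = correlation_threshold,
                                 linkage = linkage, absolute = absolute)
  projector <- fit_metafeatures(Xs, clustering,
                                variance_threshold = variance_threshold)
  structure(list(scaler = scaler, clustering = clustering,
                 projector = projector),
            class = "feature_reducer")
}

#' @rdname fit_reducer
#' @param reducer a fitted `feature_reducer`.
#' @param table feature table to reduce (training or validation).
#' @export
apply_reducer <- function(reducer, table) {
  apply_metafeatures(reducer$projector, apply_scaler(reducer$scaler, table))
}

#' Serialise / restore a fitted reducer as JSON
#'
#' Stores medians, IQRs, cluster membership, loadings and the kept
#' meta-feature list so a validation run is exactly reproducible.
#'
#' @param reducer a `feature_reducer`.
#' @param path JSON output path.
#' @return `path` (write) or a `feature_reducer` (read).
#' @export
write_reducer <- function(reducer, path) {
  jsonlite::write_json(reducer_to_list(reducer), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

reducer_to_list <- function(reducer) {
  list(
    scaler = list(features = reducer$scaler$features,
                  median = unname(reducer$scaler$median),
                  iqr = unname(reducer$scaler$iqr),
                  zero_iqr = unname(reducer$scaler$zero_iqr)),
    clustering = reducer$projector$clustering,
    variance_threshold = reducer$projector$variance_threshold,
    components = lapply(reducer$projector$components, function(cp)
      list(name = cp$name, members = cp$members,
           centre = unname(cp$centre), loading = unname(cp$loading))))
}

#' @rdname write_reducer
#' @export
read_reducer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- unlist(obj$scaler$features)
  scaler <- structure(list(
    median = stats::setNames(unlist(obj$scaler$median), feats),
    iqr = stats::setNames(unlist(obj$scaler$iqr), feats),
    zero_iqr = stats::setNames(unlist(obj$scaler$zero_iqr), feats),
    features = feats), class = "robust_scaler")
  components <- lapply(obj$components, function(cp)
    list(name = cp$name, members = unlist(cp$members),
         centre = unlist(cp$centre), loading = unlist(cp$loading)))
  projector <- structure(list(
    components = components,
    names = vapply(components, `[[`, character(1), "name"),
    variance_threshold = obj$variance_threshold,
    clustering = obj$clustering), class = "metafeature_projector")
  structure(list(scaler = scaler, clustering = obj$clustering,
                 projector = projector), class = "feature_reducer")
}
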