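# Texture features over the five grey-level matrix families. Matrices are
# built in C++ (see src/texture.cpp) over the 13 unique 3-D directions with
# 26-connected zones/neighbourhoods; counts are merged over directions by
# default ("merged" aggregation) or features averaged over per-direction
# matrices ("averaged").

directions_13 <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,
           1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

to_int_dirs <- function(dirs) {
  storage.mode(dirs) <- "integer"
  dirs
}

crop_to_bbox <- function(levels) {
  idx <- which(levels > 0L, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  levels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
}

aggregate_family <- function(levels, ng, feature_fun, matrix_fun,
                             aggregation) {
  dirs <- to_int_dirs(directions_13())
  if (aggregation == "merged") {
    feature_fun(matrix_fun(levels, dirs), ng)
  } else {
    per_dir <- lapply(seq_len(nrow(dirs)), function(i)
      feature_fun(matrix_fun(levels, dirs[i, , drop = FALSE]), ng))
    Reduce(`+`, per_dir) / length(per_dir)
  }
}

#' Grey-level co-occurrence features
#'
#' Co-occurrences at Chebyshev distance 1, symmetric, merged over the 13
#' unique 3-D directions (or feature-averaged with
#' `aggregation = "averaged"`), normalised to a joint probability matrix.
#' 25 IBSI-style features including Cluster Tendency
#' `sum_ij (i + j - 2 mu)^2 p(i,j)`. Correlation-type features are 0 by
#' convention when the marginal variance vanishes (single-level ROI).
#'
#' @param d a [discretise()] result.
#' @param aggregation `"merged"` (default) or `"averaged"`.
#' @return named numeric vector of length 25.
#' @export
glcm_features <- function(d, aggregation = c("merged", "averaged")) {
  aggregation <- match.arg(aggregation)
  lev <- crop_to_bbox(d$levels)
  aggregate_family(lev, d$n_levels, glcm_from_counts,
                   function(l, dirs) cpp_glcm(as.integer(l), dim(l),
                                              d$n_levels, dirs),
                   aggregation)
}

# per-Ng index machinery for the GLCM formulas, memoised: row/column index
# matrices and cumulative-sum orderings for the |i-j| and i+j marginals
.glcm_idx_cache <- new.env(parent = emptyenv())
glcm_index <- function(ng) {
  key <- as.character(ng)
  if (!is.null(.glcm_idx_cache[[key]])) return(.glcm_idx_cache[[key]])
  i <- matrix(rep(seq_len(ng), ng), ng)
  j <- t(i)
  kd <- abs(i - j)
  ks <- i + j
  group_sums <- function(g) {
    ord <- order(as.vector(g))
    ends <- cumsum(tabulate(as.vector(g)[ord] - min(g) + 1L))
    list(ord = ord, ends = ends)
  }
  out <- list(i = i, j = j, kd = kd, gd = group_sums(kd), gs = group_sums(ks))
  .glcm_idx_cache[[key]] <- out
  out
}

glcm_from_counts <- function(counts, ng) {
  P <- counts / max(sum(counts), 1)
  ix <- glcm_index(ng)
  i <- ix$i
  j <- ix$j
  pi_ <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  # diagonal (|i-j|, dense over 0..ng-1) and cross-diagonal (i+j, dense over
  # 2..2ng) probability distributions via precomputed orderings
  marg <- function(g) {
    cs <- cumsum(as.vector(P)[g$ord])
    diff(c(0, cs[g$ends]))
  }
  pd <- marg(ix$gd)
  ps <- marg(ix$gs)
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps)
  hxy <- xlogx(P)
  hx <- xlogx(pi_)
  pipj <- outer(pi_, pi_)
  hxy1 <- -sum(P[pipj > 0] * log2(pipj[pipj > 0]))
  hxy2 <- -sum(pipj[pipj > 0] * log2(pipj[pipj > 0]))
  ic2sq <- 1 - 2^(-2 * (hxy2 - hxy))
  c(glcm_joint_max = max(P),
    glcm_joint_avg = mu,
    glcm_joint_var = sig2,
    glcm_joint_entropy = hxy,
    glcm_diff_avg = da,
    glcm_diff_var = sum(((0:(ng - 1)) - da)^2 * pd),
    glcm_diff_entropy = xlogx(pd),
    glcm_sum_avg = sa,
    glcm_sum_var = sum(((2:(2 * ng)) - sa)^2 * ps),
    glcm_sum_entropy = xlogx(ps),
    glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_inv_diff = sum(P / (1 + abs(i - j))),
    glcm_inv_diff_norm = sum(P / (1 + abs(i - j) / ng)),
    glcm_inv_diff_mom = sum(P / (1 + (i - j)^2)),
    glcm_inv_diff_mom_norm = sum(P / (1 + (i - j)^2 / ng^2)),
    glcm_inv_var = sum(P[i != j] / (i - j)[i != j]^2),
    glcm_correlation = if (sig2 == 0) 0 else
      sum((i - mu) * (j - mu) * P) / sig2,
    glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_info_corr1 = if (hx == 0) 0 else (hxy - hxy1) / hx,
    glcm_info_corr2 = sqrt(max(ic2sq, 0)))
}

#' Grey-level run-length features
#'
#' Runs of equal level along the 13 directions (merged counts by default).
#' Includes Grey-Level Variance `sum_ij (i - mu)^2 p(i,j)` over the run
#' probability matrix.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(d, aggregation = c("merged", "averaged")) {
  aggregation <- match.arg(aggregation)
  lev <- crop_to_bbox(d$levels)
  nv <- sum(lev > 0L)
  # run percentage denominator: voxels x directions under merged aggregation
  ndir <- if (aggregation == "merged") 13 else 1
  aggregate_family(lev, d$n_levels,
                   function(counts, ng) rl_family_features(counts, ng, nv * ndir, "glrlm"),
                   function(l, dirs) cpp_glrlm(as.integer(l), dim(l),
                                               d$n_levels, dirs),
                   aggregation)
}

# shared run-length / size-zone / distance-zone feature kernel:
# counts is an Ng x J matrix over (level, j) with j = run length, zone size
# or zone distance.
rl_family_features <- function(counts, ng, nv, prefix) {
  counts <- as.matrix(counts)
  ns <- sum(counts)
  P <- counts / max(ns, 1)
  i <- row(P); j <- col(P)
  gi <- rowSums(counts)
  rj <- colSums(counts)
  mu_i <- sum(i * P)
  mu_j <- sum(j * P)
  out <- c(
    sje = sum(P / j^2),
    lje = sum(P * j^2),
    lgle = sum(P / i^2),
    hgle = sum(P * i^2),
    sjlge = sum(P / (i^2 * j^2)),
    sjhge = sum(P * i^2 / j^2),
    ljlge = sum(P * j^2 / i^2),
    ljhge = sum(P * i^2 * j^2),
    glnu = sum(gi^2) / max(ns, 1),
    glnu_norm = sum(gi^2) / max(ns, 1)^2,
    jnu = sum(rj^2) / max(ns, 1),
    jnu_norm = sum(rj^2) / max(ns, 1)^2,
    j_pct = ns / nv,
    grey_level_variance = sum((i - mu_i)^2 * P),
    j_variance = sum((j - mu_j)^2 * P),
    j_entropy = xlogx(P)
  )
  names(out) <- paste0(prefix, "_", rl_feature_names(prefix))
  out
}

rl_feature_names <- function(prefix) {
  lohi <- function(a, b) c(
    paste0(a, "_low_grey_level_emphasis"),
    paste0(a, "_high_grey_level_emphasis"),
    paste0(b, "_low_grey_level_emphasis"),
    paste0(b, "_high_grey_level_emphasis"))
  shared <- c("grey_level_nonuniformity", "grey_level_nonuniformity_norm")
  switch(prefix,
    glrlm = c("short_run_emphasis", "long_run_emphasis",
              "low_grey_level_emphasis", "high_grey_level_emphasis",
              lohi("short_run", "long_run"), shared,
              "run_length_nonuniformity", "run_length_nonuniformity_norm",
              "run_percentage", "grey_level_variance",
              "run_length_variance", "run_entropy"),
    glszm = c("small_zone_emphasis", "large_zone_emphasis",
              "low_grey_level_emphasis", "high_grey_level_emphasis",
              lohi("small_zone", "large_zone"), shared,
              "zone_size_nonuniformity", "zone_size_nonuniformity_norm",
              "zone_percentage", "grey_level_variance",
              "zone_size_variance", "zone_entropy"),
    gldzm = c("small_distance_emphasis", "large_distance_emphasis",
              "low_grey_level_emphasis", "high_grey_level_emphasis",
              lohi("small_distance", "large_distance"), shared,
              "zone_distance_nonuniformity", "zone_distance_nonuniformity_norm",
              "zone_percentage", "grey_level_variance",
              "zone_distance_variance", "zone_distance_entropy"))
}

#' Grey-level size-zone features
#'
#' Zones are 26-connected components of equal level; the count matrix is over
#' (level, zone size). Large Zone Emphasis is `sum s^2 p(s)`.
#'
#' @param d a [discretise()] result.
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(d) {
  lev <- crop_to_bbox(d$levels)
  glszm_core(zone_table(lev), d$n_levels, sum(lev > 0L))
}

glszm_core <- function(zones, ng, nv) {
  counts <- zone_count_matrix(zones[, "level"], zones[, "size"], ng)
  rl_family_features(counts, ng, nv, "glszm")
}

#' Grey-level distance-zone features
#'
#' Same zones as [glszm_features()], but the second axis is the zone
#' distance: the minimum Chebyshev distance of the zone's voxels to outside
#' the ROI, with border voxels at distance 1.
#'
#' @param d a [discretise()] result.
#' @return named numeric vector of length 16.
#' @export
gldzm_features <- function(d) {
  lev <- crop_to_bbox(d$levels)
  gldzm_core(zone_table(lev), d$n_levels, sum(lev > 0L))
}

gldzm_core <- function(zones, ng, nv) {
  counts <- zone_count_matrix(zones[, "level"], zones[, "distance"], ng)
  rl_family_features(counts, ng, nv, "gldzm")
}

# all five texture families on one discretised channel, computing the
# cropped array and the zone decomposition once
texture_block <- function(d, aggregation = "merged") {
  lev <- crop_to_bbox(d$levels)
  nv <- sum(lev > 0L)
  zones <- zone_table(lev)
  dsub <- list(levels = lev, n_levels = d$n_levels, scheme = d$scheme,
               spacing_mm = d$spacing_mm)
  class(dsub) <- "discretised_roi"
  c(glcm_features(dsub, aggregation),
    glrlm_features(dsub, aggregation),
    glszm_core(zones, d$n_levels, nv),
    gldzm_core(zones, d$n_levels, nv),
    ngtdm_features(dsub))
}

zone_table <- function(lev) {
  dist <- cpp_roi_distance_map(as.integer(lev), dim(lev))
  cpp_zones(as.integer(lev), dim(lev), as.integer(dist))
}

zone_count_matrix <- function(level, j, ng) {
  jm <- max(j)
  counts <- matrix(0, nrow = ng, ncol = jm)
  for (k in seq_along(level)) counts[level[k], j[k]] <- counts[level[k], j[k]] + 1
  counts
}

#' Neighbourhood grey-tone difference features
#'
#' Per-level sums `s_i` of the absolute difference between a voxel's level
#' and the mean of its valid 26-neighbourhood, with the occupied-level
#' probability vector `p_i`. Conventions on degenerate input: coarseness is
#' capped at 1e6 when the denominator vanishes; busyness and strength are 0
#' when their denominators vanish.
#'
#' @param d a [discretise()] result.
#' @return named numeric vector of length 5 (coarseness, contrast, busyness,
#'   complexity, strength).
#' @export
ngtdm_features <- function(d) {
  lev <- crop_to_bbox(d$levels)
  ng <- d$n_levels
  sn <- cpp_ngtdm(as.integer(lev), dim(lev), ng)
  s <- sn[, 1]
  n_i <- sn[, 2]
  nv <- sum(n_i)
  p <- n_i / nv
  occ <- which(p > 0)
  np <- length(occ)
  denom_coarse <- sum(p * s)
  po <- p[occ]
  so <- s[occ]
  dij <- outer(occ, occ, `-`)
  pij <- outer(po, po, `+`)
  contrast <- if (np <= 1) 0 else
    sum(outer(po, po) * dij^2) / (np * (np - 1)) * sum(s) / nv
  busy_den <- sum(abs(outer(occ * po, occ * po, `-`)))
  complexity <- sum(abs(dij) * outer(po * so, po * so, `+`) / pij) / nv
  strength <- if (sum(s) == 0) 0 else sum(pij * dij^2) / sum(s)
  c(ngtdm_coarseness = min(1 / max(denom_coarse, 1e-6), 1e6),
    ngtdm_contrast = contrast,
    ngtdm_busyness = if (busy_den == 0) 0 else denom_coarse / busy_den,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
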