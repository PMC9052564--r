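#' Intensity features of a region of interest
#'
#' Computes the 48 first-order features of the catalogue from the masked
#' intensities: 18 intensity statistics (moments use the population
#' convention, divisor n), 23 intensity-histogram features on the discretised
#' grey levels, and 7 intensity-volume-histogram features. Degenerate
#' conventions guarantee finite values on constant ROIs: coefficients of
#' variation and dispersion are 0 when their denominator is 0, `0 log 0 = 0`,
#' and histogram gradients of a single-level histogram are 0 at level 1.
#'
#' @param values numeric vector of in-ROI intensities (non-empty).
#' @param levels integer vector of in-ROI grey levels (same length), e.g.
#'   `d$levels[d$levels > 0]` from [discretise()].
#' @param n_levels number of grey levels Ng.
#' @return named numeric vector of length 48.
#' @export
intensity_features <- function(values, levels, n_levels) {
  stopifnot(length(values) > 0L, length(levels) == length(values))
  c(stat_features(values),
    histogram_features(levels, n_levels),
    ivh_features(values))
}

safe_div <- function(a, b, default = 0) if (b == 0) default else a / b

xlogx <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

moments_block <- function(x, prefix) {
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  qs <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                        type = 7)
  rob <- x[x >= qs[1] & x <= qs[5]]
  out <- c(
    mean = mu,
    variance = v,
    skewness = if (s == 0) 0 else sum((x - mu)^3) / n / s^3,
    kurtosis = if (s == 0) 0 else sum((x - mu)^4) / n / v^2 - 3,
    median = qs[3],
    minimum = min(x),
    p10 = qs[1],
    p90 = qs[5],
    maximum = max(x),
    iqr = qs[4] - qs[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = mean(abs(rob - mean(rob))),
    medad = mean(abs(x - qs[3])),
    cov = safe_div(s, mu),
    qcod = safe_div(qs[4] - qs[2], qs[4] + qs[2])
  )
  names(out) <- paste0(prefix, "_", names(out))
  out
}

stat_features <- function(x) {
  out <- moments_block(x, "stat")
  c(out, stat_energy = sum(x^2), stat_rms = sqrt(mean(x^2)))
}

histogram_features <- function(lev, ng) {
  counts <- tabulate(lev, nbins = ng)
  p <- counts / sum(counts)
  base <- moments_block(as.numeric(lev), "ih")
  grad <- if (ng >= 2) diff(counts) else 0
  gmax <- which.max(grad)
  gmin <- which.min(grad)
  mode_lev <- which.max(counts) # smallest level on ties
  c(base,
    ih_mode = as.numeric(mode_lev),
    ih_entropy = xlogx(p),
    ih_uniformity = sum(p^2),
    ih_max_grad = if (ng >= 2) max(grad) else 0,
    ih_max_grad_level = if (ng >= 2) as.numeric(gmax) else 1,
    ih_min_grad = if (ng >= 2) min(grad) else 0,
    ih_min_grad_level = if (ng >= 2) as.numeric(gmin) else 1)
}

# Intensity-volume histogram: nu(i) = fraction of ROI voxels with intensity
# >= i. V_x = nu at x% of the intensity range; I_x = smallest intensity whose
# nu is <= x% (constant ROI: all volume fractions 1, intensities the value).
ivh_features <- function(x) {
  lo <- min(x)
  hi <- max(x)
  n <- length(x)
  if (hi == lo) {
    v10 <- 1; v90 <- 1; i10 <- lo; i90 <- lo; auc <- 1
  } else {
    xs <- sort(x)
    # nu(i) = fraction of voxels with intensity >= i, vectorised over i
    nu <- function(i) (n - findInterval(i, xs, left.open = TRUE)) / n
    v10 <- nu(lo + 0.10 * (hi - lo))
    v90 <- nu(lo + 0.90 * (hi - lo))
    frac_ge <- (n - seq_len(n) + 1) / n
    pick <- function(thr) {
      idx <- match(TRUE, frac_ge <= thr)
      if (is.na(idx)) hi else xs[idx]
    }
    i10 <- pick(0.10)
    i90 <- pick(0.90)
    auc <- mean(nu(seq(lo, hi, length.out = 201L)))
  }
  c(ivh_v10 = v10, ivh_v90 = v90, ivh_i10 = i10, ivh_i90 = i90,
    ivh_v10_minus_v90 = v10 - v90, ivh_i10_minus_i90 = i10 - i90,
    ivh_auc = auc)
}
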