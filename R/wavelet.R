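#' Coiflet-1 analysis filter bank
#'
#' Returns the 6-tap coiflet-1 low-pass analysis filter together with its
#' quadrature-mirror high-pass counterpart. Under the default `"dc"`
#' normalisation the low-pass taps sum to 1, so low-pass-only channels (LLL)
#' preserve the mean HU of the input and wavelet intensity features stay on an
#' interpretable scale; `"orthonormal"` keeps the classical sqrt(2) scaling.
#'
#' @param normalisation `"dc"` (unit DC gain, default) or `"orthonormal"`.
#' @return An object of class `filter_bank`: a list with `name`, `lowpass`,
#'   `highpass` and `normalisation`.
#' @export
coif1_bank <- function(normalisation = c("dc", "orthonormal")) {
  normalisation <- match.arg(normalisation)
  # orthonormal coiflet-1 decomposition low-pass taps (sum = sqrt(2))
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  if (normalisation == "dc") lo <- lo / sum(lo)
  structure(
    list(name = "coif1", lowpass = lo, highpass = qmf_highpass(lo),
         normalisation = normalisation),
    class = "filter_bank"
  )
}

#' Quadrature-mirror high-pass filter of a low-pass filter
#'
#' `g[k] = (-1)^k * h[L + 1 - k]` (1-based), which has zero DC gain for any
#' low-pass `h`.
#'
#' @param lowpass numeric vector of low-pass taps.
#' @return numeric vector of high-pass taps, same length.
#' @export
qmf_highpass <- function(lowpass) {
  L <- length(lowpass)
  rev(lowpass) * (-1)^(seq_len(L))
}

# Fold an out-of-range 1-based index back into [1, n] by half-sample
# symmetric reflection (edge value repeated), period 2n.
sym_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

#' Filter a 1-D signal without decimation
#'
#' Correlates `x` with `kernel` under half-sample symmetric boundary padding,
#' keeping the output the same length as the input (undecimated). The kernel
#' is centred: tap `k` multiplies `x[i + k - 1 - floor((L-1)/2)]`.
#'
#' @param x numeric vector (non-empty).
#' @param kernel numeric filter taps.
#' @param boundary only `"symmetric"` is implemented.
#' @return numeric vector, `length(x)`.
#' @export
filter_1d <- function(x, kernel, boundary = "symmetric") {
  if (length(x) == 0L) stop("empty signal")
  boundary <- match.arg(boundary, "symmetric")
  n <- length(x)
  L <- length(kernel)
  pl <- (L - 1L) %/% 2L
  xp <- x[sym_index(seq.int(1L - pl, n + (L - 1L - pl)), n)]
  y <- numeric(n)
  for (k in seq_len(L)) y <- y + kernel[k] * xp[seq.int(k, k + n - 1L)]
  y
}

# n x n weight matrix W with y = W^T x equal to the centred symmetric-padded
# correlation of x with the kernel (same convention as filter_1d)
filter_weight_matrix <- function(kernel, n) {
  L <- length(kernel)
  pl <- (L - 1L) %/% 2L
  rows <- sym_index(seq.int(1L - pl, n + (L - 1L - pl)), n)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(L)) {
      r <- rows[i + k - 1L]
      W[r, i] <- W[r, i] + kernel[k]
    }
  }
  W
}

# Apply a 1-D kernel along one axis of a 3-D array (same boundary and
# centring as filter_1d), as dense matrix products along the chosen axis.
apply_filter_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  W <- filter_weight_matrix(kernel, n)
  if (axis == 1L) {
    array(crossprod(W, matrix(arr, nrow = n)), d)
  } else if (axis == 3L) {
    array(matrix(arr, ncol = n) %*% W, d)
  } else {
    out <- arr
    for (z in seq_len(d[3L])) out[, , z] <- arr[, , z] %*% W
    out
  }
}

#' One-level undecimated separable wavelet decomposition
#'
#' Filters the full volume along x, y and z with every low/high-pass
#' combination of the bank, producing the 8 channels `LLL` .. `HHH` plus the
#' untouched `original` channel. Channel label letter order is (x, y, z):
#' channel `"HLL"` is high-pass along x, low-pass along y and z. No
#' downsampling is performed, so every channel has the input's shape.
#'
#' @param volume a [ct_volume()] or a 3-D numeric array.
#' @param bank a [coif1_bank()]-style filter bank.
#' @return named list of 9 arrays (`original`, `LLL`, `HLL`, `LHL`, `HHL`,
#'   `LLH`, `HLH`, `LHH`, `HHH`).
#' @export
wavelet_decompose <- function(volume, bank = coif1_bank()) {
  arr <- if (inherits(volume, "ct_volume")) volume$intensities else volume
  if (!(is.array(arr) && length(dim(arr)) == 3L))
    stop("volume must be a 3-D array or ct_volume")
  L <- length(bank$lowpass)
  if (any(dim(arr) < L))
    stop(sprintf("volume dimensions %s are smaller than the filter length %d",
                 paste(dim(arr), collapse = "x"), L))
  kern <- list(L = bank$lowpass, H = bank$highpass)
  ax1 <- lapply(kern, function(k) apply_filter_axis(arr, k, 1L))
  out <- list(original = arr)
  for (cz in c("L", "H")) for (cy in c("L", "H")) for (cx in c("L", "H")) {
    lab <- paste0(cx, cy, cz)
    out[[lab]] <- apply_filter_axis(
      apply_filter_axis(ax1[[cx]], kern[[cy]], 2L), kern[[cz]], 3L)
  }
  # fixed catalogue order
  out[c("original", "LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}
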