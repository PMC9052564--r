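#' Extract the masked intensities of a case
#'
#' Returns the ROI voxel values in fixed (z, y, x) scan order (x fastest),
#' together with the grid information needed by the texture stages.
#'
#' @param volume a [ct_volume()] or 3-D array.
#' @param mask a [roi_mask()] (grid-checked against the volume).
#' @return object of class `roi_voxels`: list with `values`, logical `mask`
#'   array, and `spacing_mm`.
#' @export
extract_roi <- function(volume, mask) {
  arr <- if (inherits(volume, "ct_volume")) volume$intensities else volume
  if (inherits(volume, "ct_volume")) check_same_grid(volume, mask)
  else if (!identical(dim(arr), dim(mask$voxels)))
    stop("grid mismatch between volume array and mask")
  vox <- mask$voxels
  if (!any(vox)) stop("empty ROI")
  structure(list(values = arr[vox], mask = vox,
                 spacing_mm = mask$spacing_mm),
            class = "roi_voxels")
}

#' Discretisation scheme for grey-level binning
#'
#' Two schemes are supported. `"fbs"` (fixed bin size): level =
#' `floor((value - anchor) / bin_width) + 1`, clamped at 1 — the default for
#' calibrated HU (width 25 HU anchored at -1000 HU). `"fbn"` (fixed bin
#' number): `n_bins` equal-width bins over the observed `[min, max]`, the
#' maximum mapped to `n_bins` — the default for wavelet channels, whose
#' intensities carry no absolute scale.
#'
#' @param method `"fbs"` or `"fbn"`.
#' @param bin_width positive bin width (fbs).
#' @param anchor lower edge of bin 1 (fbs).
#' @param n_bins integer >= 2 (fbn).
#' @return object of class `discretisation_scheme`.
#' @export
discretisation_scheme <- function(method = c("fbs", "fbn"), bin_width = 25,
                                  anchor = -1000, n_bins = 64L) {
  method <- match.arg(method)
  if (method == "fbs" && (!is.finite(bin_width) || bin_width <= 0))
    stop("bin_width must be positive")
  if (method == "fbn" && n_bins < 2L) stop("n_bins must be >= 2")
  structure(list(method = method, bin_width = bin_width, anchor = anchor,
                 n_bins = as.integer(n_bins)),
            class = "discretisation_scheme")
}

#' Discretise ROI intensities into grey levels
#'
#' Maps each in-ROI voxel to an integer level in `1..Ng` (0 outside the ROI);
#' `Ng` is the maximum observed level. A constant ROI under `"fbn"` yields a
#' single-level result (`Ng = 1`), not an error. Discretisation is monotone
#' and idempotent in the sense that re-binning the same values under the same
#' scheme reproduces the levels.
#'
#' @param roi an [extract_roi()] result.
#' @param scheme a [discretisation_scheme()].
#' @return object of class `discretised_roi`: list with integer `levels`
#'   array, `n_levels`, the `scheme`, and `spacing_mm`.
#' @export
discretise <- function(roi, scheme = discretisation_scheme()) {
  stopifnot(inherits(roi, "roi_voxels"),
            inherits(scheme, "discretisation_scheme"))
  v <- roi$values
  lev <- discretise_values(v, scheme)
  grid <- array(0L, dim = dim(roi$mask))
  grid[roi$mask] <- lev
  structure(list(levels = grid, n_levels = max(lev), scheme = scheme,
                 spacing_mm = roi$spacing_mm),
            class = "discretised_roi")
}

# level assignment on a bare numeric vector (shared with histogram features)
discretise_values <- function(v, scheme) {
  if (scheme$method == "fbs") {
    pmax(1L, as.integer(floor((v - scheme$anchor) / scheme$bin_width)) + 1L)
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    w <- (rng[2] - rng[1]) / scheme$n_bins
    pmin(scheme$n_bins, as.integer(floor((v - rng[1]) / w)) + 1L)
  }
}
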