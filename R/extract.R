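#' Extract the full 1150-feature vector for one case
#'
#' Runs the whole single-case pipeline: one-level undecimated coiflet-1
#' decomposition of the full volume (filtering before masking, so wavelet
#' responses are not dominated by mask-boundary effects), then per channel a
#' masked ROI extraction, discretisation (fixed 25 HU bins anchored at
#' -1000 HU on the original channel, 64 fixed bins on wavelet channels) and
#' the intensity + five texture families; shape features are computed once
#' from the mask alone. Any non-finite feature raises an error naming it.
#'
#' @param volume a [ct_volume()].
#' @param mask the paired [roi_mask()].
#' @param config an [extraction_config()].
#' @param catalogue feature catalogue (default [feature_catalogue()]).
#' @return named numeric vector whose names are exactly `catalogue$name`.
#' @export
extract_features <- function(volume, mask, config = extraction_config(),
                             catalogue = feature_catalogue()) {
  check_same_grid(volume, mask)
  channels <- wavelet_decompose(volume, config$bank)
  out <- numeric(0)
  shp <- shape_features(mask)
  names(shp) <- paste0("original_", names(shp))
  out <- c(out, shp)
  # crop all channels to the mask bounding box once; texture and intensity
  # features only see in-ROI voxels so this is exact
  bbox <- mask_bbox(mask$voxels)
  sub <- function(a) a[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                       bbox[1, 3]:bbox[2, 3], drop = FALSE]
  vox <- sub(mask$voxels)
  submask <- roi_mask(vox, mask$spacing_mm)
  for (ch in names(channels)) {
    arr <- sub(channels[[ch]])
    roi <- extract_roi(arr, submask)
    if (ch == "original" && !is.null(config$clip))
      roi$values <- pmin(pmax(roi$values, config$clip[1]), config$clip[2])
    scheme <- if (ch == "original") config$scheme_original else
      config$scheme_wavelet
    d <- discretise(roi, scheme)
    lev_in <- d$levels[roi$mask]
    feats <- c(
      intensity_features(roi$values, lev_in, d$n_levels),
      texture_block(d, config$aggregation))
    names(feats) <- paste0(ch, "_", names(feats))
    out <- c(out, feats)
  }
  out <- out[catalogue$name]
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("non-finite feature(s): ", paste(utils::head(bad, 5), collapse = ", "))
  out
}

mask_bbox <- function(vox) {
  idx <- which(vox, arr.ind = TRUE)
  apply(idx, 2, range)
}

#' Extract features for a whole cohort
#'
#' @param cases list of cases (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config an [extraction_config()].
#' @param catalogue feature catalogue.
#' @return data.frame with `patient_id`, `cohort`, `trg`, `label`, then one
#'   column per catalogue feature.
#' @export
extract_cohort <- function(cases, config = extraction_config(),
                           catalogue = feature_catalogue()) {
  feats <- vapply(cases, function(cs)
    extract_features(cs$volume, cs$mask, config, catalogue),
    numeric(nrow(catalogue)))
  meta <- data.frame(
    patient_id = vapply(cases, `[[`, character(1), "patient_id"),
    cohort = vapply(cases, `[[`, character(1), "cohort"),
    trg = vapply(cases, function(cs) as.integer(cs$trg), integer(1)),
    label = vapply(cases, function(cs) as.integer(cs$label), integer(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(t(feats)))
}

#' Names of the non-feature columns of a feature table
#' @return character vector.
#' @export
meta_columns <- function() c("patient_id", "cohort", "trg", "label")
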