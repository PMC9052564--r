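#' Configuration for a synthetic phantom cohort
#'
#' Defines the study conditions emulated by the phantom generator: a
#' dual-cohort design (training cohort "A", external validation cohort "B"
#' with a mild additive inter-site intensity shift), roughly ellipsoidal GTV
#' masks of variable elongation on an anisotropic voxel grid, HU-scale
#' interior intensities, and a class-dependent texture contrast between good
#' responders (GR, Dworak TRG 3-4) and the rest.
#'
#' Good responders get an interior random field with a longer correlation
#' length and lower amplitude (lower heterogeneity), non-responders a rougher,
#' higher-amplitude field; `texture_effect = 0` makes the classes
#' exchangeable, and larger values separate them.
#'
#' @param n_cases total number of cases across both cohorts (>= 2).
#' @param prevalence fraction of good responders in `[0, 1]`;
#'   `round(prevalence * n_cases)` cases get label 1. Default 0.49, the
#'   observed GR rate (99/201).
#' @param grid_shape 3 positive integers, voxel grid per case.
#' @param spacing_mm 3 positive reals; default `c(1, 1, 3)` mm (3 mm slices).
#' @param elongation_range pair in (0, 1]: range of the second-to-first
#'   in-plane semi-axis ratio of the ellipsoidal masks.
#' @param texture_effect non-negative real scaling the class separation of
#'   interior heterogeneity.
#' @param site_shift_hu additive HU offset applied to every cohort-B volume.
#' @param validation_fraction fraction of cases assigned to cohort B
#'   (default 75/201, the external cohort's share).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_cases = 201L,
                                    prevalence = 0.49,
                                    grid_shape = c(40L, 40L, 16L),
                                    spacing_mm = c(1, 1, 3),
                                    elongation_range = c(0.55, 0.95),
                                    texture_effect = 1.5,
                                    site_shift_hu = 10,
                                    validation_fraction = 75 / 201,
                                    seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), prevalence = prevalence,
              grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              elongation_range = as.numeric(elongation_range),
              texture_effect = texture_effect,
              site_shift_hu = site_shift_hu,
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 2L,
            cfg$prevalence >= 0, cfg$prevalence <= 1,
            length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L),
            length(cfg$spacing_mm) == 3L, all(cfg$spacing_mm > 0),
            length(cfg$elongation_range) == 2L,
            all(cfg$elongation_range > 0), all(cfg$elongation_range <= 1),
            cfg$elongation_range[1] <= cfg$elongation_range[2],
            cfg$texture_effect >= 0,
            cfg$validation_fraction >= 0, cfg$validation_fraction < 1)
  if (cfg$prevalence > 0 && round(cfg$prevalence * cfg$n_cases) < 1)
    stop("prevalence > 0 must yield at least one positive case")
  # largest ellipsoid (semi-axes up to semi_axis_range_mm[2] mm in-plane and
  # axially) must fit the grid with a 2-voxel margin
  extent_mm <- cfg$grid_shape * cfg$spacing_mm
  if (any(2 * max(semi_axis_range_mm()) + 4 * cfg$spacing_mm > extent_mm))
    stop("grid_shape too small to contain the largest ellipsoid")
  class(cfg) <- "synthetic_cohort_config"
  cfg
}

# in-plane principal semi-axis range of the phantom GTVs (mm)
semi_axis_range_mm <- function() c(9, 14)

# Separable Gaussian smoothing of a 3-D array (kernel truncated at 3 sigma),
# reusing the undecimated filtering primitive.
gaussian_smooth3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    arr <- apply_filter_axis(arr, k / sum(k), ax)
  }
  arr
}

# One ellipsoidal mask: logical array, axis-aligned, centre jittered around
# the grid centre. Semi-axes in mm: a (in-plane major), b = elong * a
# (in-plane minor, axis assignment randomised), c in [elong, 1] * a axially.
ellipsoid_mask <- function(grid_shape, spacing_mm, a_mm, elong) {
  b_mm <- elong * a_mm
  c_mm <- stats::runif(1, elong, 1) * a_mm
  semis <- c(if (stats::runif(1) < 0.5) c(a_mm, b_mm) else c(b_mm, a_mm), c_mm)
  extent <- grid_shape * spacing_mm
  centre <- extent / 2 + stats::runif(3, -1, 1) * spacing_mm
  co <- lapply(1:3, function(ax)
    ((seq_len(grid_shape[ax]) - 1) * spacing_mm[ax] - centre[ax]) / semis[ax])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  r2 <= 1
}

#' Generate a synthetic phantom cohort
#'
#' Produces `n_cases` phantom CT cases with ellipsoid-like GTV masks and
#' class-dependent interior texture. Exactly `round(prevalence * n_cases)`
#' cases carry label 1 (stratified per cohort); Dworak TRG is drawn
#' conditionally on the label (3:4 as 74:25 for responders, 0:1:2 as 2:31:69
#' otherwise) so that good response derives from TRG exactly as in the
#' clinical endpoint definition. Cohort-B volumes are offset by
#' `site_shift_hu`. Fully deterministic given `config$seed`.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list of cases; each case is a list with `patient_id`, `volume`
#'   ([ct_volume()]), `mask` ([roi_mask()]), `cohort` ("A"/"B"), `trg`, and
#'   binary `label`.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  set.seed(config$seed)
  n <- config$n_cases
  n_b <- round(config$validation_fraction * n)
  n_a <- n - n_b
  n_pos <- round(config$prevalence * n)
  n_pos_a <- min(n_a, round(config$prevalence * n_a))
  n_pos_b <- n_pos - n_pos_a
  stopifnot(n_pos_b >= 0, n_pos_b <= n_b)
  labels <- c(sample(rep(c(1L, 0L), c(n_pos_a, n_a - n_pos_a))),
              sample(rep(c(1L, 0L), c(n_pos_b, n_b - n_pos_b))))
  cohorts <- rep(c("A", "B"), c(n_a, n_b))
  lapply(seq_len(n), function(i) {
    lab <- labels[i]
    trg <- if (lab == 1L) sample(3:4, 1, prob = c(74, 25)) else
      sample(0:2, 1, prob = c(2, 31, 69))
    a_mm <- stats::runif(1, semi_axis_range_mm()[1], semi_axis_range_mm()[2])
    elong <- stats::runif(1, config$elongation_range[1],
                          config$elongation_range[2])
    vox <- ellipsoid_mask(config$grid_shape, config$spacing_mm, a_mm, elong)
    # soft-tissue-like background so masked extraction is really exercised
    arr <- 40 + stats::rnorm(prod(config$grid_shape), sd = 15)
    dim(arr) <- config$grid_shape
    # interior: Gaussian random field; good responders smoother and flatter
    te <- config$texture_effect
    sigma <- if (lab == 1L) 1 + 0.35 * te else 1.0
    amp <- if (lab == 1L) 25 / (1 + 0.25 * te) else 25 * (1 + 0.25 * te)
    field <- stats::rnorm(prod(config$grid_shape))
    dim(field) <- config$grid_shape
    field <- gaussian_smooth3d(field, rep(sigma, 3) / c(1, 1, config$spacing_mm[3] / config$spacing_mm[1]))
    field <- field / stats::sd(field)
    base <- stats::rnorm(1, 40, 5)
    arr[vox] <- base + amp * field[vox]
    if (cohorts[i] == "B") arr <- arr + config$site_shift_hu
    list(patient_id = sprintf("case_%03d", i),
         volume = ct_volume(arr, config$spacing_mm),
         mask = roi_mask(vox, config$spacing_mm),
         cohort = cohorts[i], trg = as.integer(trg), label = lab)
  })
}

#' Write a cohort to disk as NIfTI volumes, masks, and a clinical CSV
#'
#' One `<id>_volume.nii.gz` and `<id>_mask.nii.gz` per case, a
#' `clinical.csv` with columns `patient_id`, `cohort`, `trg`, and a
#' `manifest.json` listing the files (and the generating config when given).
#'
#' @param cases list of cases from [generate_cohort()] (may be empty).
#' @param directory output directory, created if needed.
#' @param config optional generating config stored in the manifest.
#' @return path of the written manifest, invisibly.
#' @export
write_cohort <- function(cases, directory, config = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    vp <- file.path(directory, paste0(cs$patient_id, "_volume.nii.gz"))
    mp <- file.path(directory, paste0(cs$patient_id, "_mask.nii.gz"))
    write_nifti(cs$volume$intensities, cs$volume$spacing_mm, vp)
    write_nifti(cs$mask$voxels + 0L, cs$mask$spacing_mm, mp)
    data.frame(patient_id = cs$patient_id, cohort = cs$cohort,
               trg = cs$trg, volume = basename(vp), mask = basename(mp),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), cohort = character(),
               trg = integer(), volume = character(), mask = character())
  utils::write.csv(tab[c("patient_id", "cohort", "trg")],
                   file.path(directory, "clinical.csv"), row.names = FALSE)
  manifest <- list(clinical = "clinical.csv",
                   cases = tab,
                   config = if (is.null(config)) NULL else unclass(config))
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}

#' Read back a cohort written by [write_cohort()]
#'
#' @param directory cohort directory containing `manifest.json`.
#' @return list of cases as produced by [generate_cohort()] (labels derived
#'   from TRG via [derive_gr_labels()]).
#' @export
read_cohort <- function(directory) {
  man <- jsonlite::read_json(file.path(directory, "manifest.json"),
                             simplifyVector = TRUE)
  tab <- as.data.frame(man$cases)
  if (nrow(tab) == 0L) return(list())
  labels <- derive_gr_labels(tab)
  lapply(seq_len(nrow(tab)), function(i) {
    cs <- read_case(file.path(directory, tab$volume[i]),
                    file.path(directory, tab$mask[i]))
    list(patient_id = tab$patient_id[i], volume = cs$volume, mask = cs$mask,
         cohort = tab$cohort[i], trg = as.integer(tab$trg[i]),
         label = unname(labels[i]))
  })
}
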