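#' CT volume container
#'
#' A 3-D intensity grid (Hounsfield units) with anisotropic voxel spacing.
#' Indices are 0-based in world-coordinate arithmetic: the centre of voxel
#' (i, j, k) (1-based R index) sits at `origin + (c(i,j,k) - 1) * spacing_mm`.
#' Axis convention is x fastest, z slowest (R column-major order).
#'
#' @param intensities 3-D numeric array of finite HU values.
#' @param spacing_mm length-3 positive numeric, (x, y, z) voxel size in mm.
#' @param origin length-3 numeric world coordinate of the first voxel centre.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing_mm, origin = c(0, 0, 0)) {
  if (!(is.array(intensities) && length(dim(intensities)) == 3L))
    stop("intensities must be a 3-D array")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Binary region-of-interest mask
#'
#' Shares the paired volume's grid. Input voxel values are binarised at
#' `> 0`, tolerant of interpolated masks.
#'
#' @param voxels 3-D array; foreground is `> 0`.
#' @param spacing_mm,origin as in [ct_volume()].
#' @return object of class `roi_mask` holding a logical array.
#' @export
roi_mask <- function(voxels, spacing_mm, origin = c(0, 0, 0)) {
  if (!(is.array(voxels) && length(dim(voxels)) == 3L))
    stop("mask voxels must be a 3-D array")
  vox <- voxels > 0
  if (!any(vox)) stop("empty ROI: mask has no foreground voxel")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  structure(list(voxels = vox, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

check_same_grid <- function(volume, mask, tol = 1e-5) {
  if (!identical(dim(volume$intensities), dim(mask$voxels)))
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dim(volume$intensities), collapse = "x"),
                 paste(dim(mask$voxels), collapse = "x")))
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > tol)
    stop("grid mismatch: volume and mask spacing differ")
  invisible(TRUE)
}

#' Write a 3-D array to NIfTI with voxel spacing
#'
#' @param arr 3-D numeric array.
#' @param spacing_mm length-3 voxel size in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, spacing_mm, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume/mask pair with grid-consistency checks
#'
#' Reads two NIfTI files, checks that they share shape and spacing, binarises
#' the mask at `> 0`, and rejects empty masks (tumours unrecognisable on the
#' planning scan are excluded, not imputed).
#'
#' @param volume_path,mask_path NIfTI file paths.
#' @return list with elements `volume` ([ct_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
read_case <- function(volume_path, mask_path) {
  vol_img <- RNifti::readNifti(volume_path)
  mask_img <- RNifti::readNifti(mask_path)
  vol <- ct_volume(array(as.numeric(vol_img), dim = dim(vol_img)),
                   spacing_mm = RNifti::pixdim(vol_img)[1:3])
  if (!any(mask_img > 0))
    stop(sprintf("empty ROI in %s", mask_path))
  mask <- roi_mask(array(as.numeric(mask_img), dim = dim(mask_img)),
                   spacing_mm = RNifti::pixdim(mask_img)[1:3])
  check_same_grid(vol, mask)
  list(volume = vol, mask = mask)
}

#' Read and validate a clinical table
#'
#' Expects a CSV with columns `patient_id`, `cohort`, `trg`. Patient ids must
#' be unique and TRG must lie on Dworak's 5-point scale (0-4).
#'
#' @param path CSV path.
#' @return data.frame with the validated columns.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical_table(tab)
}

validate_clinical_table <- function(tab) {
  need <- c("patient_id", "cohort", "trg")
  if (!all(need %in% names(tab)))
    stop("clinical table must have columns patient_id, cohort, trg")
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id")
  trg <- tab$trg
  if (any(is.na(trg)) || any(trg != as.integer(trg)) ||
      any(trg < 0 | trg > 4))
    stop("trg must be an integer on Dworak's scale 0-4")
  tab$trg <- as.integer(trg)
  tab
}

#' Good-response labels from tumor regression grades
#'
#' Pathologic good response (GR) is Dworak TRG 3 or 4; the binary study
#' endpoint. `derive_pcr_labels()` gives the stricter pathologic complete
#' response (TRG 4 only), used for reporting, not modelling.
#'
#' @param table a clinical table (data.frame with a `trg` column, validated).
#' @return integer vector of 0/1 labels, one per row, named by `patient_id`
#'   when present.
#' @export
derive_gr_labels <- function(table) {
  table <- as.data.frame(table)
  check_trg(table$trg)
  lab <- as.integer(table$trg %in% c(3L, 4L))
  if (!is.null(table$patient_id)) names(lab) <- table$patient_id
  lab
}

#' @rdname derive_gr_labels
#' @export
derive_pcr_labels <- function(table) {
  table <- as.data.frame(table)
  check_trg(table$trg)
  lab <- as.integer(table$trg == 4L)
  if (!is.null(table$patient_id)) names(lab) <- table$patient_id
  lab
}

check_trg <- function(trg) {
  if (is.null(trg)) stop("table has no trg column")
  if (any(is.na(trg)) || any(trg != as.integer(trg)) ||
      any(trg < 0 | trg > 4))
    stop("trg must be an integer on Dworak's scale 0-4")
  invisible(trg)
}
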