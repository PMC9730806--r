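#' 3D image volume with voxel geometry
#'
#' A `volume3d` bundles a 3D scalar array with its voxel spacing (mm) and the
#' 4x4 voxel-to-world affine.  Voxel indices are 0-based in all geometric
#' computations; array access from R remains 1-based as usual.  World
#' coordinates are obtained only through the affine -- no orientation
#' convention (e.g. RAS) is assumed.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `spacing` with zero origin.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `affine`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume3d: `data` contains non-finite values")
  data <- array(as.numeric(data), dim(data))  # plain double, no stray attrs
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("volume3d: `spacing` must be 3 strictly positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume3d: `affine` must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Binary lesion mask on a volume grid
#'
#' @param data 3D array with values in \{0, 1\} (logical accepted).
#' @param spacing voxel spacing in mm, as in [volume3d()].
#' @param connectivity neighbourhood rule for connected-component
#'   decomposition, 6 or 26 (default 26).
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1), connectivity = 26,
                        affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("lesion_mask: `data` must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("lesion_mask: values must be exactly binary (0/1)")
  data <- array(as.numeric(data), dim(data))  # one storage mode throughout
  if (!connectivity %in% c(6, 26))
    stop("lesion_mask: `connectivity` must be 6 or 26")
  v <- volume3d(data, spacing, affine)
  structure(list(data = v$data, spacing = v$spacing, affine = v$affine,
                 connectivity = as.integer(connectivity)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " positive, ", x$connectivity, "-connectivity\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#'
#' All millimetre volume thresholds in the pipeline (notably the minimum
#' lesion volume post-filter) use this product-of-spacings convention.
#'
#' @param x a `volume3d`, `lesion_mask`, or numeric spacing vector.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  s <- if (is.numeric(x)) x else x$spacing
  prod(s)
}

# Grid-compatibility check between two volumes/masks.  Shapes must match
# exactly; spacing within 1e-4 mm and affine entries within 1e-3 absorb
# float32 NIfTI header rounding.
check_same_grid <- function(a, b, what_a = "first", what_b = "second",
                            spacing_tol = 1e-4, affine_tol = 1e-3) {
  da <- dim(a$data); db <- dim(b$data)
  bad <- which(da != db)
  if (length(bad))
    stop(sprintf("incompatible grid: %s has shape (%s) but %s has (%s); axis %d differs",
                 what_a, paste(da, collapse = ","),
                 what_b, paste(db, collapse = ","), bad[1]))
  bad <- which(abs(a$spacing - b$spacing) > spacing_tol)
  if (length(bad))
    stop(sprintf("incompatible grid: spacing differs between %s and %s on axis %d (%g vs %g mm)",
                 what_a, what_b, bad[1], a$spacing[bad[1]], b$spacing[bad[1]]))
  if (any(abs(a$affine - b$affine) > affine_tol))
    stop(sprintf("incompatible grid: affine differs between %s and %s", what_a, what_b))
  invisible(TRUE)
}

#' Two-timepoint case: baseline and follow-up on one grid
#'
#' @param baseline,followup `volume3d` objects sharing one grid.
#' @param brain_mask optional `lesion_mask` delimiting brain tissue.
#' @param gt_new_lesions optional ground-truth `lesion_mask` of new lesions
#'   (present at follow-up only).
#' @param normalized logical; set by the preprocessing step once both
#'   timepoints are on the standard intensity scale.
#' @return An object of class `case_pair`.
#' @export
case_pair <- function(baseline, followup, brain_mask = NULL,
                      gt_new_lesions = NULL, normalized = FALSE) {
  stopifnot(inherits(baseline, "volume3d"), inherits(followup, "volume3d"))
  check_same_grid(baseline, followup, "baseline", "followup")
  if (!is.null(brain_mask)) {
    stopifnot(inherits(brain_mask, "lesion_mask"))
    check_same_grid(baseline, brain_mask, "baseline", "brain_mask")
  }
  if (!is.null(gt_new_lesions)) {
    stopifnot(inherits(gt_new_lesions, "lesion_mask"))
    check_same_grid(baseline, gt_new_lesions, "baseline", "gt_new_lesions")
  }
  structure(list(baseline = baseline, followup = followup,
                 brain_mask = brain_mask, gt_new_lesions = gt_new_lesions,
                 normalized = isTRUE(normalized)),
            class = "case_pair")
}

#' @export
print.case_pair <- function(x, ...) {
  cat("<case_pair> ", paste(dim(x$baseline$data), collapse = " x "),
      " voxels", if (!is.null(x$gt_new_lesions))
        sprintf(", %d GT lesion voxels", sum(x$gt_new_lesions$data)) else "",
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) > 3L) data <- array(data, dim(data)[1:3])
  if (!all(is.finite(data))) {
    data[!is.finite(data)] <- 0  # repair stray NaN/Inf from upstream tools
  }
  volume3d(data, spacing = RNifti::pixdim(img)[1:3],
           affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Load a two-timepoint case from NIfTI files
#'
#' Reads baseline and follow-up volumes (and optionally a brain mask and a
#' ground-truth new-lesion mask), checks that all images share one grid, and
#' binarizes mask values at > 0.5.
#'
#' @param baseline_path,followup_path paths to NIfTI (.nii/.nii.gz) volumes.
#' @param mask_path optional path to a brain mask.
#' @param gt_path optional path to a ground-truth new-lesion mask.
#' @return A [case_pair()].
#' @export
load_case <- function(baseline_path, followup_path, mask_path = NULL,
                      gt_path = NULL) {
  baseline <- read_volume_nifti(baseline_path)
  followup <- read_volume_nifti(followup_path)
  read_mask <- function(p) {
    v <- read_volume_nifti(p)
    lesion_mask(v$data > 0.5, v$spacing, affine = v$affine)
  }
  brain_mask <- if (!is.null(mask_path)) read_mask(mask_path)
  gt <- if (!is.null(gt_path)) read_mask(gt_path)
  case_pair(baseline, followup, brain_mask = brain_mask, gt_new_lesions = gt)
}

write_nifti_array <- function(data, spacing, affine, path, datatype) {
  attr(data, "pixdim") <- spacing
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a lesion mask to NIfTI
#'
#' The mask is stored as unsigned 8-bit with the reference volume's spacing
#' and affine, so that a save/load round trip is bit-identical.
#'
#' @param mask a `lesion_mask`.
#' @param reference a `volume3d` on the same grid supplying the affine.
#' @param path output path (.nii or .nii.gz).
#' @export
save_mask <- function(mask, reference, path) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(reference, "volume3d"))
  check_same_grid(mask, reference, "mask", "reference")
  write_nifti_array(array(as.integer(mask$data), dim(mask$data)),
                    reference$spacing, reference$affine, path, "uint8")
}

#' Write a scalar volume (e.g. a probability map) to NIfTI as float32
#'
#' @param vol a `volume3d` or `probability_map`.
#' @param path output path.
#' @export
save_volume <- function(vol, path) {
  write_nifti_array(vol$data, vol$spacing, vol$affine %||% diag(c(vol$spacing, 1)),
                    path, "float")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a deformation field as 4D NIfTI
#'
#' The field is stored with the three displacement components (voxel units,
#' component order matching the spatial axis order) in the last dimension.
#'
#' @param path NIfTI path.
#' @return [read_deformation_field()] returns a `deformation_field`.
#' @export
read_deformation_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("deformation field file must be 4D NIfTI with last dimension 3")
  deformation_field(array(as.numeric(data), dim(data)),
                    spacing = RNifti::pixdim(img)[1:3])
}

#' @param df a `deformation_field`.
#' @rdname read_deformation_field
#' @export
write_deformation_field <- function(df, path) {
  write_nifti_array(df$displacements, df$spacing,
                    diag(c(df$spacing, 1)), path, "float")
}
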