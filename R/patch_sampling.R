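#' Set of co-located 3D patches
#'
#' Bundles patch-origin coordinates (0-based voxel indices), the patch
#' shape, the parent grid, and per-patch channel data (baseline, follow-up,
#' optional label, optional deformation field).  Every patch lies fully
#' inside the source grid.
#'
#' @param coords integer matrix, one row per patch, 0-based origins.
#' @param patch_shape 3 integers.
#' @param source_grid shape of the parent volume.
#' @param case_id optional integer vector identifying the source case of
#'   each patch (used for case-stratified validation splits).
#' @param data optional list, one entry per patch, each a list with
#'   elements `baseline`, `followup`, and optionally `label`, `df`.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(coords, patch_shape, source_grid, case_id = NULL,
                      data = NULL) {
  coords <- matrix(as.integer(coords), ncol = 3)
  patch_shape <- as.integer(patch_shape)
  source_grid <- as.integer(source_grid)
  if (nrow(coords) > 0) {
    if (any(coords < 0) || any(t(coords) + patch_shape > source_grid))
      stop("patch_set: some patches fall outside the source grid")
  }
  structure(list(coords = coords, patch_shape = patch_shape,
                 source_grid = source_grid, case_id = case_id, data = data),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", nrow(x$coords), " patches of ",
      paste(x$patch_shape, collapse = "x"), " in a ",
      paste(x$source_grid, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' @export
length.patch_set <- function(x) nrow(x$coords)

extract_patch <- function(arr, origin, ps) {
  arr[origin[1] + seq_len(ps[1]), origin[2] + seq_len(ps[2]),
      origin[3] + seq_len(ps[3]), drop = FALSE]
}

extract_patch_df <- function(u, origin, ps) {
  u[origin[1] + seq_len(ps[1]), origin[2] + seq_len(ps[2]),
    origin[3] + seq_len(ps[3]), , drop = FALSE]
}

fill_patch_data <- function(coords, ps, case, df = NULL) {
  b <- case$baseline$data; f <- case$followup$data
  g <- if (!is.null(case$gt_new_lesions)) case$gt_new_lesions$data
  u <- if (inherits(df, "deformation_field")) df$displacements else df
  lapply(seq_len(nrow(coords)), function(i) {
    o <- coords[i, ]
    p <- list(baseline = extract_patch(b, o, ps),
              followup = extract_patch(f, o, ps))
    if (!is.null(g)) p$label <- extract_patch(g, o, ps)
    if (!is.null(u)) p$df <- extract_patch_df(u, o, ps)
    p
  })
}

#' Lesion-centred training patches
#'
#' Extracts one patch per ground-truth lesion voxel, centred on it (centre
#' voxel at `origin + patch_shape %/% 2`), with the origin clamped so the
#' patch fits inside the grid.  Duplicate origins after clamping are
#' retained: each lesion voxel contributes one training sample, implicitly
#' weighting larger lesions.
#'
#' @param case a [case_pair()] with ground truth.
#' @param patch_shape 3 integers (default 32^3).
#' @param df optional `deformation_field` to slice alongside the images.
#' @return A [patch_set()]; empty when the ground truth is empty.
#' @export
lesion_centered_patches <- function(case, patch_shape = c(32, 32, 32),
                                    df = NULL) {
  if (is.null(case$gt_new_lesions))
    stop("lesion_centered_patches: case has no ground truth")
  ps <- as.integer(patch_shape)
  grid <- dim(case$baseline$data)
  if (any(ps > grid))
    stop("configuration error: patch larger than volume grid")
  pos <- which(case$gt_new_lesions$data > 0)
  if (length(pos) == 0)
    return(patch_set(matrix(integer(0), 0, 3), ps, grid, integer(0), list()))
  centers <- arrayInd(pos, grid) - 1L  # 0-based
  origins <- sweep(centers, 2, ps %/% 2L)
  origins <- pmax(origins, 0L)
  origins <- pmin(origins, matrix(rep(grid - ps, each = nrow(origins)),
                                  ncol = 3))
  patch_set(origins, ps, grid,
            data = fill_patch_data(origins, ps, case, df))
}

grid_origins <- function(grid, ps, step) {
  lapply(1:3, function(a) {
    v <- seq.int(0L, grid[a] - ps[a], by = step[a])
    unique(c(v, grid[a] - ps[a]))  # clamped final origin covers the far face
  })
}

#' Regular-lattice (overlapped) patches
#'
#' Origins lie on the lattice `0, step, 2*step, ...` per axis, plus a final
#' clamped origin per axis so the far face of the volume is always covered.
#' When a region mask is given, only patches intersecting it are kept (used
#' for hard-example mining around lesions and stage-one mistakes).
#'
#' @param case a [case_pair()].
#' @param patch_shape 3 integers.
#' @param step positive step per axis (default 8^3, the overlapped-inference
#'   setting).
#' @param region_mask optional `lesion_mask` restricting the patches.
#' @param df optional `deformation_field` to slice alongside the images.
#' @return A [patch_set()].
#' @export
grid_patches <- function(case, patch_shape = c(32, 32, 32), step = c(8, 8, 8),
                         region_mask = NULL, df = NULL) {
  ps <- as.integer(patch_shape)
  step <- as.integer(rep(step, length.out = 3))
  if (any(step < 1)) stop("grid_patches: step components must be >= 1")
  grid <- dim(case$baseline$data)
  if (any(ps > grid))
    stop("configuration error: patch larger than volume grid")
  ax <- grid_origins(grid, ps, step)
  coords <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  dimnames(coords) <- NULL
  if (!is.null(region_mask)) {
    keep <- vapply(seq_len(nrow(coords)), function(i) {
      any(extract_patch(region_mask$data, coords[i, ], ps) > 0)
    }, logical(1))
    coords <- coords[keep, , drop = FALSE]
  }
  patch_set(coords, ps, grid, data = fill_patch_data(coords, ps, case, df))
}

#' Hard-example mining region
#'
#' Union of the ground-truth lesion voxels and every voxel where the
#' stage-one prediction disagrees with the ground truth (false positives
#' and false negatives) -- the area from which second-stage training patches
#' are drawn.
#'
#' @param gt,pred `lesion_mask` objects on one grid.
#' @return A `lesion_mask`.
#' @export
hard_example_region <- function(gt, pred) {
  check_same_grid(gt, pred, "gt", "pred")
  lesion_mask((gt$data > 0) | (pred$data != gt$data), gt$spacing,
              connectivity = gt$connectivity, affine = gt$affine)
}

#' Per-voxel probability map on a volume grid
#'
#' @param data 3D array with values in \[0, 1\].
#' @param spacing voxel spacing, mm.
#' @param affine optional voxel-to-world matrix.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  v <- volume3d(data, spacing, affine)
  if (min(v$data) < 0 || max(v$data) > 1)
    stop("probability_map: values must lie in [0, 1]")
  structure(list(data = v$data, spacing = v$spacing, affine = v$affine),
            class = "probability_map")
}

#' Reconstruct a full-volume probability map from overlapped patches
#'
#' Each voxel receives the arithmetic mean of the probabilities of all
#' patches covering it.  Every voxel of the source grid must be covered by
#' at least one patch.
#'
#' @param patches a [patch_set()].
#' @param values list of 3D probability patches, one per patch in
#'   `patches`.
#' @param spacing voxel spacing for the returned map.
#' @param affine optional affine for the returned map.
#' @return A [probability_map()].
#' @export
reconstruct_probability <- function(patches, values, spacing = c(1, 1, 1),
                                    affine = NULL) {
  grid <- patches$source_grid
  ps <- patches$patch_shape
  if (length(values) != nrow(patches$coords))
    stop("reconstruct_probability: one value patch required per coordinate")
  acc <- array(0, grid)
  cnt <- array(0L, grid)
  for (i in seq_len(nrow(patches$coords))) {
    o <- patches$coords[i, ]
    i1 <- o[1] + seq_len(ps[1]); i2 <- o[2] + seq_len(ps[2])
    i3 <- o[3] + seq_len(ps[3])
    acc[i1, i2, i3] <- acc[i1, i2, i3] + values[[i]]
    cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1L
  }
  n_uncovered <- sum(cnt == 0L)
  if (n_uncovered > 0)
    stop(sprintf("coverage error: %d voxels not covered by any patch",
                 n_uncovered))
  probability_map(pmin(pmax(acc / cnt, 0), 1), spacing, affine)
}
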