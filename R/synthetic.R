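#' Specification of a two-timepoint phantom case
#'
#' Describes the synthetic data regime used to exercise the pipeline without
#' clinical scans: a smooth ellipsoidal "brain" phantom with internal
#' structure imaged at two timepoints.  The follow-up is the baseline warped
#' by a smooth random deformation, shifted globally in intensity
#' (scanner-like nuisance), with a small number of small bright "new
#' lesions" added only at follow-up, and independent voxel noise at both
#' timepoints.
#'
#' Optional bright distractor blobs are present at *both* timepoints; they
#' mimic stable hyperintense structures that bait false positives in a
#' change-detection model.
#'
#' @param shape grid size in voxels (default 64^3, large enough for 32^3
#'   patches yet small enough for CPU work).
#' @param spacing_mm voxel spacing in mm (default 1 mm isotropic).
#' @param n_new_lesions number of new lesions at follow-up.
#' @param lesion_radius_range_mm min/max lesion semi-axis in mm; the minimum
#'   keeps every lesion above the 3 mm^3 post-filter.
#' @param lesion_contrast additive lesion brightness over local tissue.
#' @param deformation_amplitude_vox maximum displacement magnitude per
#'   component, voxel units (kept below a quarter patch so correspondence
#'   stays local).
#' @param deformation_smoothness_vox Gaussian smoothing scale (voxels) of the
#'   random deformation.
#' @param intensity_shift global additive intensity offset of the follow-up.
#' @param noise_sigma standard deviation of the additive voxel noise.
#' @param n_distractors number of bright blobs present at both timepoints.
#' @param distractor_contrast additive brightness of distractor blobs.
#' @param seed RNG seed; identical specs generate bit-identical cases.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing_mm = c(1, 1, 1),
                         n_new_lesions = 3,
                         lesion_radius_range_mm = c(1.3, 2.1),
                         lesion_contrast = 60,
                         deformation_amplitude_vox = 1.0,
                         deformation_smoothness_vox = 6,
                         intensity_shift = 5, noise_sigma = 2,
                         n_distractors = 0, distractor_contrast = 30,
                         seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0), length(spacing_mm) == 3L,
            all(spacing_mm > 0), n_new_lesions >= 0,
            length(lesion_radius_range_mm) == 2L,
            lesion_radius_range_mm[1] <= lesion_radius_range_mm[2],
            lesion_contrast > 0, deformation_amplitude_vox >= 0,
            deformation_smoothness_vox > 0, noise_sigma >= 0,
            n_distractors >= 0)
  if (any(lesion_radius_range_mm[1] / spacing_mm < 1))
    stop("phantom_spec: minimum lesion radius below one voxel on some axis")
  if (deformation_amplitude_vox >= 8)
    stop("phantom_spec: deformation amplitude must stay below a quarter of a 32-voxel patch")
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 n_new_lesions = as.integer(n_new_lesions),
                 lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
                 lesion_contrast = lesion_contrast,
                 deformation_amplitude_vox = deformation_amplitude_vox,
                 deformation_smoothness_vox = deformation_smoothness_vox,
                 intensity_shift = intensity_shift,
                 noise_sigma = noise_sigma,
                 n_distractors = as.integer(n_distractors),
                 distractor_contrast = distractor_contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Logical ellipsoid support on the grid.  center is 1-based (may be
# fractional); semi-axes in voxels.
ellipsoid_mask <- function(shape, center, semi_axes) {
  u1 <- ((seq_len(shape[1]) - center[1]) / semi_axes[1])^2
  u2 <- ((seq_len(shape[2]) - center[2]) / semi_axes[2])^2
  u3 <- ((seq_len(shape[3]) - center[3]) / semi_axes[3])^2
  outer(outer(u1, u2, `+`), u3, `+`) <= 1
}

#' Generate one synthetic two-timepoint case
#'
#' @param spec a [phantom_spec()].
#' @param max_retries bounded number of placement attempts per blob before a
#'   placement error is raised.
#' @return An object of class `synthetic_case` with fields `pair` (a
#'   [case_pair()] with ground truth and brain mask populated), `true_df`
#'   (the `deformation_field` actually applied) and `spec`.
#' @export
generate_case <- function(spec, max_retries = 200) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sh <- spec$shape
  ctr <- (sh + 1) / 2

  brain <- ellipsoid_mask(sh, ctr, 0.42 * sh)
  vent <- ellipsoid_mask(sh, ctr + c(0, 0.04, 0.02) * sh, 0.13 * sh)

  # smooth internal texture so the tissue is not flat
  texture <- .gaussian_smooth3d(array(stats::rnorm(prod(sh)), sh), sh, 4)
  texture <- texture / stats::sd(texture) * 8
  phantom <- array(0, sh)
  phantom[brain] <- 100 + texture[brain]
  phantom[vent] <- 55

  # blob placement bookkeeping: bounding boxes kept >= 2 voxels apart so
  # supports can never touch under 26-connectivity
  boxes <- list()
  allowed <- brain & !ellipsoid_mask(sh, ctr + c(0, 0.04, 0.02) * sh, 0.19 * sh) &
    ellipsoid_mask(sh, ctr, 0.34 * sh)
  allowed_idx <- which(allowed)
  margin <- ceiling(spec$deformation_amplitude_vox) + 2

  place_blob <- function(radius_range_mm) {
    for (try in seq_len(max_retries)) {
      cvox <- arrayInd(sample(allowed_idx, 1L), sh)
      r_mm <- stats::runif(1, radius_range_mm[1], radius_range_mm[2])
      semi_mm <- r_mm * stats::runif(3, 0.85, 1.15)
      semi_mm <- pmin(pmax(semi_mm, radius_range_mm[1]), radius_range_mm[2])
      semi_vox <- semi_mm / spec$spacing_mm
      lo <- floor(cvox - semi_vox) - margin
      hi <- ceiling(cvox + semi_vox) + margin
      if (any(lo < 1) || any(hi > sh)) next
      clash <- any(vapply(boxes, function(b)
        all(lo <= b$hi) && all(hi >= b$lo), logical(1)))
      if (clash) next
      supp <- ellipsoid_mask(sh, as.numeric(cvox), semi_vox)
      if (!all(allowed[supp])) next
      if (sum(supp) * voxel_volume(spec$spacing_mm) <= 3) next
      boxes[[length(boxes) + 1L]] <<- list(lo = lo, hi = hi)
      return(supp)
    }
    stop("placement error: could not place a lesion/distractor without overlap")
  }

  if (spec$n_distractors > 0) {
    for (i in seq_len(spec$n_distractors)) {
      supp <- place_blob(spec$lesion_radius_range_mm * c(1, 1.3))
      phantom[supp] <- phantom[supp] + spec$distractor_contrast
    }
  }

  # smooth random deformation: smoothed white noise rescaled to the
  # requested maximum per-component amplitude
  df <- array(0, c(sh, 3))
  if (spec$deformation_amplitude_vox > 0) {
    for (cc in 1:3) {
      w <- .gaussian_smooth3d(array(stats::rnorm(prod(sh)), sh), sh,
                              spec$deformation_smoothness_vox)
      df[, , , cc] <- w
    }
    df <- df / max(abs(df)) * spec$deformation_amplitude_vox
  }

  followup_clean <- .warp3d_forward(phantom, df, sh) + spec$intensity_shift

  gt <- array(0, sh)
  if (spec$n_new_lesions > 0) {
    for (i in seq_len(spec$n_new_lesions)) {
      supp <- place_blob(spec$lesion_radius_range_mm)
      followup_clean[supp] <- followup_clean[supp] + spec$lesion_contrast
      gt[supp] <- 1
    }
  }

  baseline <- phantom +
    if (spec$noise_sigma > 0) stats::rnorm(prod(sh), sd = spec$noise_sigma) else 0
  followup <- followup_clean +
    if (spec$noise_sigma > 0) stats::rnorm(prod(sh), sd = spec$noise_sigma) else 0

  sp <- spec$spacing_mm
  pair <- case_pair(
    baseline = volume3d(array(baseline, sh), sp),
    followup = volume3d(array(followup, sh), sp),
    brain_mask = lesion_mask(brain, sp),
    gt_new_lesions = lesion_mask(gt, sp))
  structure(list(pair = pair, true_df = deformation_field(df, sp),
                 spec = spec),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("<synthetic_case> seed ", x$spec$seed, ", ",
      x$spec$n_new_lesions, " new lesions\n", sep = "")
  invisible(x)
}

#' Generate a cohort of synthetic cases
#'
#' Per-case seeds are derived deterministically from `seed`; a configurable
#' fraction of the cases (default 25%, echoing the share of stable patients
#' in longitudinal MS cohorts) is generated with no new lesions.
#'
#' @param spec_template a [phantom_spec()] whose seed and lesion count are
#'   overridden per case.
#' @param n_cases number of cases (>= 1).
#' @param seed cohort-level RNG seed.
#' @param zero_lesion_fraction fraction of cases generated with
#'   `n_new_lesions = 0` (count rounded to nearest integer; these are the
#'   last cases of the cohort).
#' @return List of `synthetic_case`.
#' @export
generate_cohort <- function(spec_template, n_cases, seed = spec_template$seed,
                            zero_lesion_fraction = 0.25) {
  stopifnot(inherits(spec_template, "phantom_spec"), n_cases >= 1)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max %/% 2, n_cases)
  n_zero <- round(zero_lesion_fraction * n_cases)
  lapply(seq_len(n_cases), function(i) {
    sp <- spec_template
    sp$seed <- case_seeds[i]
    if (i > n_cases - n_zero) sp$n_new_lesions <- 0L
    generate_case(sp)
  })
}
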