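#' Voxel-level Dice similarity coefficient
#'
#' `2*TPs / (FNs + FPs + 2*TPs)` over voxels.  When both masks are empty
#' the score is defined as 1 and flagged with attribute `both_empty`.
#'
#' @param pred,gt `lesion_mask` objects on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(pred, gt) {
  check_same_grid(pred, gt, "pred", "gt")
  p <- pred$data > 0; g <- gt$data > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0) return(structure(1, both_empty = TRUE))
  2 * tp / (fn + fp + 2 * tp)
}

#' Lesion-wise matching of predicted against ground-truth lesions
#'
#' Lesions are 26-connected components.  A ground-truth lesion counts as
#' detected (TP) when predicted voxels cover strictly more than
#' `min_overlap_fraction` of it; a predicted component counts as a false
#' positive only when it overlaps no ground-truth lesion at all; FN is the
#' number of undetected ground-truth lesions.  The matching rule is
#' configurable and should always be reported with results.
#'
#' @param pred,gt `lesion_mask` objects on one grid.
#' @param min_overlap_fraction minimum covered fraction in \[0, 1) for a
#'   detection (default 0.1).
#' @return List with counts `tp`, `fp`, `fn`, the rule used, and the
#'   component counts `n_gt`, `n_pred`.
#' @export
match_lesions <- function(pred, gt, min_overlap_fraction = 0.1) {
  check_same_grid(pred, gt, "pred", "gt")
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction < 1)
  pm <- array(as.integer(pred$data > 0), dim(pred$data))
  gm <- array(as.integer(gt$data > 0), dim(gt$data))
  gl <- .label_components3d(gm, dim(gm), 26L)
  pl <- .label_components3d(pm, dim(pm), 26L)
  n_gt <- max(gl); n_pred <- max(pl)
  tp <- 0L
  if (n_gt > 0) {
    for (l in seq_len(n_gt)) {
      comp <- gl == l
      frac <- sum(pm[comp]) / sum(comp)
      if (frac > min_overlap_fraction) tp <- tp + 1L
    }
  }
  fp <- 0L
  if (n_pred > 0) {
    for (l in seq_len(n_pred)) {
      if (sum(gm[pl == l]) == 0) fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = n_gt - tp,
       matching_rule = min_overlap_fraction, n_gt = n_gt, n_pred = n_pred)
}

#' Lesion-wise detection scores
#'
#' `F1 = 2*TP / (FN + FP + 2*TP)`, `PPVL = TP / (TP + FP)`,
#' `SensL = TP / (TP + FN)`.  With no predictions against a nonempty ground
#' truth PPVL is 0; all-zero counts yield (0, 0, 0).
#'
#' @param counts a list with `tp`, `fp`, `fn` (e.g. from
#'   [match_lesions()]).
#' @return Named list `f1`, `ppvl`, `sensl`.
#' @export
detection_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  f1 <- if (fn + fp + 2 * tp > 0) 2 * tp / (fn + fp + 2 * tp) else 0
  ppvl <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensl <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(f1 = f1, ppvl = ppvl, sensl = sensl)
}

#' False-lesion volume for a lesion-free case
#'
#' Total volume (mm^3) of the predicted lesions in a case whose ground
#' truth contains no new lesion; the cohort-level VolTested measure is the
#' mean of this quantity over the lesion-free cases.
#'
#' @param pred predicted `lesion_mask`.
#' @param spacing voxel spacing (defaults to the mask's).
#' @param gt optional ground truth; supplying a nonempty one is an error.
#' @return Scalar volume in mm^3.
#' @export
vol_tested <- function(pred, spacing = pred$spacing, gt = NULL) {
  if (!is.null(gt) && sum(gt$data) > 0)
    stop("vol_tested applies only to cases with an empty ground truth")
  sum(pred$data > 0) * voxel_volume(spacing)
}

#' Evaluate a cohort of predictions
#'
#' Cases with at least one ground-truth lesion contribute the detection
#' (F1, PPVL, SensL) and segmentation (Dice) metrics, reported as mean and
#' standard deviation over cases; lesion-free cases contribute only the
#' VolTested measure (mean falsely predicted volume).  This mirrors the
#' two-track protocol of longitudinal new-lesion challenges.
#'
#' @param cases list, one entry per case, each a list with `pred` and `gt`
#'   (`lesion_mask`) and optionally `spacing`.
#' @param min_overlap_fraction lesion-matching rule, see [match_lesions()].
#' @return List with `per_case` (data frame with columns `dsc`, `f1`,
#'   `ppvl`, `sensl`, `voltested_mm3`, `n_gt_lesions`, `n_pred_lesions`)
#'   and `summary` (means and standard deviations; metrics are on the 0-1
#'   scale, with `percent` duplicating the means on the 0-100 scale).
#' @export
evaluate_cohort <- function(cases, min_overlap_fraction = 0.1) {
  if (length(cases) < 1) stop("evaluate_cohort: empty case list")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    spacing <- cs$spacing %||% cs$pred$spacing
    has_gt <- sum(cs$gt$data) > 0
    if (has_gt) {
      mt <- match_lesions(cs$pred, cs$gt, min_overlap_fraction)
      sc <- detection_scores(mt)
      data.frame(case = i, dsc = as.numeric(dice(cs$pred, cs$gt)),
                 f1 = sc$f1, ppvl = sc$ppvl, sensl = sc$sensl,
                 voltested_mm3 = NA_real_,
                 n_gt_lesions = mt$n_gt, n_pred_lesions = mt$n_pred)
    } else {
      pl <- .label_components3d(array(as.integer(cs$pred$data > 0),
                                      dim(cs$pred$data)),
                                dim(cs$pred$data), 26L)
      data.frame(case = i, dsc = NA_real_, f1 = NA_real_, ppvl = NA_real_,
                 sensl = NA_real_,
                 voltested_mm3 = vol_tested(cs$pred, spacing),
                 n_gt_lesions = 0L, n_pred_lesions = max(pl))
    }
  })
  per_case <- do.call(rbind, rows)
  with_gt <- per_case[per_case$n_gt_lesions > 0, , drop = FALSE]
  no_gt <- per_case[per_case$n_gt_lesions == 0, , drop = FALSE]
  msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  summary <- list(n_cases = nrow(per_case),
                  n_cases_with_lesions = nrow(with_gt),
                  matching_rule = min_overlap_fraction)
  if (nrow(with_gt) > 0) {
    for (m in c("dsc", "f1", "ppvl", "sensl")) {
      s <- msd(with_gt[[m]])
      summary[[m]] <- s[["mean"]]
      summary[[paste0(m, "_sd")]] <- s[["sd"]]
      summary$percent[[m]] <- 100 * s[["mean"]]
    }
  }
  if (nrow(no_gt) > 0)
    summary$voltested_mm3 <- mean(no_gt$voltested_mm3)
  list(per_case = per_case, summary = summary)
}
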