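#' Weights of the combined training loss
#'
#' The total loss is the sum of a supervised cross-entropy term on the
#' segmentation and an unsupervised registration term (image similarity of
#' the moved baseline against the follow-up, plus a smoothness penalty on
#' the deformation-field gradients).  The similarity term is a mean over
#' voxels while the smoothness term is a sum, so their natural scales
#' differ; explicit weights make the balance reproducible and tunable.
#'
#' @param w_segmentation,w_similarity,w_regularization non-negative weights;
#'   at least one must be strictly positive.  Defaults are the unweighted
#'   sum (1, 1, 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_segmentation = 1, w_similarity = 1,
                         w_regularization = 1) {
  w <- c(w_segmentation, w_similarity, w_regularization)
  if (any(w < 0) || all(w == 0))
    stop("loss_weights: weights must be non-negative with at least one positive")
  structure(list(w_segmentation = w_segmentation,
                 w_similarity = w_similarity,
                 w_regularization = w_regularization),
            class = "loss_weights")
}

#' Image-similarity loss between moved baseline and follow-up
#'
#' Mean over voxels of the squared intensity difference,
#' `(1/N) * sum_i (F_i - B(DF)_i)^2`.
#'
#' @param moved_baseline,followup equally shaped numeric arrays.
#' @return Scalar loss.
#' @export
similarity_loss <- function(moved_baseline, followup) {
  if (!all(dim(moved_baseline) == dim(followup)) ||
      length(moved_baseline) != length(followup))
    stop("similarity_loss: shape mismatch")
  mean((followup - moved_baseline)^2)
}

#' Smoothness (regularization) loss on a deformation field
#'
#' Sum over voxels of the squared norm of the spatial gradients of all
#' displacement components, with gradients taken by forward finite
#' differences (zero gradient at the far face of each axis).
#'
#' @param df a `deformation_field` or a 4D displacement array.
#' @return Scalar loss (0 for a constant field).
#' @export
regularization_loss <- function(df) {
  u <- if (inherits(df, "deformation_field")) df$displacements else df
  if (!all(is.finite(u))) stop("regularization_loss: non-finite displacements")
  d <- dim(u)[1:3]
  s <- 0
  if (d[1] > 1) s <- s + sum((u[2:d[1], , , , drop = FALSE] -
                              u[1:(d[1] - 1), , , , drop = FALSE])^2)
  if (d[2] > 1) s <- s + sum((u[, 2:d[2], , , drop = FALSE] -
                              u[, 1:(d[2] - 1), , , drop = FALSE])^2)
  if (d[3] > 1) s <- s + sum((u[, , 2:d[3], , drop = FALSE] -
                              u[, , 1:(d[3] - 1), , drop = FALSE])^2)
  s
}

# Gradient of regularization_loss w.r.t. the displacement array.
regularization_grad <- function(u) {
  d <- dim(u)[1:3]
  g <- array(0, dim(u))
  if (d[1] > 1) {
    dd <- u[2:d[1], , , , drop = FALSE] - u[1:(d[1] - 1), , , , drop = FALSE]
    g[2:d[1], , , ] <- g[2:d[1], , , , drop = FALSE] + 2 * dd
    g[1:(d[1] - 1), , , ] <- g[1:(d[1] - 1), , , , drop = FALSE] - 2 * dd
  }
  if (d[2] > 1) {
    dd <- u[, 2:d[2], , , drop = FALSE] - u[, 1:(d[2] - 1), , , drop = FALSE]
    g[, 2:d[2], , ] <- g[, 2:d[2], , , drop = FALSE] + 2 * dd
    g[, 1:(d[2] - 1), , ] <- g[, 1:(d[2] - 1), , , drop = FALSE] - 2 * dd
  }
  if (d[3] > 1) {
    dd <- u[, , 2:d[3], , drop = FALSE] - u[, , 1:(d[3] - 1), , drop = FALSE]
    g[, , 2:d[3], ] <- g[, , 2:d[3], , drop = FALSE] + 2 * dd
    g[, , 1:(d[3] - 1), ] <- g[, , 1:(d[3] - 1), , drop = FALSE] - 2 * dd
  }
  g
}

#' Voxelwise binary cross-entropy segmentation loss
#'
#' Mean voxelwise binary cross-entropy between predicted probabilities and
#' the binary ground truth, with probabilities clipped at `eps` to keep the
#' loss finite.
#'
#' @param prob array of probabilities in \[0, 1\].
#' @param gt binary array of the same shape.
#' @param eps clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
segmentation_loss <- function(prob, gt, eps = 1e-7) {
  if (!all(dim(prob) == dim(gt)) || length(prob) != length(gt))
    stop("segmentation_loss: shape mismatch")
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

#' Combined training loss
#'
#' `w_seg * cross-entropy + w_sim * similarity + w_reg * smoothness`, with
#' the three components returned alongside the total for logging.  `moved`
#' and `df` may be NULL (configurations without a deformation field), in
#' which case the corresponding terms are zero.
#'
#' @param prob,gt segmentation probabilities and binary ground truth.
#' @param moved_baseline,followup moved baseline and follow-up patches.
#' @param df deformation-field patch.
#' @param weights a [loss_weights()].
#' @return List with `total` and components `segmentation`, `similarity`,
#'   `regularization`.
#' @export
total_loss <- function(prob, gt, moved_baseline = NULL, followup = NULL,
                       df = NULL, weights = loss_weights()) {
  ce <- segmentation_loss(prob, gt)
  sim <- if (!is.null(moved_baseline) && !is.null(followup))
    similarity_loss(moved_baseline, followup) else 0
  reg <- if (!is.null(df)) regularization_loss(df) else 0
  list(total = weights$w_segmentation * ce + weights$w_similarity * sim +
         weights$w_regularization * reg,
       segmentation = ce, similarity = sim, regularization = reg)
}
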