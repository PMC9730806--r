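#' Training configuration for one cascade stage
#'
#' Defaults follow the training protocol of the pipeline: up to 100 epochs
#' with early stopping after 10 epochs without a decrease in validation
#' loss, and 25% of the selected patches held out for validation.  The
#' validation split is stratified by case (whole cases held out) so that
#' neighbouring patches of one lesion cannot leak between the two sets.
#' Optimization is adaptive gradient descent (Adam).
#'
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-loss decrease before stopping
#'   (must be < `max_epochs`).
#' @param validation_fraction fraction of patches held out for validation.
#' @param batch_size patches per gradient step (gradients averaged).
#' @param learning_rate Adam step size for the segmentation path.
#' @param warmup_steps linear learning-rate warmup horizon (optimization
#'   steps).  Adam's bias-corrected first steps are full-sized, and on the
#'   heavily imbalanced segmentation loss they can kill every rectifier
#'   unit in the narrow layers before any feature forms; ramping the rate
#'   over the first steps prevents that.
#' @param clip_norm gradient-norm ceiling per optimization step, applied
#'   to each subnetwork (registration U-Net, flow head, each segmentation
#'   branch, classifier) separately (default 1).  The ceiling is far above
#'   the typical gradient scale and binds only during loss spikes, which
#'   otherwise throw the classifier into a dead all-background regime it
#'   cannot leave within a short epoch budget; clipping per group keeps a
#'   spike in the registration terms from also scaling away the
#'   cross-entropy signal.
#' @param reg_lr_factor multiplier on `learning_rate` for the registration
#'   subnetwork (default 0.1).  The spatial-transformer path sits on a much
#'   less benign loss surface than the classifier -- once displacements
#'   overshoot the patch, the warp gradient vanishes and the field cannot
#'   recover -- so it gets a gentler rate.
#' @param seed RNG seed governing the split, weight init, and shuffling;
#'   the second stage trains from scratch with `seed + 1`.
#' @param loss_weights a [loss_weights()], or NULL (default) for the
#'   auto-balanced setting: unit weights on the cross-entropy and
#'   similarity terms and `1 / prod(patch_shape)` on the smoothness term,
#'   which converts the gradient-norm sum to a per-voxel mean so that all
#'   three terms share one scale.  The balance also keeps the field from
#'   inflating through the segmentation branch, which receives it as an
#'   input.
#' @param max_restarts additional deterministic initializations tried by
#'   [train_stage()] when a fit is degenerate (default 3; 0 disables
#'   restarts).
#' @param network a [network_config()].
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_epochs = 100, patience = 10,
                            validation_fraction = 0.25, batch_size = 8,
                            learning_rate = 1e-3, warmup_steps = 100,
                            clip_norm = 1, reg_lr_factor = 0.1,
                            max_restarts = 3,
                            seed = 1, loss_weights = NULL,
                            network = network_config()) {
  stopifnot(max_epochs >= 1, patience >= 1, validation_fraction > 0,
            validation_fraction < 1, batch_size >= 1, learning_rate > 0,
            reg_lr_factor > 0, is.null(clip_norm) || clip_norm > 0,
            warmup_steps >= 0, max_restarts >= 0)
  if (patience >= max_epochs)
    stop("training_config: patience must be smaller than max_epochs")
  if (is.null(loss_weights))
    loss_weights <- lesioncascade::loss_weights(
      w_segmentation = 1, w_similarity = 1,
      w_regularization = 1 / prod(network$patch_shape))
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 clip_norm = clip_norm,
                 reg_lr_factor = reg_lr_factor,
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed),
                 loss_weights = loss_weights, network = network),
            class = "training_config")
}

# Case-stratified split: whole cases go to validation until ~the requested
# fraction of patches is held out.  Falls back to a patch-level split when
# the set stems from fewer than two cases.
split_train_val <- function(patches, fraction) {
  n <- length(patches)
  cid <- patches$case_id
  if (!is.null(cid) && length(unique(cid)) >= 2) {
    ord <- sample(unique(cid))
    val_cases <- integer(0); tot <- 0
    for (cs in ord) {
      if (tot >= fraction * n || length(val_cases) >= length(ord) - 1) break
      val_cases <- c(val_cases, cs)
      tot <- tot + sum(cid == cs)
    }
    val <- which(cid %in% val_cases)
  } else {
    val <- sample.int(n, max(1L, round(fraction * n)))
  }
  if (length(val) == n) val <- val[-1]
  list(train = setdiff(seq_len(n), val), val = val)
}

# Loss terms included in training: with a learned deformation field the
# similarity and smoothness terms are trainable; with an external or absent
# field only the cross-entropy has a gradient path.
stage_loss <- function(model, fw, pd, w) {
  if (model$cfg$df_source == "learned")
    total_loss(fw$prob, pd$label, fw$moved,
               (pd$followup - model$cfg$input_center) * model$cfg$input_scale,
               fw$df, w)
  else
    total_loss(fw$prob, pd$label, weights = w)
}

patch_step <- function(model, pd, w) {
  learned <- model$cfg$df_source == "learned"
  fw <- forward_joint(model, pd$baseline, pd$followup, df_external = pd$df,
                      with_cache = TRUE, need_moved = learned)
  losses <- stage_loss(model, fw, pd, w)
  N <- length(fw$prob)
  gz <- w$w_segmentation * (fw$prob - pd$label) / N
  gmoved <- if (learned)
    w$w_similarity * 2 *
      (fw$moved - (pd$followup - model$cfg$input_center) *
         model$cfg$input_scale) / N
  gdf <- if (learned) w$w_regularization * regularization_grad(fw$df)
  list(loss = losses$total, components = losses,
       grads = backward_joint(model, fw, gz, gmoved, gdf))
}

eval_patch_loss <- function(model, pd, w) {
  learned <- model$cfg$df_source == "learned"
  fw <- forward_joint(model, pd$baseline, pd$followup, df_external = pd$df,
                      need_moved = learned)
  stage_loss(model, fw, pd, w)
}

# One full optimization run from one initialization.  Returns the best
# validation checkpoint plus the validation cross-entropy, which the
# restart logic in train_stage compares against the constant-prior
# predictor.  probe_ce0 aborts a run early (after probe_epoch epochs) when
# the validation cross-entropy is still at the level of that constant
# predictor -- such runs are stuck in the all-background regime and never
# recover within a short epoch budget.
train_stage_once <- function(patches, cfg, attempt_seed, probe_epoch = 5,
                             probe_ce0 = NULL) {
  set.seed(attempt_seed)
  split <- split_train_val(patches, cfg$validation_fraction)
  model <- build_joint_model(cfg$network)
  pd0 <- patches$data[[split$train[1]]]
  model <- calibrate_model(model, pd0$baseline, pd0$followup, pd0$df)
  mst <- zeros_like_params(model$params)
  vst <- zeros_like_params(model$params)
  w <- cfg$loss_weights
  best <- Inf; best_params <- model$params; best_epoch <- 0L
  best_ce <- Inf
  wait <- 0L; tstep <- 0L
  hist <- vector("list", cfg$max_epochs)
  aborted <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- split$train[sample.int(length(split$train))]
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    tr <- 0
    for (bt in batches) {
      gacc <- NULL; lb <- 0
      for (i in bt) {
        st <- patch_step(model, patches$data[[i]], w)
        gacc <- grad_add(gacc, st$grads)
        lb <- lb + st$loss
      }
      gacc <- grad_scale(gacc, 1 / length(bt))
      if (!is.null(cfg$clip_norm)) {
        for (nm in names(gacc)) {
          gn <- sqrt(grad_sumsq(gacc[[nm]]))
          if (gn > cfg$clip_norm)
            gacc[[nm]] <- grad_scale(gacc[[nm]], cfg$clip_norm / gn)
        }
      }
      tstep <- tstep + 1L
      warm <- if (cfg$warmup_steps > 0) min(1, tstep / cfg$warmup_steps) else 1
      for (nm in names(model$params)) {
        lr_nm <- warm * cfg$learning_rate *
          if (nm %in% c("reg", "reg_head")) cfg$reg_lr_factor else 1
        r <- adam_step(model$params[[nm]], gacc[[nm]], mst[[nm]], vst[[nm]],
                       lr_nm, tstep)
        model$params[[nm]] <- r$p; mst[[nm]] <- r$m; vst[[nm]] <- r$v
      }
      tr <- tr + lb
    }
    vals <- vapply(split$val, function(i) {
      l <- eval_patch_loss(model, patches$data[[i]], w)
      c(l$total, l$segmentation)
    }, numeric(2))
    val <- mean(vals[1, ]); val_ce <- mean(vals[2, ])
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = tr / length(idx),
                                val_loss = val, val_ce = val_ce)
    if (val < best) {
      best <- val; best_params <- model$params
      best_epoch <- epoch; best_ce <- val_ce; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
    if (!is.null(probe_ce0) && epoch == probe_epoch &&
        best_ce > 0.25 * probe_ce0) {
      aborted <- TRUE
      break
    }
  }
  model$params <- best_params
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, val_loss = best,
                 val_ce = best_ce, aborted = aborted,
                 val_indices = split$val, attempt_seed = attempt_seed),
            class = "trained_stage")
}

#' Train one cascade stage on a patch set
#'
#' Splits the patches 75/25 into training and validation (case-stratified),
#' minimizes the combined loss by Adam, stops early when the validation
#' loss has not decreased for `patience` epochs, and returns the weights of
#' the best validation epoch.
#'
#' With few channels and few epochs the imbalanced segmentation loss has a
#' degenerate basin -- a constant near-prior output -- and whether a random
#' initialization escapes it is seed luck.  Training therefore restarts
#' from a fresh deterministic init (up to `max_restarts` extra attempts)
#' whenever the fit fails a degeneracy check: its validation cross-entropy
#' must clearly beat the best constant predictor on the validation labels
#' Stuck fits are recognized early (probe after five epochs), so restarts
#' are cheap; each attempt respects the configured epoch budget.
#'
#' @param patches a [patch_set()] with labels (and deformation-field
#'   patches for `df_source = "external"`).
#' @param cfg a [training_config()]; `cfg$network$patch_shape` must match
#'   the patch set.
#' @param init_seed RNG seed for this stage (default `cfg$seed`).
#' @param max_restarts additional deterministic initializations tried when
#'   the fit is degenerate (default 3).
#' @return An object of class `trained_stage` with fields `model` (the
#'   `joint_model` at the best epoch), `history` (per-epoch train and
#'   validation losses), `best_epoch`, `val_loss`, `val_ce`, `attempts`.
#' @export
train_stage <- function(patches, cfg, init_seed = cfg$seed,
                        max_restarts = cfg$max_restarts %||% 3) {
  n <- length(patches)
  if (n < 2)
    stop("insufficient data: at least two patches are needed for a train/validation split")
  if (!all(patches$patch_shape == cfg$network$patch_shape))
    stop("configuration error: patch set shape does not match network patch_shape")
  # cross-entropy of the best constant predictor on the pooled labels:
  # the degeneracy yardstick for the restart rule
  pos <- vapply(patches$data, function(pd) sum(pd$label), numeric(1))
  tot <- vapply(patches$data, function(pd) length(pd$label), numeric(1))
  pbar <- min(max(sum(pos) / sum(tot), 1e-7), 1 - 1e-7)
  ce0 <- -(pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  fits <- list()
  for (a in seq_len(1L + max_restarts)) {
    seed_a <- (init_seed + (a - 1L) * 100003L) %% 2000000000L
    fit <- train_stage_once(patches, cfg, seed_a, probe_ce0 = ce0)
    fit$attempts <- a
    fits[[a]] <- fit
    if (fit$val_ce <= 0.25 * ce0) return(fit)
  }
  # no attempt escaped the degenerate basin; return the best one anyway
  fits[[which.min(vapply(fits, `[[`, numeric(1), "val_ce"))]]
}

as_joint_model <- function(net) {
  if (inherits(net, "trained_stage")) net$model else net
}

#' Whole-volume inference with one stage
#'
#' Extracts overlapped patches on a regular lattice, runs the network on
#' each, and reconstructs the full-volume probability map by voxelwise
#' averaging of the overlapping patch outputs.
#'
#' @param net a `trained_stage` or `joint_model`.
#' @param case a [case_pair()] (already intensity-normalized).
#' @param step lattice step per axis (default 8^3).
#' @param df optional `deformation_field` for `df_source = "external"`.
#' @return A [probability_map()].
#' @export
predict_stage <- function(net, case, step = c(8, 8, 8), df = NULL) {
  model <- as_joint_model(net)
  pset <- grid_patches(case, model$cfg$patch_shape, step, df = df)
  vals <- lapply(pset$data, function(pd)
    forward_joint(model, pd$baseline, pd$followup, df_external = pd$df,
                  need_moved = FALSE)$prob)
  reconstruct_probability(pset, vals, case$baseline$spacing,
                          case$baseline$affine)
}

#' Threshold and post-filter a probability map
#'
#' Voxels strictly above `threshold` form the candidate mask; 26-connected
#' components whose volume (voxel count times voxel volume) is below
#' `min_volume_mm3` are removed.
#'
#' @param map a [probability_map()] (or 3D array with `spacing` given).
#' @param threshold probability threshold in (0, 1); strictly greater-than.
#' @param min_volume_mm3 minimum component volume in mm^3 (default 3).
#' @param spacing voxel spacing, needed when `map` is a bare array.
#' @return A `lesion_mask`.
#' @export
binarize <- function(map, threshold = 0.5, min_volume_mm3 = 3,
                     spacing = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(map, "probability_map")) {
    data <- map$data; spacing <- map$spacing; affine <- map$affine
  } else {
    data <- as.array(map)
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    affine <- NULL
  }
  m <- array(as.integer(data > threshold), dim(data))
  if (sum(m) > 0 && min_volume_mm3 > 0) {
    lab <- .label_components3d(m, dim(m), 26L)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * voxel_volume(spacing) < min_volume_mm3)
    if (length(small)) m[array(lab %in% small, dim(m))] <- 0L
  }
  lesion_mask(m, spacing, affine = affine)
}

as_case <- function(x) {
  if (inherits(x, "synthetic_case")) x$pair else x
}

empty_mask_like <- function(case) {
  lesion_mask(array(0, dim(case$baseline$data)), case$baseline$spacing,
              affine = case$baseline$affine)
}

#' Normalize both timepoints of a case onto the standard intensity scale
#'
#' @param case a [case_pair()].
#' @param std a trained `intensity_standardizer`.
#' @return The case with standardized intensities and `normalized = TRUE`.
#' @export
normalize_case <- function(case, std) {
  case_pair(normalize_volume(case$baseline, std, case$brain_mask),
            normalize_volume(case$followup, std, case$brain_mask),
            brain_mask = case$brain_mask,
            gt_new_lesions = case$gt_new_lesions, normalized = TRUE)
}

# Pool per-case patch sets into one training set with case ids.  The
# per-case sets have already validated their coordinates against their own
# grids, which may differ between cases.
pool_patch_sets <- function(sets) {
  keep <- vapply(sets, length, integer(1)) > 0
  sets <- sets[keep]
  ids <- rep(which(keep), vapply(sets, length, integer(1)))
  structure(list(coords = do.call(rbind, lapply(sets, `[[`, "coords")),
                 patch_shape = sets[[1]]$patch_shape,
                 source_grid = sets[[1]]$source_grid,
                 case_id = as.integer(ids),
                 data = do.call(c, lapply(sets, `[[`, "data"))),
            class = "patch_set")
}

#' Train the two-stage cascade
#'
#' The full cascade training procedure: (1) the first network is trained on
#' patches centred on every ground-truth lesion voxel pooled over the
#' cohort, making it sensitive to candidate new-lesion voxels; (2) its
#' thresholded, volume-filtered predictions on the training cases define a
#' hard-example region (lesion area plus stage-one misclassifications);
#' (3) overlapped patches with step 8^3 restricted to that region train the
#' second network from scratch (fresh seed); at test time the two
#' probability maps are averaged.  Intensities are standardized over the
#' cohort before any patch extraction.
#'
#' @param cohort list of [case_pair()] or `synthetic_case` objects; at
#'   least one case must have a nonempty ground truth.
#' @param cfg a [training_config()].
#' @param mining_step lattice step of the second-stage patch extraction
#'   (default 8^3).
#' @param inference_step lattice step used for whole-volume inference both
#'   during mining and at prediction time (default 8^3).
#' @param verbose print per-stage progress.
#' @return An object of class `cascade_model`.
#' @export
fit_cascade <- function(cohort, cfg, mining_step = c(8, 8, 8),
                        inference_step = c(8, 8, 8), verbose = FALSE) {
  cases <- lapply(cohort, as_case)
  has_gt <- vapply(cases, function(cs)
    !is.null(cs$gt_new_lesions) && sum(cs$gt_new_lesions$data) > 0, logical(1))
  if (!any(has_gt))
    stop("insufficient data: no lesion voxels in the training cohort")

  vols <- c(lapply(cases, `[[`, "baseline"), lapply(cases, `[[`, "followup"))
  masks <- lapply(cases, `[[`, "brain_mask")
  masks <- if (!any(vapply(masks, is.null, logical(1)))) c(masks, masks)
  std <- fit_standardizer(vols, masks)
  cases <- lapply(cases, normalize_case, std = std)

  ps <- cfg$network$patch_shape
  sets1 <- lapply(cases, lesion_centered_patches, patch_shape = ps)
  pooled1 <- pool_patch_sets(sets1)
  if (verbose)
    message(sprintf("stage 1: %d lesion-centred patches", length(pooled1)))
  net1 <- train_stage(pooled1, cfg, init_seed = cfg$seed)

  sets2 <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    y1 <- predict_stage(net1, cs, step = inference_step)
    m1 <- binarize(y1, threshold = 0.5, min_volume_mm3 = 3)
    gt <- if (!is.null(cs$gt_new_lesions)) cs$gt_new_lesions
          else empty_mask_like(cs)
    region <- hard_example_region(gt, m1)
    if (sum(region$data) == 0)
      return(patch_set(matrix(integer(0), 0, 3), ps, dim(cs$baseline$data),
                       data = list()))
    grid_patches(cs, ps, step = mining_step, region_mask = region)
  })
  pooled2 <- pool_patch_sets(sets2)
  if (verbose)
    message(sprintf("stage 2: %d hard-example patches", length(pooled2)))
  net2 <- train_stage(pooled2, cfg, init_seed = cfg$seed + 1L)

  structure(list(fcnn1 = net1, fcnn2 = net2, config = cfg,
                 standardizer = std,
                 postprocess = list(threshold = 0.5, min_lesion_volume_mm3 = 3),
                 inference_step = inference_step),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model> two stages, df_source =", x$config$network$df_source,
      "\n  stage best epochs:", x$fcnn1$best_epoch, "and",
      x$fcnn2$best_epoch, "\n")
  invisible(x)
}

#' Predict new lesions for a case with the trained cascade
#'
#' Runs both stages over overlapped patches, averages the two probability
#' maps voxelwise, thresholds at > 0.5 and removes components below
#' 3 mm^3.  The case is intensity-normalized with the model's standardizer
#' if it has not been already.
#'
#' @param model a `cascade_model`.
#' @param case a [case_pair()] or `synthetic_case`.
#' @param step inference lattice step (defaults to the model's).
#' @param stages which stages to average: `c(1, 2)` (the cascade), `1`
#'   (stage-one only, the no-cascade reference) or `2`.
#' @param df optional `deformation_field` for `df_source = "external"`.
#' @return List with `probability` (the averaged [probability_map()]),
#'   `mask` (the post-filtered `lesion_mask`) and the per-stage maps
#'   `y1`, `y2`.
#' @export
predict_cascade <- function(model, case, step = model$inference_step,
                            stages = c(1, 2), df = NULL) {
  case <- as_case(case)
  if (!isTRUE(case$normalized))
    case <- normalize_case(case, model$standardizer)
  y1 <- if (1 %in% stages) predict_stage(model$fcnn1, case, step, df = df)
  y2 <- if (2 %in% stages) predict_stage(model$fcnn2, case, step, df = df)
  maps <- Filter(Negate(is.null), list(y1, y2))
  avg <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  final <- probability_map(pmin(pmax(avg, 0), 1), case$baseline$spacing,
                           case$baseline$affine)
  mask <- binarize(final, model$postprocess$threshold,
                   model$postprocess$min_lesion_volume_mm3)
  list(probability = final, mask = mask, y1 = y1, y2 = y2)
}
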