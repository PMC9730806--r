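test_that("binarize applies the strict threshold and the 3 mm^3 filter", {
  m <- array(0, c(12, 12, 12))
  m[2:3, 2, 2] <- 0.9          # 2 voxels = 2 mm^3 at 1 mm isotropic
  m[7:10, 7, 7] <- 0.9         # 4 voxels = 4 mm^3
  bm <- binarize(probability_map(m, c(1, 1, 1)))
  expect_equal(sum(bm$data[2:3, 2, 2]), 0)      # below 3 mm^3: removed
  expect_equal(sum(bm$data[7:10, 7, 7]), 4)     # 4 mm^3: retained
  # threshold is strictly greater-than
  m2 <- array(0.5, c(8, 8, 8))
  expect_equal(sum(binarize(probability_map(m2, c(1, 1, 1)))$data), 0)
})

test_that("binarize matches brute-force component filtering", {
  set.seed(21)
  spacings <- list(c(1, 1, 1), c(0.5, 0.5, 0.5), c(0.7, 1.1, 1.3))
  for (sp in spacings) {
    for (rep in 1:3) {
      pr <- array(runif(10^3), c(10, 10, 10))
      bm <- binarize(probability_map(pr, sp), threshold = 0.7,
                     min_volume_mm3 = 3)
      ref <- array(as.integer(pr > 0.7), c(10, 10, 10))
      lab <- bfs_label(ref, 26)
      if (max(lab) > 0) {
        for (l in seq_len(max(lab)))
          if (sum(lab == l) * prod(sp) < 3) ref[lab == l] <- 0L
      }
      expect_identical(bm$data, array(as.numeric(ref), dim(ref)))
    }
  }
})

test_that("binarize is monotone in threshold and minimum volume", {
  set.seed(22)
  pr <- probability_map(array(runif(12^3), c(12, 12, 12)), c(1, 1, 1))
  v1 <- binarize(pr, 0.6, 0)
  v2 <- binarize(pr, 0.8, 0)
  expect_true(all(v2$data <= v1$data))
  n1 <- max(bfs_label(binarize(pr, 0.6, 2)$data, 26))
  n2 <- max(bfs_label(binarize(pr, 0.6, 5)$data, 26))
  expect_lte(n2, n1)
})

test_that("training configuration enforces the patience contract", {
  expect_error(training_config(max_epochs = 5, patience = 5), "patience")
  cfg <- training_config(network = test_net_config())
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$patience, 10L)
  expect_equal(cfg$validation_fraction, 0.25)
  expect_equal(cfg$loss_weights$w_regularization, 1 / 16^3)
})

test_that("train_stage needs at least two patches", {
  cs <- generate_case(phantom_spec(shape = c(16, 16, 16), n_new_lesions = 0,
                                   seed = 1))$pair
  one <- grid_patches(cs, c(16, 16, 16), step = 16)
  cfg <- training_config(max_epochs = 2, patience = 1,
                         network = test_net_config())
  expect_error(train_stage(one, cfg), "insufficient data")
})

test_that("the checkpoint keeps the best validation epoch and stopping is bounded", {
  set.seed(30)
  sc <- generate_cohort(phantom_spec(shape = c(48, 48, 48), n_new_lesions = 2,
                                     lesion_radius_range_mm = c(1.1, 1.4),
                                     seed = 3),
                        2, seed = 7, zero_lesion_fraction = 0)
  cases <- lapply(sc, `[[`, "pair")
  pooled <- lesioncascade:::pool_patch_sets(
    lapply(cases, lesion_centered_patches, patch_shape = c(16, 16, 16)))
  cfg <- training_config(max_epochs = 4, patience = 2, batch_size = 8,
                         learning_rate = 3e-3, seed = 5,
                         network = test_net_config())
  net <- train_stage(pooled, cfg)
  h <- net$history
  expect_lte(nrow(h), 4)
  expect_equal(net$val_loss, min(h$val_loss))
  expect_lte(h$val_loss[net$best_epoch], h$val_loss[1])
  # early-stopping accounting: replay the strict-decrease rule on the
  # recorded history and check the loop stopped exactly when it said to
  best <- Inf; wait <- 0; stop_at <- nrow(h)
  for (e in seq_len(nrow(h))) {
    if (h$val_loss[e] < best) { best <- h$val_loss[e]; wait <- 0 }
    else wait <- wait + 1
    if (wait >= cfg$patience) { stop_at <- e; break }
  }
  expect_equal(nrow(h), stop_at)
})

test_that("predict_stage reconstructs a constant predictor exactly", {
  cs <- generate_case(phantom_spec(shape = c(32, 32, 32), seed = 2,
                                   n_new_lesions = 1))$pair
  m <- constant_model(0.3)
  map <- predict_stage(m, cs, step = c(8, 8, 8))
  expect_true(all(abs(map$data - 0.3) < 1e-12))
  expect_true(min(map$data) >= 0 && max(map$data) <= 1)
  # repeated calls with the same weights are identical
  map2 <- predict_stage(m, cs, step = c(8, 8, 8))
  expect_identical(map$data, map2$data)
})

test_that("stage averaging is the voxelwise mean of the two maps", {
  cs <- generate_case(phantom_spec(shape = c(32, 32, 32), seed = 5,
                                   n_new_lesions = 1))
  model <- structure(list(
    fcnn1 = constant_model(0.8), fcnn2 = constant_model(0.4),
    config = training_config(network = test_net_config(df_source = "none")),
    standardizer = fit_standardizer(list(cs$pair$baseline,
                                         cs$pair$followup)),
    postprocess = list(threshold = 0.5, min_lesion_volume_mm3 = 3),
    inference_step = c(8, 8, 8)), class = "cascade_model")
  out <- predict_cascade(model, cs)
  expect_true(all(abs(out$probability$data - 0.6) < 1e-12))
  expect_true(all(out$mask$data == 1))  # 0.6 > 0.5 everywhere
  out1 <- predict_cascade(model, cs, stages = 1)
  expect_true(all(abs(out1$probability$data - 0.8) < 1e-12))
})

test_that("fit_cascade rejects cohorts without lesions", {
  coh <- generate_cohort(phantom_spec(shape = c(16, 16, 16),
                                      n_new_lesions = 0, seed = 2),
                         2, seed = 3, zero_lesion_fraction = 0)
  cfg <- training_config(max_epochs = 2, patience = 1,
                         network = test_net_config())
  expect_error(fit_cascade(coh, cfg), "insufficient data")
})

test_that("a perfect stage-one map mines exactly the lesion region", {
  gt <- random_mask(c(20, 20, 20), 0.03, seed = 9)
  region <- hard_example_region(gt, gt)
  expect_equal(region$data, gt$data)
})
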