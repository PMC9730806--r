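test_that("network configuration validates patch divisibility and channels", {
  expect_error(network_config(patch_shape = c(24, 24, 24)), "divisible by 16")
  expect_error(network_config(base_channels = c(8, 16, 32)), "4 positive")
  expect_error(network_config(kernel_size = 4), "odd")
  cfg <- network_config(df_source = "none",
                        base_channels = c(4, 8, 16, 32),
                        patch_shape = c(16, 16, 16))
  expect_false(cfg$use_registration_branch)
})

test_that("the registration network maps an image pair to a displacement patch", {
  cfg <- test_net_config()
  net <- build_registration_net(cfg, seed = 2)
  x <- array(rnorm(16^3), c(16, 16, 16))
  y <- array(rnorm(16^3), c(16, 16, 16))
  df <- forward_registration(net, x, y)
  expect_equal(dim(df), c(16, 16, 16, 3))
  expect_true(all(is.finite(df)))
  # default configuration handles the full 32-voxel patch
  net32 <- build_registration_net(network_config(), seed = 2)
  df32 <- forward_registration(net32, array(rnorm(32^3), c(32, 32, 32)),
                               array(rnorm(32^3), c(32, 32, 32)))
  expect_equal(dim(df32), c(32, 32, 32, 3))
})

test_that("leaky activations let displacements take both signs", {
  cfg <- test_net_config()
  net <- build_registration_net(cfg, seed = 5)
  # undo the near-zero flow-head scaling to probe the feature signs
  net$params$head$W <- net$params$head$W * 1e3
  set.seed(1)
  df <- forward_registration(net, array(rnorm(16^3, 50, 20), c(16, 16, 16)),
                             array(rnorm(16^3, 50, 20), c(16, 16, 16)))
  expect_true(min(df) < 0 && max(df) > 0)
})

test_that("segmentation network honours its deformation-field configuration", {
  x <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  y <- x + rnorm(16^3)
  u <- array(rnorm(16^3 * 3), c(16, 16, 16, 3))
  seg <- build_segmentation_net(test_net_config(), seed = 3)
  p <- forward_segmentation(seg, x, y, u)
  expect_equal(dim(p), c(16, 16, 16))
  expect_true(min(p) >= 0 && max(p) <= 1)
  # df_source = "none": single branch, df input rejected
  seg0 <- build_segmentation_net(test_net_config(df_source = "none"), seed = 3)
  p0 <- forward_segmentation(seg0, x, y)
  expect_equal(dim(p0), c(16, 16, 16))
  expect_error(forward_segmentation(seg0, x, y, u), "accepts only")
  expect_error(forward_segmentation(seg, x, y), "requires")
  # external df: same output shape through the joint model
  me <- build_joint_model(test_net_config(df_source = "external"), seed = 3)
  fe <- forward_joint(me, x, y, df_external = u)
  expect_equal(dim(fe$prob), c(16, 16, 16))
})

test_that("the joint model returns probability, field, and moved baseline", {
  m <- build_joint_model(test_net_config(), seed = 4)
  x <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  y <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  fw <- forward_joint(m, x, y)
  expect_equal(dim(fw$prob), c(16, 16, 16))
  expect_equal(dim(fw$df), c(16, 16, 16, 3))
  expect_equal(dim(fw$moved), c(16, 16, 16))
  m0 <- build_joint_model(test_net_config(df_source = "none"), seed = 4)
  fw0 <- forward_joint(m0, x, y)
  expect_null(fw0$df)
  expect_null(fw0$moved)
})

test_that("builders are deterministic given a seed", {
  a <- build_joint_model(test_net_config(), seed = 11)
  b <- build_joint_model(test_net_config(), seed = 11)
  expect_identical(a$params, b$params)
  c2 <- build_joint_model(test_net_config(), seed = 12)
  expect_false(identical(a$params$seg1$enc1$c1$W, c2$params$seg1$enc1$c1$W))
})

test_that("registration and segmentation-branch U-Nets share one parameter count", {
  ch <- c(64L, 128L, 256L, 512L)
  # identical input channels give identical counts
  expect_equal(n_params(lesioncascade:::unet_init(2L, ch, 3L)),
               n_params(lesioncascade:::unet_init(2L, ch, 3L)))
  # differing input channels change only the first convolution
  d <- n_params(lesioncascade:::unet_init(3L, ch, 3L)) -
    n_params(lesioncascade:::unet_init(2L, ch, 3L))
  expect_equal(d, 27 * ch[1])
})

test_that("one optimization step decreases the loss on a smooth problem", {
  cfg <- test_net_config()
  m <- build_joint_model(cfg, seed = 6)
  set.seed(6)
  base <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  pd <- list(baseline = base, followup = base + 2,
             label = array(rbinom(16^3, 1, 0.02), c(16, 16, 16)))
  w <- loss_weights(1, 1, 0.01 / 16^3)
  st <- lesioncascade:::patch_step(m, pd, w)
  mst <- lesioncascade:::zeros_like_params(m$params)
  vst <- lesioncascade:::zeros_like_params(m$params)
  r <- lesioncascade:::adam_step(m$params, st$grads, mst, vst,
                                 lr = 1e-3, t = 1)
  m2 <- m; m2$params <- r$p
  after <- lesioncascade:::eval_patch_loss(m2, pd, w)
  expect_lt(after$total, st$loss)
})

test_that("models survive a JSON checkpoint round trip", {
  dir <- withr::local_tempdir()
  m <- build_joint_model(test_net_config(), seed = 9)
  p <- file.path(dir, "model.json")
  save_model(m, p)
  r <- load_model(p)
  x <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  y <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  expect_equal(forward_joint(r, x, y)$prob, forward_joint(m, x, y)$prob,
               tolerance = 1e-12)
})
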