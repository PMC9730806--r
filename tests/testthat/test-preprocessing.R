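test_that("a single training volume is its own fixed point", {
  v <- tiny_volume(c(20, 20, 20), seed = 3)
  std <- fit_standardizer(list(v))
  expect_true(std$trained)
  expect_true(all(diff(std$standard_scale_landmarks) > 0))
  expect_equal(std$standard_scale_landmarks[1], 0)
  expect_equal(std$standard_scale_landmarks[length(std$standard_scale_landmarks)],
               100)
  # the map sends the volume's own landmark intensities exactly onto the
  # standard scale
  nodes <- quantile(v$data[v$data > 0], std$landmark_percentiles / 100,
                    names = FALSE)
  expect_equal(piecewise_linear_map(nodes, nodes, std$standard_scale_landmarks),
               std$standard_scale_landmarks, tolerance = 1e-12)
  # and the normalized volume's landmark intensities land close to it
  # (quantile interpolation does not commute exactly across segment breaks)
  nv <- normalize_volume(v, std)
  q <- quantile(nv$data, std$landmark_percentiles / 100, names = FALSE)
  expect_equal(q, std$standard_scale_landmarks, tolerance = 0.05)
})

test_that("normalization is invariant to positive affine intensity maps", {
  v <- tiny_volume(c(18, 18, 18), seed = 4)
  v2 <- volume3d(2 * v$data, v$spacing)        # doubled
  v3 <- volume3d(3 * v$data + 40, v$spacing)   # scaled and shifted
  std <- fit_standardizer(list(v, v2))
  # both training volumes land on the same standard scale
  expect_equal(normalize_volume(v, std)$data, normalize_volume(v2, std)$data,
               tolerance = 1e-9)
  # monotone affine maps with k > 0 leave percentile ranks unchanged; use a
  # mask so the foreground voxel set is identical for both volumes
  msk <- lesion_mask(array(1, dim(v$data)), v$spacing)
  std2 <- fit_standardizer(list(v), list(msk))
  expect_equal(normalize_volume(v, std2, msk)$data,
               normalize_volume(v3, std2, msk)$data, tolerance = 1e-9)
})

test_that("a voxel at the median intensity maps to the median landmark", {
  v <- tiny_volume(c(16, 16, 16), seed = 5)
  std <- fit_standardizer(list(v))
  med <- quantile(v$data[v$data > 0], 0.5, names = FALSE)
  probe <- v
  probe$data[1, 1, 1] <- med
  out <- normalize_volume(probe, std)
  k <- which(std$landmark_percentiles == 50)
  # the probe voxel perturbs the volume's own quantiles slightly, so the
  # node identity holds to the size of that perturbation
  expect_equal(out$data[1, 1, 1], std$standard_scale_landmarks[k],
               tolerance = 1e-3)
})

test_that("normalization is monotone and near-idempotent", {
  v <- tiny_volume(c(24, 24, 24), seed = 6)
  msk <- lesion_mask(array(1, dim(v$data)), v$spacing)
  std <- fit_standardizer(list(v), list(msk))
  nv <- normalize_volume(v, std, msk)
  ord <- order(as.vector(v$data))
  expect_true(all(diff(as.vector(nv$data)[ord]) >= -1e-12))
  # renormalizing moves the landmark intensities by < 1e-6
  nv2 <- normalize_volume(nv, std, msk)
  q1 <- quantile(nv$data[msk$data > 0], std$landmark_percentiles / 100,
                 names = FALSE)
  q2 <- quantile(nv2$data[msk$data > 0], std$landmark_percentiles / 100,
                 names = FALSE)
  expect_lt(max(abs(q2 - q1)), 1e-6)
})

test_that("degenerate intensity distributions are rejected", {
  flat <- volume3d(array(7, c(10, 10, 10)), c(1, 1, 1))
  expect_error(fit_standardizer(list(flat)), "degenerate")
  v <- tiny_volume()
  std <- fit_standardizer(list(v))
  expect_error(normalize_volume(flat, std), "degenerate")
  untrained <- structure(list(trained = FALSE), class = "intensity_standardizer")
  expect_error(normalize_volume(v, untrained), "not trained")
})

test_that("standardizers survive a JSON round trip", {
  dir <- withr::local_tempdir()
  std <- fit_standardizer(list(tiny_volume(seed = 7), tiny_volume(seed = 8)))
  p <- file.path(dir, "std.json")
  save_standardizer(std, p)
  r <- load_standardizer(p)
  expect_equal(r$standard_scale_landmarks, std$standard_scale_landmarks)
  expect_equal(r$landmark_percentiles, std$landmark_percentiles)
  v <- tiny_volume(seed = 9)
  expect_equal(normalize_volume(v, r)$data, normalize_volume(v, std)$data)
})

test_that("the trivial brain mask recovers a bright ellipsoid support", {
  sh <- c(32, 32, 32)
  supp <- lesioncascade:::ellipsoid_mask(sh, c(16, 16, 16), c(10, 8, 9))
  v <- volume3d(array(as.numeric(supp) * 100, sh), c(1, 1, 1))
  m <- trivial_brain_mask(v, 0.5)
  expect_equal(m$data, array(as.numeric(supp), sh))

  # a cavity inside the object is filled
  holey <- v
  holey$data[15:17, 15:17, 15:17] <- 0
  m2 <- trivial_brain_mask(holey, 0.5)
  expect_equal(m2$data, array(as.numeric(supp), sh))

  # of two disjoint blobs only the larger survives
  two <- array(0, sh)
  two[2:12, 2:12, 2:12] <- 100
  two[20:24, 20:24, 20:24] <- 100
  m3 <- trivial_brain_mask(volume3d(two, c(1, 1, 1)), 0.5)
  expect_equal(sum(m3$data), 11^3)
  expect_true(all(m3$data[20:24, 20:24, 20:24] == 0))

  expect_error(trivial_brain_mask(volume3d(array(1, sh), c(1, 1, 1))),
               "degenerate")
})
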