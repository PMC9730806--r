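make_case <- function(shape = c(40, 40, 40), gt_voxels = NULL, seed = 1) {
  set.seed(seed)
  g <- array(0, shape)
  if (!is.null(gt_voxels)) g[gt_voxels] <- 1
  case_pair(volume3d(array(rnorm(prod(shape)), shape), c(1, 1, 1)),
            volume3d(array(rnorm(prod(shape)), shape), c(1, 1, 1)),
            gt_new_lesions = lesion_mask(g, c(1, 1, 1)))
}

test_that("one lesion-centred patch is extracted per ground-truth voxel", {
  cs <- make_case(c(64, 64, 64))
  cs$gt_new_lesions$data[c(10, 500, 70000, 90000, 130000)] <- 1
  ps <- lesion_centered_patches(cs, c(32, 32, 32))
  expect_equal(length(ps), 5)
  # centre voxel of each unclamped patch is the lesion voxel
  for (i in seq_len(5)) {
    o <- ps$coords[i, ]
    lbl <- ps$data[[i]]$label
    if (all(o > 0) && all(o < 64 - 32)) {
      expect_equal(lbl[17, 17, 17], 1)
    }
  }
  # empty ground truth gives an empty set, not an error
  empty <- lesion_centered_patches(make_case(c(40, 40, 40)), c(32, 32, 32))
  expect_equal(length(empty), 0)
})

test_that("patch origins are clamped against a brute-force bound", {
  cs <- make_case(c(40, 40, 40))
  cs$gt_new_lesions$data[1, 1, 1] <- 1       # corner voxel
  cs$gt_new_lesions$data[40, 40, 40] <- 1    # far corner
  ps <- lesion_centered_patches(cs, c(32, 32, 32))
  expect_equal(ps$coords[1, ], c(0L, 0L, 0L))
  expect_equal(ps$coords[2, ], c(8L, 8L, 8L))
  # every patch fits: brute-force bound check over random gt
  cs2 <- make_case(c(40, 36, 48), seed = 2)
  cs2$gt_new_lesions$data[sample(prod(c(40, 36, 48)), 50)] <- 1
  ps2 <- lesion_centered_patches(cs2, c(32, 32, 32))
  expect_equal(length(ps2), sum(cs2$gt_new_lesions$data))
  expect_true(all(ps2$coords >= 0))
  expect_true(all(t(ps2$coords) + c(32, 32, 32) <= c(40, 36, 48)))
})

test_that("grid patch origins match lattice enumeration", {
  cs <- make_case(c(32, 32, 32))
  expect_equal(length(grid_patches(cs, c(32, 32, 32), step = 5)), 1)
  cs2 <- make_case(c(40, 40, 40))
  gp <- grid_patches(cs2, c(32, 32, 32), step = 8)
  expect_equal(length(gp), 8)  # origins {0, 8} per axis
  expect_setequal(unique(gp$coords[, 1]), c(0L, 8L))
  # lattice plus clamped final origin on a non-multiple grid
  cs3 <- make_case(c(44, 40, 42))
  gp3 <- grid_patches(cs3, c(32, 32, 32), step = 8)
  expect_setequal(unique(gp3$coords[, 1]), c(0L, 8L, 12L))
  expect_setequal(unique(gp3$coords[, 3]), c(0L, 8L, 10L))
  expect_error(grid_patches(make_case(c(16, 16, 16)), c(32, 32, 32)),
               "configuration")
})

test_that("region-restricted grid patches match a brute-force filter", {
  cs <- make_case(c(64, 64, 64))
  region <- array(0, c(64, 64, 64))
  region[1:8, 1:8, 1:8] <- 1
  rm <- lesion_mask(region, c(1, 1, 1))
  gp <- grid_patches(cs, c(32, 32, 32), step = 8, region_mask = rm)
  all_gp <- grid_patches(cs, c(32, 32, 32), step = 8)
  keep <- vapply(seq_len(length(all_gp)), function(i) {
    o <- all_gp$coords[i, ]
    any(region[o[1] + 1:32, o[2] + 1:32, o[3] + 1:32] > 0)
  }, logical(1))
  expect_equal(gp$coords, all_gp$coords[keep, , drop = FALSE])
  # only patches touching the corner block survive
  expect_true(all(gp$coords <= 7))
})

test_that("the mining region is the union of lesions and mistakes", {
  g <- random_mask(c(16, 16, 16), 0.05, seed = 3)
  p_same <- g
  expect_equal(hard_example_region(g, p_same)$data, g$data)
  # false-positive blob disjoint from the lesions
  p_fp <- g
  p_fp$data[1:3, 1:3, 1:3] <- 1
  r <- hard_example_region(g, p_fp)
  expect_equal(r$data, pmax(g$data, p_fp$data))
  # empty prediction leaves exactly the lesion region
  p_empty <- lesion_mask(array(0, c(16, 16, 16)), c(1, 1, 1))
  expect_equal(hard_example_region(g, p_empty)$data, g$data)
  expect_error(hard_example_region(g, random_mask(c(16, 16, 17), 0.05)),
               "axis|shape|grid")
})

test_that("probability reconstruction equals the count-weighted mean", {
  cs <- make_case(c(24, 20, 16))
  ps <- grid_patches(cs, c(16, 16, 16), step = 8)
  # constant predictor
  vals <- lapply(seq_len(length(ps)), function(i) array(0.7, c(16, 16, 16)))
  rec <- reconstruct_probability(ps, vals, c(1, 1, 1))
  expect_true(all(abs(rec$data - 0.7) < 1e-12))
  # random patch values against an accumulation oracle
  set.seed(4)
  vals2 <- lapply(seq_len(length(ps)), function(i) array(runif(16^3), c(16, 16, 16)))
  rec2 <- reconstruct_probability(ps, vals2, c(1, 1, 1))
  acc <- array(0, c(24, 20, 16)); cnt <- array(0, c(24, 20, 16))
  for (i in seq_len(length(ps))) {
    o <- ps$coords[i, ]
    ix <- list(o[1] + 1:16, o[2] + 1:16, o[3] + 1:16)
    acc[ix[[1]], ix[[2]], ix[[3]]] <- acc[ix[[1]], ix[[2]], ix[[3]]] + vals2[[i]]
    cnt[ix[[1]], ix[[2]], ix[[3]]] <- cnt[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  expect_equal(rec2$data, acc / cnt)
  # an identity predictor reproduces the follow-up volume
  vals3 <- lapply(ps$data, function(pd) (pd$followup - min(cs$followup$data)) /
                    diff(range(cs$followup$data)))
  rec3 <- reconstruct_probability(ps, vals3, c(1, 1, 1))
  expect_equal(rec3$data,
               (cs$followup$data - min(cs$followup$data)) /
                 diff(range(cs$followup$data)),
               tolerance = 1e-12)
})

test_that("uncovered voxels raise a coverage error with a count", {
  cs <- make_case(c(24, 20, 16))
  ps <- grid_patches(cs, c(16, 16, 16), step = 8)
  bad <- patch_set(ps$coords[1, , drop = FALSE], c(16, 16, 16), c(24, 20, 16))
  expect_error(reconstruct_probability(bad, list(array(0.5, c(16, 16, 16)))),
               "coverage error: [0-9]+")
})

test_that("full lattice coverage holds whenever step <= patch size", {
  set.seed(5)
  for (i in 1:5) {
    grid <- sample(20:40, 3, replace = TRUE)
    patch <- c(16, 16, 16)
    step <- sample(1:16, 3, replace = TRUE)
    ax <- lesioncascade:::grid_origins(grid, patch, step)
    cov <- array(0L, grid)
    for (o1 in ax[[1]]) for (o2 in ax[[2]]) for (o3 in ax[[3]])
      cov[o1 + 1:16, o2 + 1:16, o3 + 1:16] <- 1L
    expect_true(all(cov == 1L))
  }
})
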