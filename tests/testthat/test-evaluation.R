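mk <- function(idx, shape = c(10, 10, 10), spacing = c(1, 1, 1)) {
  m <- array(0, shape); m[idx] <- 1
  lesion_mask(m, spacing)
}

test_that("dice matches the voxel-count formula", {
  a <- mk(1:10); b <- mk(1:10)
  expect_equal(dice(a, b), 1)
  expect_equal(dice(mk(1:5), mk(6:10)), 0)
  # pred 4 voxels, gt 6, 3 shared -> 2*3 / (3 + 1 + 2*3) = 0.6
  expect_equal(dice(mk(1:4), mk(c(1:3, 5:7))), 0.6)
  both <- dice(mk(integer(0)), mk(integer(0)))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_true(abs(dice(mk(1:4), mk(2:9)) - dice(mk(2:9), mk(1:4))) < 1e-15)
  expect_error(dice(mk(1), mk(1, shape = c(10, 10, 11))), "axis")
})

test_that("lesion matching follows the overlap-fraction rule", {
  g <- array(0, c(20, 10, 10)); g[1:20, 1, 1] <- 1   # one 20-voxel lesion
  gt <- lesion_mask(g, c(1, 1, 1))
  # a single predicted voxel covers 1/20 = 0.05 <= 0.1: not detected,
  # but the predicted blob touches the lesion so it is not a false positive
  pred <- mk(1, shape = c(20, 10, 10))
  mt <- match_lesions(pred, gt, min_overlap_fraction = 0.1)
  expect_equal(unlist(mt[c("tp", "fp", "fn")]), c(tp = 0, fp = 0, fn = 1))
  # with a laxer rule the same overlap counts
  mt2 <- match_lesions(pred, gt, min_overlap_fraction = 0.04)
  expect_equal(mt2$tp, 1)
  # disjoint prediction is a false positive
  far <- array(0, c(20, 10, 10)); far[5:6, 8, 8] <- 1
  mt3 <- match_lesions(lesion_mask(far, c(1, 1, 1)), gt)
  expect_equal(unlist(mt3[c("tp", "fp", "fn")]), c(tp = 0, fp = 1, fn = 1))
})

test_that("matching a mask against itself is perfect at any rule", {
  set.seed(8)
  for (fr in c(0, 0.1, 0.5, 0.9)) {
    m <- random_mask(c(14, 14, 14), 0.08, seed = 8)
    mt <- match_lesions(m, m, fr)
    expect_equal(mt$fp, 0)
    expect_equal(mt$fn, 0)
    expect_equal(mt$tp, mt$n_gt)
  }
})

test_that("raising the overlap rule never increases detections", {
  set.seed(9)
  for (i in 1:5) {
    g <- random_mask(c(16, 16, 16), 0.05, seed = 10 + i)
    p <- random_mask(c(16, 16, 16), 0.05, seed = 20 + i)
    tps <- vapply(c(0, 0.2, 0.5, 0.8), function(fr)
      match_lesions(p, g, fr)$tp, numeric(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("detection scores evaluate the printed formulas", {
  sc <- detection_scores(list(tp = 2, fp = 1, fn = 1))
  expect_equal(sc$f1, 4 / 6)
  expect_equal(sc$ppvl, 2 / 3)
  expect_equal(sc$sensl, 2 / 3)
  expect_equal(unlist(detection_scores(list(tp = 3, fp = 0, fn = 0))),
               c(f1 = 1, ppvl = 1, sensl = 1))
  expect_equal(unlist(detection_scores(list(tp = 0, fp = 0, fn = 3))),
               c(f1 = 0, ppvl = 0, sensl = 0))
})

test_that("f1 is the harmonic mean of ppvl and sensl for shared counts", {
  set.seed(10)
  for (i in 1:50) {
    counts <- list(tp = sample(0:5, 1), fp = sample(0:5, 1),
                   fn = sample(0:5, 1))
    sc <- detection_scores(counts)
    if (sc$ppvl + sc$sensl > 0)
      expect_equal(sc$f1, 2 * sc$ppvl * sc$sensl / (sc$ppvl + sc$sensl),
                   tolerance = 1e-12)
  }
})

test_that("vol_tested converts voxel counts to millimetre volumes", {
  expect_equal(vol_tested(mk(integer(0))), 0)
  expect_equal(vol_tested(mk(1:7)), 7)
  expect_equal(vol_tested(mk(1:4, spacing = c(0.5, 0.5, 0.5))), 0.5)
  expect_error(vol_tested(mk(1:2), gt = mk(1:3)), "empty ground truth")
})

test_that("cohort evaluation routes lesion and lesion-free cases separately", {
  g <- mk(c(1:4, 301:303))
  perfect <- list(pred = g, gt = g)
  missed <- list(pred = mk(integer(0)), gt = g)
  rep1 <- evaluate_cohort(list(perfect))
  expect_equal(rep1$summary$dsc, 1)
  expect_equal(rep1$summary$f1, 1)
  expect_equal(rep1$summary$percent$sensl, 100)
  rep2 <- evaluate_cohort(list(perfect, missed))
  expect_equal(rep2$summary$dsc, 0.5)
  expect_equal(rep2$summary$sensl, 0.5)
  # lesion-free cases only contribute VolTested
  fp_case <- list(pred = mk(1:7), gt = mk(integer(0)))
  clean <- list(pred = mk(integer(0)), gt = mk(integer(0)))
  rep3 <- evaluate_cohort(list(fp_case, clean))
  expect_null(rep3$summary$dsc)
  expect_equal(rep3$summary$voltested_mm3, 3.5)
  mixed <- evaluate_cohort(list(perfect, fp_case))
  expect_equal(mixed$summary$n_cases_with_lesions, 1)
  expect_equal(mixed$summary$voltested_mm3, 7)
  expect_equal(mixed$per_case$n_pred_lesions, c(2, 1))
  expect_error(evaluate_cohort(list()), "empty")
})
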