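# Centroidal Voronoi parcellation.

test_that("k = 1 yields a single parcel equal to the mask", {
  mask <- ellipsoidMask(c(5, 6, 5))
  p <- generateCvtParcellation(mask, 1, nIterations = 5, seed = 1)
  expect_true(all(p$labels == 1L))
  expect_equal(p$sizes, nrow(mask))
})

test_that("quantization energy is non-increasing across Lloyd iterations", {
  mask <- ellipsoidMask(c(8, 9, 8))
  p <- generateCvtParcellation(mask, 25, nIterations = 20, seed = 2)
  # recompute energy independently from the returned assignment
  eCheck <- sum((mask - p$centroids[p$labels, ])^2)
  expect_true(all(diff(p$energy) <= 1e-9))
  # centroids were updated after the last assignment, so the
  # recomputed energy can only be <= the last recorded one
  expect_lte(eCheck, utils::tail(p$energy, 1) + 1e-9)
})

test_that("labels partition the mask and k is conserved", {
  mask <- ellipsoidMask(c(7, 8, 7))
  k <- 40
  p <- generateCvtParcellation(mask, k, nIterations = 15, seed = 3)
  expect_equal(length(p$labels), nrow(mask))
  expect_true(all(p$labels %in% seq_len(k)))
  expect_true(all(p$sizes > 0))
  expect_equal(sum(p$sizes), nrow(mask))
})

test_that("500 parcels on a brain-sized mask are approximately equal-sized", {
  mask <- ellipsoidMask()                     # ~60,000 voxels
  expect_gt(nrow(mask), 50000)
  p <- generateCvtParcellation(mask, 500, nIterations = 50, seed = 4)
  expect_true(all(p$sizes > 0))
  cv <- stats::sd(p$sizes) / mean(p$sizes)
  expect_lt(cv, 0.25)
})

test_that("k above the voxel count errors", {
  mask <- ellipsoidMask(c(3, 3, 3))
  expect_error(generateCvtParcellation(mask, nrow(mask) + 1, seed = 1),
               "exceeds")
})
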