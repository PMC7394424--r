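test_that("phantom generation is a pure function of its seed", {
  t1 <- synthesizeVesselTree(phantomSpec(seed = 5))
  t2 <- synthesizeVesselTree(phantomSpec(seed = 5))
  expect_identical(t1, t2)
  p1 <- generatePhantomPair(phantomSpec(seed = 5))
  p2 <- generatePhantomPair(phantomSpec(seed = 5))
  expect_identical(voxels(p1@ncct), voxels(p2@ncct))
  expect_identical(voxels(p1@cta), voxels(p2@cta))
  expect_identical(voxels(p1@truth), voxels(p2@truth))
  p3 <- generatePhantomPair(phantomSpec(seed = 6))
  expect_false(identical(voxels(p3@cta), voxels(p1@cta)))
})

test_that("centrelines lie strictly inside the inner skull surface", {
  spec <- phantomSpec(seed = 9)
  tree <- synthesizeVesselTree(spec)
  h <- (spec$shape - 1) * spec$spacing / 2
  ax <- spec$skull$inner_frac * spec$skull$aspect * h
  pts <- rbind(as.matrix(tree[, c("z0", "y0", "x0")]),
               as.matrix(tree[, c("z1", "y1", "x1")]))
  en <- sqrt(colSums((t(pts) - h)^2 / ax^2))
  expect_true(all(en < 1))
})

test_that("branching depth 0 gives exactly n_roots unbranched tubes", {
  spec <- phantomSpec(seed = 2,
                      vessel = list(n_roots = 3, depth = 0,
                                    radius_range = c(1.2, 2.5),
                                    contrast_range = c(120, 500),
                                    ncct_hu = 45))
  tree <- synthesizeVesselTree(spec)
  expect_equal(length(unique(tree$branch)), 3)
})

test_that("vessel voxels enhance only in the CTA member", {
  spec <- phantomSpec(seed = 7, brain = list(mean_hu = 30, noise_sd = 0))
  p <- generatePhantomPair(spec)
  sel <- voxels(p@truth) == 1
  expect_gt(sum(sel), 0)
  expect_true(all(voxels(p@cta)[sel] > 120))
  expect_true(all(voxels(p@ncct)[sel] < 120))
  # outside the vessels the two clean scans are identical
  expect_equal(voxels(p@cta)[!sel], voxels(p@ncct)[!sel])
})

test_that("the labeling pipeline recovers a clean phantom's truth exactly", {
  spec <- phantomSpec(seed = 8, brain = list(mean_hu = 30, noise_sd = 0))
  p <- generatePhantomPair(spec)
  lab <- generateVesselLabel(p@ncct, p@cta,
                             config = labelingConfig(min_component_voxels = 1))
  expect_identical(voxels(lab), voxels(p@truth))
})

test_that("cohorts have unique ids, alternating sexes and ~45% aneurysms", {
  cohort <- makeCohort(12, tinySpec(), seed = 3)
  ids <- vapply(cohort, function(p) patientId(p@ncct), "")
  expect_equal(anyDuplicated(ids), 0L)
  sexes <- vapply(cohort, function(p) p@patientSex, "")
  expect_equal(sexes, rep(c("F", "M"), 6))
  cohort2 <- makeCohort(12, tinySpec(), seed = 3)
  expect_identical(voxels(cohort2[[5]]@cta), voxels(cohort[[5]]@cta))

  big <- makeCohort(100, tinySpec(), seed = 11)
  nvox <- vapply(big, function(p) sum(voxels(p@truth)), 1)
  expect_true(all(nvox > 0))
  # aneurysm-bearing phantoms carry extra vessel volume relative to their
  # aneurysm-free regeneration; count them via the internal flag pathway
  aneur <- ncctangio:::.withSeed(11 + 1L, runif(100) < 0.45)
  expect_gt(mean(aneur), 0.35)
  expect_lt(mean(aneur), 0.55)
})

test_that("a misaligned pair records the transform that realigns it", {
  tr <- rigidTransform(rotations = c(3, 0, 0), translations = c(2, -1, 1))
  p <- generatePhantomPair(phantomSpec(seed = 4, misalignment = tr,
                                       brain = list(mean_hu = 30,
                                                    noise_sd = 0)))
  back <- composeTransforms(tr, p@trueTransform)
  expect_lt(max(abs(c(back@rotations, back@translations))), 1e-6)
  # realigning the NCCT brings it close to the CTA outside the vessels
  re <- resampleToGrid(p@ncct, p@cta, p@trueTransform)
  sel <- voxels(p@truth) == 0 & voxels(re) > -900  # inside the head
  expect_lt(mean(abs(voxels(re)[sel] - voxels(p@cta)[sel])), 60)
})

test_that("invalid specifications are rejected", {
  expect_error(phantomSpec(shape = c(4, 64, 64)), "shape")
  expect_error(phantomSpec(vessel = list(n_roots = 1, depth = 0,
                                         radius_range = c(1, 2),
                                         contrast_range = c(80, 500),
                                         ncct_hu = 45)),
               "contrast")
})
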