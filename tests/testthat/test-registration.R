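test_that("similarity metrics obey their bounds and identities", {
  set.seed(81)
  a <- ctVolume(array(rnorm(4 * 8 * 8), c(4, 8, 8)))
  expect_equal(similarity(a, a, "ncc"), 1)
  neg <- ctVolume(-voxels(a))
  expect_equal(similarity(a, neg, "ncc"), -1)
  flat <- ctVolume(array(5, c(4, 8, 8)))
  expect_error(similarity(flat, a, "ncc"), "constant")
  expect_error(similarity(a, ctVolume(array(0, c(4, 8, 9)))), "grid")
  # NMI is maximal for identical images and bounded by 2
  expect_equal(similarity(a, a, "nmi"), 2, tolerance = 1e-10)
})

test_that("NMI of independent noise is near 1", {
  set.seed(82)
  a <- ctVolume(array(runif(32^3), c(32, 32, 32)))
  b <- ctVolume(array(runif(32^3), c(32, 32, 32)))
  expect_lt(abs(similarity(a, b, "nmi") - 1), 0.05)
})

test_that("registering a volume to itself returns the identity", {
  p <- generatePhantomPair(phantomSpec(seed = 19))
  rec <- registerRigid(p@cta, p@cta)
  expect_lt(max(abs(rec@translations)), 0.1)
  expect_lt(max(abs(rec@rotations)), 0.1)
})

test_that("a pure translation is recovered to subvoxel accuracy", {
  tr <- rigidTransform(translations = c(3.0, -2.0, 1.5))
  p <- generatePhantomPair(phantomSpec(seed = 20, misalignment = tr))
  rec <- registerRigid(p@ncct, p@cta)
  expect_lt(max(abs(rec@translations - p@trueTransform@translations)), 0.5)
})

test_that("the metric decreases away from the recovered optimum", {
  tr <- rigidTransform(translations = c(0, 3, -2))
  p <- generatePhantomPair(phantomSpec(seed = 23, misalignment = tr))
  rec <- registerRigid(p@ncct, p@cta)
  cfg <- registrationConfig()
  fx <- ncctangio:::.smoothVolume(p@cta, cfg$smooth_mm)
  mv <- ncctangio:::.smoothVolume(p@ncct, cfg$smooth_mm)
  obj <- ncctangio:::.levelObjective(mv, fx, cfg)
  atOpt <- obj(c(rec@translations, rec@rotations))
  for (ax in 1:3) {
    off <- rec@translations
    off[ax] <- off[ax] + 2
    expect_gt(obj(c(off, rec@rotations)), atOpt)   # objective is -metric
  }
})

test_that("invalid configurations are rejected", {
  expect_error(registrationConfig(levels = 0))
  expect_error(registrationConfig(bins = 4))
  expect_error(registrationConfig(metric = "ssd"))
})
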