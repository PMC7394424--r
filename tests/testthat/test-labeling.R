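test_that("thresholding is strictly greater-than", {
  vol <- ctVolume(array(c(119, 120, 120.0001, 121, 500, -1000),
                        c(1, 2, 3)))
  m <- thresholdMask(vol, 120)
  expect_equal(as.numeric(voxels(m)), c(0, 0, 1, 1, 1, 0))
  air <- ctVolume(array(-1000, c(2, 4, 4)))
  expect_equal(sum(voxels(thresholdMask(air, 120))), 0)
})

test_that("thresholding matches a voxel-by-voxel loop oracle", {
  set.seed(41)
  v <- array(runif(1000, -1000, 3000), c(10, 10, 10))
  got <- voxels(thresholdMask(ctVolume(v), 120))
  ref <- array(0, dim(v))
  for (i in seq_along(v)) if (v[i] > 120) ref[i] <- 1
  expect_identical(got, ref)
})

test_that("mask subtraction implements the set difference", {
  cta <- binaryMask(array(c(1, 1, 0, 0), c(1, 2, 2)))
  ncct <- binaryMask(array(c(0, 1, 1, 0), c(1, 2, 2)))
  expect_equal(as.numeric(voxels(subtractMasks(cta, ncct))),
               c(1, 0, 0, 0))
  empty <- binaryMask(array(0, c(1, 2, 2)))
  expect_equal(voxels(subtractMasks(cta, empty)), voxels(cta))
  wrong <- binaryMask(array(0, c(1, 2, 3)))
  expect_error(subtractMasks(cta, wrong), "grids do not match")
})

test_that("bone dilation removes face-adjacent contrast voxels", {
  cta <- binaryMask(array(0, c(3, 3, 3)))
  cta@voxels[2, 1, 1] <- 1          # face-adjacent to the bone voxel
  cta@voxels[3, 3, 3] <- 1          # two steps away: survives 1 dilation
  ncct <- binaryMask(array(0, c(3, 3, 3)))
  ncct@voxels[1, 1, 1] <- 1
  plain <- subtractMasks(cta, ncct, 0)
  expect_equal(sum(voxels(plain)), 2)
  dil <- subtractMasks(cta, ncct, 1)
  expect_equal(voxels(dil)[2, 1, 1], 0)
  expect_equal(voxels(dil)[3, 3, 3], 1)
})

test_that("small-component removal keeps boundary-size components", {
  m <- binaryMask(array(0, c(1, 5, 5)))
  m@voxels[1, 1, 1] <- 1                         # isolated single voxel
  m@voxels[1, 3, 3:5] <- 1                       # component of size 3
  out <- removeSmallComponents(m, 2, 26)
  expect_equal(voxels(out)[1, 1, 1], 0)
  expect_equal(sum(voxels(out)), 3)
  out3 <- removeSmallComponents(m, 3, 26)        # exactly min size: kept
  expect_equal(sum(voxels(out3)), 3)
  out4 <- removeSmallComponents(m, 4, 26)
  expect_equal(sum(voxels(out4)), 0)
})

test_that("component removal matches a flood-fill oracle", {
  set.seed(42)
  for (conn in c(6, 26)) {
    for (rep in 1:3) {
      v <- array(rbinom(12^3, 1, 0.25), c(12, 12, 12))
      got <- voxels(removeSmallComponents(binaryMask(v), 5, conn))
      expect_identical(got, refRemoveSmall(v, 5, conn),
                       info = sprintf("conn %d rep %d", conn, rep))
    }
  }
})

test_that("component removal is monotone and idempotent", {
  set.seed(43)
  v <- binaryMask(array(rbinom(10^3, 1, 0.3), c(10, 10, 10)))
  prev <- voxels(v)
  for (minv in c(2, 5, 10)) {
    cur <- voxels(removeSmallComponents(v, minv, 26))
    expect_true(all(cur <= prev))     # larger cutoffs never add voxels
    prev <- cur
  }
  once <- removeSmallComponents(v, 5, 6)
  twice <- removeSmallComponents(once, 5, 6)
  expect_identical(voxels(once), voxels(twice))
})

test_that("no labeled voxel exceeds the threshold on the aligned NCCT", {
  p <- generatePhantomPair(phantomSpec(seed = 13))
  lab <- generateVesselLabel(p@ncct, p@cta)
  expect_equal(sum(voxels(lab) * (voxels(p@ncct) > 120)), 0)
})

test_that("degenerate labels raise the unusable-exam error", {
  p <- generatePhantomPair(tinySpec(seed = 2))
  everything <- binaryMask(array(1, dim(p@cta)), spacing = spacing(p@cta))
  expect_error(
    generateVesselLabel(p@ncct, p@cta,
                        config = labelingConfig(exclusion_mask = everything)),
    "unusable")
  air <- ctVolume(array(-1000, c(8, 16, 16)), spacing = c(2, 1, 1))
  expect_error(generateVesselLabel(air, air), "unusable")
})
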