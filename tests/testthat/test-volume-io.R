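test_that("NIfTI write/read round-trips voxels and geometry", {
  set.seed(11)
  vol <- ctVolume(array(rnorm(4 * 8 * 8, 30, 200), c(4, 8, 8)),
                  spacing = c(5, 1, 1), origin = c(1, -2, 3),
                  patientId = "rt")
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  v2 <- readVolume(f, patientId = "rt")
  expect_lt(max(abs(voxels(v2) - voxels(vol))), 1e-3)
  expect_equal(spacing(v2), spacing(vol))
  expect_equal(origin(v2), origin(vol))

  one <- ctVolume(array(0, c(1, 1, 1)))
  f1 <- tempfile(fileext = ".nii.gz")
  writeVolume(one, f1)
  expect_equal(voxels(readVolume(f1)), array(0, c(1, 1, 1)))

  expect_error(readVolume(tempfile()), "no such file")
})

test_that("spacing written by an independent NIfTI writer is preserved", {
  arr <- array(seq_len(4 * 6 * 6), c(6, 6, 4))   # oro order: x, y, z
  nim <- oro.nifti::nifti(arr, datatype = 16)
  oro.nifti::pixdim(nim)[2:4] <- c(1, 1, 5)
  f <- tempfile()
  oro.nifti::writeNIfTI(nim, f)
  vol <- readVolume(paste0(f, ".nii.gz"))
  expect_equal(spacing(vol), c(5, 1, 1))
  expect_equal(dim(vol), c(4, 6, 6))
})

test_that("masks round-trip exactly with their grid metadata", {
  set.seed(3)
  m <- randomMask(c(8, 8, 8))
  m@spacing <- c(2, 1, 1); m@origin <- c(0, 5, -5)
  f <- tempfile(fileext = ".nii.gz")
  writeMask(m, f)
  m2 <- readMask(f)
  expect_identical(voxels(m2), voxels(m))
  expect_equal(spacing(m2), spacing(m))
  expect_equal(origin(m2), origin(m))

  empty <- binaryMask(array(0, c(2, 4, 4)))
  fe <- tempfile(fileext = ".nii.gz")
  writeMask(empty, fe)
  expect_identical(voxels(readMask(fe)), voxels(empty))
})

test_that("resampling with the identity transform is the identity map", {
  set.seed(4)
  vol <- ctVolume(array(rnorm(4 * 8 * 8), c(4, 8, 8)), spacing = c(5, 1, 1))
  out <- resampleToGrid(vol, vol)
  expect_equal(voxels(out), voxels(vol))
})

test_that("nearest-neighbour resampling preserves the binary value set", {
  set.seed(5)
  m <- randomMask(c(6, 10, 10))
  out <- resampleToGrid(m, m, rigidTransform(rotations = c(7, 0, 0),
                                             translations = c(1, 0.3, -0.7)))
  expect_true(all(voxels(out) %in% c(0, 1)))
  expect_s4_class(out, "BinaryMask")
})

test_that("a one-voxel translation shifts a volume by one voxel", {
  gv <- array(0, c(4, 8, 8))
  for (i in 1:4) gv[i, , ] <- outer(1:8, 1:8, "+") * 10 + i
  vol <- ctVolume(gv)
  sh <- resampleToGrid(vol, vol, rigidTransform(translations = c(0, 0, 1)))
  expect_equal(voxels(sh)[, , 1:7], voxels(vol)[, , 2:8])
  # out-of-field column filled with air
  expect_true(all(voxels(sh)[, , 8] == -1024))
})

test_that("unknown interpolation modes are rejected", {
  vol <- ctVolume(array(0, c(2, 4, 4)))
  expect_error(resampleToGrid(vol, vol, interpolation = "spline"),
               "unknown interpolation")
})
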