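test_that("a synthetic series round-trips through DICOM", {
  set.seed(21)
  vol <- ctVolume(array(sample(-1000:2500, 4 * 6 * 6, TRUE), c(4, 6, 6)),
                  spacing = c(5, 0.5, 0.5), origin = c(10, -5, -4),
                  patientId = "RT1")
  d <- tempfile()
  writeDicomSeries(vol, d)
  v2 <- readDicomSeries(d)
  expect_lt(max(abs(voxels(v2) - voxels(vol))), 1e-6)
  expect_equal(spacing(v2), spacing(vol))
  expect_equal(origin(v2), origin(vol))
  expect_equal(patientId(v2), "RT1")
})

test_that("stored values convert to HU via rescale slope and intercept", {
  # stored value 100 with slope 1 / intercept -1024 must read as -924 HU
  vol <- ctVolume(array(-924, c(1, 4, 4)))
  d <- tempfile()
  writeDicomSeries(vol, d)   # writes stored = HU + 1024 = 100
  expect_true(all(voxels(readDicomSeries(d)) == -924))
})

test_that("slice order on disk does not matter", {
  set.seed(22)
  vol <- ctVolume(array(sample(0:500, 5 * 4 * 4, TRUE), c(5, 4, 4)),
                  spacing = c(2, 1, 1))
  d1 <- tempfile()
  writeDicomSeries(vol, d1)
  d2 <- tempfile()
  dir.create(d2)
  files <- list.files(d1, full.names = TRUE)
  scrambled <- sample(sprintf("%s/z_%s.dcm", d2, letters[seq_along(files)]))
  file.copy(files, scrambled)
  expect_equal(voxels(readDicomSeries(d2)), voxels(vol))
})

test_that("mixed series identifiers are rejected with a clear error", {
  vol <- ctVolume(array(0, c(2, 4, 4)))
  d <- tempfile()
  writeDicomSeries(vol, d, seriesUID = "1.2.3.4")
  other <- ctVolume(array(0, c(1, 4, 4)), origin = c(10, 0, 0))
  d2 <- tempfile()
  writeDicomSeries(other, d2, seriesUID = "1.2.3.5")
  file.copy(list.files(d2, full.names = TRUE),
            file.path(d, "other_series.dcm"))
  expect_error(readDicomSeries(d), "mixed DICOM series")
})

test_that("non-uniform slice gaps beyond tolerance are rejected", {
  vol <- ctVolume(array(0, c(3, 4, 4)), spacing = c(2, 1, 1))
  d <- tempfile()
  writeDicomSeries(vol, d)
  stray <- ctVolume(array(0, c(1, 4, 4)), spacing = c(2, 1, 1),
                    origin = c(2.7, 0, 0))
  d2 <- tempfile()
  writeDicomSeries(stray, d2)
  file.copy(list.files(d2, full.names = TRUE), file.path(d, "stray.dcm"))
  expect_error(readDicomSeries(d), "non-uniform slice spacing")
})

test_that("empty directories are rejected", {
  d <- tempfile()
  dir.create(d)
  expect_error(readDicomSeries(d), "no files")
})
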