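test_that("composing a transform with its inverse yields the identity", {
  set.seed(31)
  for (i in 1:20) {
    a <- rigidTransform(rotations = runif(3, -15, 15),
                        translations = runif(3, -20, 20))
    id <- composeTransforms(a, invertTransform(a))
    expect_lt(max(abs(c(id@rotations, id@translations))), 1e-6)
    R <- ncctangio:::.rotationMatrixZYX(a@rotations)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
  }
})

test_that("composition matches matrix-product order", {
  a <- rigidTransform(rotations = c(10, 0, 0), translations = c(1, 2, 3))
  b <- rigidTransform(rotations = c(0, 5, 0), translations = c(-2, 0, 1))
  ctr <- c(5, 5, 5)
  fa <- ncctangio:::.affineFor(a, ctr)
  fb <- ncctangio:::.affineFor(b, ctr)
  fc <- ncctangio:::.affineFor(composeTransforms(a, b), ctr)
  p <- c(1.5, -4, 7)
  expect_equal(as.numeric(fc$M %*% p + fc$b),
               as.numeric(fa$M %*% (fb$M %*% p + fb$b) + fa$b),
               tolerance = 1e-10)
})

test_that("transforms serialize to plain text and back", {
  a <- rigidTransform(rotations = c(1.25, -3.5, 0.125),
                      translations = c(-7.75, 0.5, 2))
  f <- tempfile(fileext = ".json")
  writeTransform(a, f)
  b <- readTransform(f)
  expect_equal(b@rotations, a@rotations)
  expect_equal(b@translations, a@translations)
})
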