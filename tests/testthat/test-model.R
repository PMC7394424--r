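test_that("the network maps inputs to same-size two-class probability maps", {
  m <- buildModel(microModelConfig(seed = 2))
  for (size in c(16, 64)) {
    x <- array(runif(size * size * 3 * 2), c(size, size, 3, 2))
    p <- ncctangio:::.netForward(m, x)
    expect_equal(dim(p), c(size, size, 2, 2))
    expect_lt(max(abs(apply(p, c(1, 2, 4), sum) - 1)), 1e-5)
  }
  bad <- array(0, c(20, 20, 3, 1))
  expect_error(ncctangio:::.netForward(m, bad), "divisible")
})

test_that("weight initialization is deterministic given the seed", {
  m1 <- buildModel(microModelConfig(seed = 5))
  m2 <- buildModel(microModelConfig(seed = 5))
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(microModelConfig(seed = 6))
  expect_false(identical(m1@params, m3@params))
})

test_that("the gated attention block starts as the identity map", {
  set.seed(61)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  pa <- ncctangio:::.netForward(
    buildModel(microModelConfig(seed = 3, self_attention = TRUE)), x)
  pb <- ncctangio:::.netForward(
    buildModel(microModelConfig(seed = 3, self_attention = FALSE)), x)
  expect_lt(max(abs(pa - pb)), 1e-5)
})

test_that("pixel-shuffle layers satisfy the ICNR property at init only", {
  m <- buildModel(microModelConfig(seed = 4))
  expect_true(icnrCheck(m))
  # a gradient step on the up-convolutions breaks the sub-kernel ties
  set.seed(62)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  tg <- array(0, c(16, 16, 2, 2))
  v <- array(runif(16 * 16 * 2) > 0.8, c(16, 16, 2))
  tg[, , 2, ] <- v; tg[, , 1, ] <- 1 - v
  m@params$head.w[] <- rnorm(length(m@params$head.w), 0, 0.3)
  res <- ncctangio:::.netTrainStep(m, x, tg)
  for (wn in m@config$icnr)
    m@params[[wn]] <- m@params[[wn]] - 0.05 * res$grads[[wn]]
  expect_false(icnrCheck(m))

  tm <- buildModel(microModelConfig(seed = 4, upsampling = "transposed"))
  expect_error(icnrCheck(tm), "pixel_shuffle_icnr")
})

test_that("generalized Dice loss matches its formula and bounds", {
  t1 <- array(0, c(2, 2, 2)); t1[, , 1] <- c(1, 0, 0, 1)
  t1[, , 2] <- 1 - t1[, , 1]
  expect_equal(generalizedDiceLoss(t1, t1), 0)
  expect_equal(generalizedDiceLoss(1 - t1, t1), 1)

  pr <- array(0, c(2, 2, 2))
  pr[, , 2] <- c(0.9, 0.2, 0.8, 0.3); pr[, , 1] <- 1 - pr[, , 2]
  tg <- array(0, c(2, 2, 2))
  tg[, , 2] <- c(1, 0, 1, 0); tg[, , 1] <- 1 - tg[, , 2]
  r <- c(2, 2); p <- c(2.3, 1.7); i <- c(1.5, 1.7)
  hand <- 1 - 2 * sum((1 / r^2) * i) / sum((1 / r^2) * (r + p))
  expect_equal(generalizedDiceLoss(pr, tg), hand)

  # correcting a wrong pixel always decreases the loss
  worse <- pr; worse[1, 2, 2] <- 0.2; worse[1, 2, 1] <- 0.8  # pixel 3 is fg
  expect_gt(generalizedDiceLoss(worse, tg), generalizedDiceLoss(pr, tg))
  expect_error(generalizedDiceLoss(pr, tg[, 1, , drop = FALSE]),
               "shapes")
})

test_that("the compiled training loss agrees with the reference formula", {
  m <- buildModel(microModelConfig(seed = 9))
  set.seed(63)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  tg <- array(0, c(16, 16, 2, 2))
  v <- array(runif(16 * 16 * 2) > 0.85, c(16, 16, 2))
  tg[, , 2, ] <- v; tg[, , 1, ] <- 1 - v
  res <- ncctangio:::.netTrainStep(m, x, tg)
  probs <- ncctangio:::.netForward(m, x, train = TRUE)
  # pool the batch exactly as training does: classes in the last dimension
  pp <- aperm(probs, c(1, 2, 4, 3)); tt <- aperm(tg, c(1, 2, 4, 3))
  expect_equal(res$loss, generalizedDiceLoss(pp, tt), tolerance = 1e-4)
})

test_that("augmentation applies one geometry to both image and mask", {
  set.seed(64)
  img <- array(0, c(32, 32, 3))
  msk <- matrix(0, 32, 32)
  img[10:22, 10:22, ] <- 1
  msk[10:22, 10:22] <- 1

  none <- augmentationConfig(0, 0, 0, c(1, 1), 0)
  out <- augmentPair(img, msk, none)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)

  flip <- augmentationConfig(1, 0, 0, c(1, 1), 0)
  f1 <- augmentPair(img, msk, flip)
  f2 <- augmentPair(f1$image, f1$mask, flip)
  expect_equal(f2$image, img, tolerance = 1e-12)   # flipping is an involution
  expect_equal(f2$mask, msk)

  heavy <- augmentationConfig(0.5, 10, 1, c(1.0, 1.2), 1)
  for (i in 1:5) {
    a <- augmentPair(img, msk, heavy)
    expect_true(all(a$mask %in% c(0, 1)))
    inside <- a$mask == 1
    expect_gte(mean(a$image[, , 1][inside] > 0.5), 0.9)
  }
})

test_that("whole-volume prediction is deterministic and grid-preserving", {
  p <- generatePhantomPair(tinySpec(seed = 3))
  m <- buildModel(microModelConfig(seed = 7))
  ch <- preprocPreset("simple-multi")
  pred1 <- predictVolume(m, p@ncct, ch)
  pred2 <- predictVolume(m, p@ncct, ch)
  expect_identical(voxels(pred1), voxels(pred2))
  expect_equal(dim(pred1), dim(p@ncct))
  expect_equal(spacing(pred1), spacing(p@ncct))
  m1 <- buildModel(modelConfig(base_width = 4, in_channels = 1))
  expect_error(predictVolume(m1, p@ncct, ch), "channel mismatch")
})
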