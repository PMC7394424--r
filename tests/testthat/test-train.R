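test_that("the 1cycle schedule has the stated endpoints and peak", {
  cfg <- trainConfig()
  total <- 100
  expect_equal(oneCycleLR(0, total, cfg), cfg$lr_max / 25)
  expect_equal(oneCycleLR(round(0.3 * total), total, cfg), cfg$lr_max)
  expect_equal(oneCycleLR(total - 1, total, cfg),
               cfg$lr_max / (25 * 1e4))
  lr <- oneCycleLR(0:(total - 1), total, cfg)
  peak <- which.max(lr)
  expect_true(all(diff(lr[1:peak]) >= 0))
  expect_true(all(diff(lr[peak:total]) <= 0))
  expect_error(oneCycleLR(-1, total, cfg), "out of range")
  expect_error(oneCycleLR(total, total, cfg), "out of range")
})

test_that("whole-exam Dice follows 2TP/(2TP+FP+FN)", {
  a <- binaryMask(array(c(1, 1, 1, 0), c(1, 2, 2)))
  b <- binaryMask(array(c(1, 1, 0, 1), c(1, 2, 2)))
  r <- diceCoefficient(a, b)
  expect_equal(c(r$TP, r$FP, r$FN), c(2, 1, 1))
  expect_equal(r$dice, 2 / 3)

  same <- diceCoefficient(b, b)
  expect_equal(same$dice, 1)
  disj <- diceCoefficient(binaryMask(array(c(1, 0, 0, 0), c(1, 2, 2))),
                          binaryMask(array(c(0, 1, 0, 0), c(1, 2, 2))))
  expect_equal(disj$dice, 0)
  empty <- binaryMask(array(0, c(1, 2, 2)))
  expect_error(diceCoefficient(a, empty), "empty truth")
})

test_that("exam Dice aggregates counts rather than averaging slices", {
  # slice 1: perfect on 10 voxels; slice 2: 1 of 10 found
  truth <- array(0, c(2, 5, 4)); pred <- array(0, c(2, 5, 4))
  truth[1, , 1:2] <- 1; pred[1, , 1:2] <- 1
  truth[2, , 3:4] <- 1; pred[2, 1, 3] <- 1
  r <- diceCoefficient(binaryMask(pred), binaryMask(truth))
  aggregated <- 2 * 11 / (2 * 11 + 0 + 9)
  sliceMean <- mean(c(1, 2 * 1 / (2 * 1 + 0 + 9)))
  expect_equal(r$dice, aggregated)
  expect_false(isTRUE(all.equal(aggregated, sliceMean)))
})

test_that("training reduces the loss and is reproducible", {
  cohort <- makeCohort(2, tinySpec(), seed = 5)
  m <- buildModel(microModelConfig(seed = 2))
  fit1 <- trainModel(m, cohort, preprocPreset("simple-multi"),
                     microTrainConfig(epochs = 6, seed = 3), noAugment())
  expect_length(fit1$history, 6)
  expect_lt(fit1$history[6], fit1$history[1])
  fit2 <- trainModel(m, cohort, preprocPreset("simple-multi"),
                     microTrainConfig(epochs = 6, seed = 3), noAugment())
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model@params, fit2$model@params)

  expect_error(
    trainModel(m, cohort[1], preprocPreset("simple-multi"),
               trainConfig(batch_size = 999)),
    "larger than dataset")
})

test_that("augmented training also converges", {
  cohort <- makeCohort(2, tinySpec(), seed = 8)
  m <- buildModel(microModelConfig(seed = 4))
  fit <- trainModel(m, cohort, preprocPreset("simple-multi"),
                    microTrainConfig(epochs = 6, seed = 4),
                    augmentationConfig())
  expect_lt(fit$history[6], fit$history[1])
  expect_equal(fit$model@channels$config$mode, "simple")
})
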