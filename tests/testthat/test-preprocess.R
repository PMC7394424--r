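test_that("window scaling is the clipped linear map", {
  w <- windowSpec(-100, 300)
  expect_equal(windowScale(array(c(-100, 300, 100), c(1, 1, 3)), w),
               array(c(0, 1, 0.5), c(1, 1, 3)))
  expect_equal(windowScale(array(c(-500, 400), c(1, 1, 2)), w),
               array(c(0, 1), c(1, 1, 2)))
  expect_equal(windowScale(array(2500, c(1, 1, 1)), windowSpec(300, 2000)),
               array(1, c(1, 1, 1)))
  # exactly linear between the bounds
  v <- seq(-100, 300, by = 25)
  expect_equal(as.numeric(windowScale(array(v, c(1, 1, length(v))), w)),
               (v + 100) / 400)
  expect_error(windowSpec(300, 300))
})

test_that("channel construction replicates or windows per channel", {
  vol <- ctVolume(array(200, c(1, 2, 2)))
  single <- makeChannels(vol, preprocPreset("simple-single"))
  expect_equal(dim(single), c(1, 2, 2, 3))
  expect_true(all(single == 0.75))   # (200 + 100) / 400 on every channel
  multi <- makeChannels(vol, preprocPreset("simple-multi"))
  expect_equal(as.numeric(multi[1, 1, 1, ]), c(1.0, 0.75, 0.0))
  expect_error(channelConfig("simple",
                             windows = list(windowSpec(0, 1),
                                            windowSpec(1, 2))),
               "1 or 3")
  expect_error(makeChannels(vol, preprocPreset("uniform-full")),
               "requires a fitted")
})

test_that("percentile knots follow the empirical distribution", {
  set.seed(51)
  vals <- runif(20000, -500, 1000)
  volWide <- ctVolume(array(vals, c(20, 100, 10)))
  vals <- runif(20000, 0, 1000)
  vol <- ctVolume(array(vals, c(20, 100, 10)))
  m <- fitPercentileMapping(vol, n_bins = 100)
  knots <- m@knots
  expect_equal(length(knots), 101)
  expect_false(is.unsorted(knots))
  expect_lt(max(abs(knots - seq(0, 1000, by = 10))), 10)  # one bin width

  clipped <- fitPercentileMapping(volWide, n_bins = 50,
                                  clip = windowSpec(-100, 300))
  expect_equal(clipped@knots[1], -100)
  expect_equal(clipped@knots[51], 300)

  two <- fitPercentileMapping(ctVolume(array(c(1, 2, 3, 4), c(1, 2, 2))),
                              n_bins = 2)
  expect_gte(two@knots[2], 2)
  expect_lte(two@knots[2], 3)

  expect_error(fitPercentileMapping(ctVolume(array(5, c(2, 2, 2)))),
               "degenerate")
})

test_that("the percentile mapping uniformizes its fitting data", {
  set.seed(52)
  # bimodal radiodensity mixture like brain + bone
  vals <- c(rnorm(30000, 30, 10), rnorm(15000, 1200, 300))
  vol <- ctVolume(array(vals, c(45, 100, 10)))
  m <- fitPercentileMapping(vol, n_bins = 100)
  mapped <- applyPercentileMapping(vol, m)
  expect_true(all(mapped >= 0 & mapped <= 1))
  expect_equal(applyPercentileMapping(array(m@knots[1], c(1, 1, 1)), m)[1], 0)
  expect_equal(applyPercentileMapping(array(m@knots[101], c(1, 1, 1)), m)[1],
               1)
  freq <- tabulate(pmin(floor(mapped * 100) + 1, 100), 100) / length(mapped)
  expect_true(all(abs(freq - 0.01) <= 0.002))   # within 20% of 1/100
  ks <- suppressWarnings(stats::ks.test(as.numeric(mapped), "punif"))
  expect_lte(unname(ks$statistic), 2 / 100)
})

test_that("the percentile mapping is monotone", {
  set.seed(53)
  vals <- sample(c(rnorm(500, 30, 10), rnorm(200, 800, 400)))
  vol <- ctVolume(array(vals[1:600], c(6, 10, 10)))
  m <- fitPercentileMapping(vol, n_bins = 20)
  x <- sort(runif(500, -500, 2000))
  y <- applyPercentileMapping(x, m)
  expect_true(all(diff(y) >= -1e-12))
})
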