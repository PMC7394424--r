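test_that("folds are disjoint, exhaustive and size-balanced", {
  ids <- sprintf("P%03d", 1:120)
  folds <- makeFolds(ids, 10, seed = 2)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, length, 1L) == 12))
  expect_equal(sort(unlist(folds)), 1:120)
  expect_identical(makeFolds(ids, 10, seed = 2), folds)
  odd <- makeFolds(1:11, 3, seed = 1)
  expect_equal(sort(unname(vapply(odd, length, 1L))), c(3L, 4L, 4L))
  expect_error(makeFolds(1:5, 6), "between 2")
})

test_that("rank-sum test matches closed-form and enumeration cases", {
  same <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p.value, 1)

  sep <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p.value, 0.1)

  # agrees with the tie-free reference implementation
  set.seed(71)
  a <- rnorm(6); b <- rnorm(7)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
  got <- rankSumTest(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("exact rank-sum p matches brute-force permutation enumeration", {
  set.seed(72)
  for (i in 1:5) {
    a <- sample(1:5, 4, replace = TRUE)   # heavy ties
    b <- sample(1:5, 4, replace = TRUE)
    expect_equal(rankSumTest(a, b)$p.value, refRankSumP(a, b),
                 info = paste(c(a, "|", b), collapse = " "))
  }
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
})

test_that("cross-validation trains by patient and reports fold summaries", {
  cohort <- makeCohort(4, tinySpec(), seed = 9)
  cv <- crossValidate(cohort, k = 2,
                      channels = preprocPreset("simple-multi"),
                      model_config = microModelConfig(),
                      train_config = microTrainConfig(epochs = 2),
                      augment = noAugment(), seed = 4)
  expect_length(cv, 2)
  allPatients <- sort(unlist(lapply(cv, function(f) f$results$patient_id)))
  expect_equal(allPatients,
               sort(vapply(cohort, function(p) patientId(p@ncct), "")))
  for (f in cv) {
    expect_equal(f$mean, mean(f$results$dice))
    expect_equal(f$sd, sd(f$results$dice))
    expect_equal(f$min, min(f$results$dice))
    expect_equal(f$max, max(f$results$dice))
    expect_true(all(f$results$TP >= 0 & f$results$FP >= 0 &
                      f$results$FN >= 0))
  }
  expect_error(crossValidate(cohort, k = 9), "exceeds")
})

test_that("the learning-curve harness runs its full design reproducibly", {
  cohort <- makeCohort(6, tinySpec(), seed = 10)
  lc <- learningCurve(cohort, sizes = c(2, 3), n_validation_sets = 1,
                      repeats = 1, validation_size = 2,
                      channels = preprocPreset("simple-multi"),
                      model_config = microModelConfig(),
                      train_config = microTrainConfig(epochs = 2),
                      augment = noAugment(), seed = 5)
  expect_equal(nrow(lc$runs), 2)        # sizes x val sets x repeats
  expect_equal(lc$summary$size, c(2, 3))
  lc2 <- learningCurve(cohort, sizes = c(2, 3), n_validation_sets = 1,
                       repeats = 1, validation_size = 2,
                       channels = preprocPreset("simple-multi"),
                       model_config = microModelConfig(),
                       train_config = microTrainConfig(epochs = 2),
                       augment = noAugment(), seed = 5)
  expect_identical(lc$runs, lc2$runs)
  expect_error(
    learningCurve(cohort, sizes = 10, n_validation_sets = 1, repeats = 1,
                  validation_size = 2),
    "infeasible")
})

test_that("the preprocessing comparison harness covers each configuration", {
  cohort <- makeCohort(4, tinySpec(), seed = 12)
  tab <- comparePreprocessing(cohort,
                              presets = c("simple-single", "uniform-clip"),
                              k = 2, model_config = microModelConfig(),
                              train_config = microTrainConfig(epochs = 1),
                              augment = noAugment(), seed = 6)
  expect_equal(tab$configuration, c("simple-single", "uniform-clip"))
  expect_true(all(tab$mean >= 0 & tab$mean <= 1))
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
})
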