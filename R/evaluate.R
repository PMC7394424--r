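# Whole-examination Dice evaluation, k-fold cross-validation, the
# training-set-size experiment and the rank-sum subgroup comparison.

#' Whole-examination Dice coefficient
#'
#' Confusion counts are aggregated over all voxels of the examination
#' before computing `2 TP / (2 TP + FP + FN)` -- deliberately not the mean
#' of per-slice Dice scores, because an angiography is assessed as a
#' whole.
#'
#' @param pred,truth [BinaryMask-class] objects on the same grid; `truth`
#'   must be non-empty.
#' @return A list of class `"ExamResult"`: `patient_id`, `TP`, `FP`, `FN`,
#'   `dice`, `sex`.
#' @examples
#' a <- binaryMask(array(c(1, 1, 1, 0), c(1, 2, 2)))
#' b <- binaryMask(array(c(1, 1, 0, 1), c(1, 2, 2)))
#' diceCoefficient(a, b)$dice   # TP=2, FP=1, FN=1 -> 2/3
#' @export
diceCoefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth grids do not match")
  tv <- voxels(truth)
  if (sum(tv) == 0)
    stop("empty truth mask: exam Dice undefined")
  pv <- voxels(pred)
  tp <- sum(pv * tv)
  fp <- sum(pv * (1 - tv))
  fn <- sum((1 - pv) * tv)
  structure(list(patient_id = patientId(truth), TP = tp, FP = fp, FN = fn,
                 dice = 2 * tp / (2 * tp + fp + fn), sex = NA_character_),
            class = "ExamResult")
}

#' Partition patients into cross-validation folds
#'
#' Random disjoint folds whose sizes differ by at most one; splitting is
#' always by patient, never by slice.
#'
#' @param ids patient identifiers (or any vector to partition).
#' @param k number of folds (2 <= k <= length(ids)).
#' @param seed partition seed.
#' @return A list of `k` integer index vectors.
#' @export
makeFolds <- function(ids, k, seed = 1) {
  n <- length(ids)
  if (k < 2 || k > n)
    stop("k must be between 2 and the number of patients")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  perm <- .withSeed(seed, sample(n))
  unname(split(perm, rep(seq_len(k), sizes)))
}

# Train on `trainCohort`, return per-exam results on `testCohort`.
.trainAndScore <- function(trainCohort, testCohort, channels, mcfg, tcfg,
                           augment) {
  model <- buildModel(mcfg)
  fit <- trainModel(model, trainCohort, channels, tcfg, augment)
  res <- lapply(testCohort, function(e) {
    pred <- predictVolume(fit$model, .examNcct(e))
    r <- diceCoefficient(pred, .examLabel(e))
    r$sex <- .examSex(e)
    r
  })
  data.frame(patient_id = vapply(res, `[[`, "", "patient_id"),
             TP = vapply(res, `[[`, 1, "TP"),
             FP = vapply(res, `[[`, 1, "FP"),
             FN = vapply(res, `[[`, 1, "FN"),
             dice = vapply(res, `[[`, 1, "dice"),
             sex = vapply(res, `[[`, "", "sex"),
             stringsAsFactors = FALSE)
}

#' k-fold cross-validation of the segmentation model
#'
#' Patients are partitioned into `k` disjoint folds; for each fold a fresh
#' model is trained on the remaining patients and evaluated by whole-exam
#' Dice on the held-out fold.
#'
#' @param cohort list of exams (see [trainModel()]).
#' @param k number of folds.
#' @param channels a [channelConfig()].
#' @param model_config a [modelConfig()].
#' @param train_config a [trainConfig()].
#' @param augment an [augmentationConfig()].
#' @param seed master seed; the partition and per-fold training seeds are
#'   derived from it.
#' @return A list of `k` `"FoldReport"` lists: `fold`, `results` (per-exam
#'   data.frame), `mean`, `sd`, `min`, `max` of Dice.
#' @export
crossValidate <- function(cohort, k = 10,
                          channels = preprocPreset("simple-multi"),
                          model_config = modelConfig(),
                          train_config = trainConfig(),
                          augment = augmentationConfig(), seed = 1) {
  if (k > length(cohort)) stop("k exceeds the cohort size")
  folds <- makeFolds(vapply(cohort, .examId, ""), k, seed)
  seeds <- .childSeeds(seed + 1L, k)
  lapply(seq_len(k), function(i) {
    test <- cohort[folds[[i]]]
    train <- cohort[-folds[[i]]]
    mcfg <- model_config; mcfg$seed <- seeds[i]
    tcfg <- train_config; tcfg$seed <- seeds[i]
    res <- .trainAndScore(train, test, channels, mcfg, tcfg, augment)
    list(fold = i, results = res, mean = mean(res$dice),
         sd = if (nrow(res) > 1) sd(res$dice) else NA_real_,
         min = min(res$dice), max = max(res$dice))
  })
}

#' Training-set-size experiment
#'
#' Isolates `n_validation_sets` disjoint validation groups; from the
#' remaining pool, training sets of each requested size are subsampled
#' `repeats` times, a model is trained on each, and the validation group's
#' mean whole-exam Dice is recorded.
#'
#' @param cohort list of exams.
#' @param sizes training-set sizes to test.
#' @param n_validation_sets number of disjoint validation groups.
#' @param repeats training subsamples per (validation set, size) cell.
#' @param validation_size patients per validation group.
#' @inheritParams crossValidate
#' @return A list with `runs` (one row per training run) and `summary`
#'   (mean Dice per size).
#' @export
learningCurve <- function(cohort, sizes, n_validation_sets = 5, repeats = 5,
                          validation_size = 12,
                          channels = preprocPreset("simple-multi"),
                          model_config = modelConfig(),
                          train_config = trainConfig(),
                          augment = augmentationConfig(), seed = 1) {
  n <- length(cohort)
  if (n_validation_sets * validation_size + max(sizes) > n)
    stop("infeasible design: validation groups plus the largest training ",
         "size exceed the cohort")
  perm <- .withSeed(seed, sample(n))
  valSets <- lapply(seq_len(n_validation_sets), function(v)
    perm[((v - 1) * validation_size + 1):(v * validation_size)])
  pool <- perm[-seq_len(n_validation_sets * validation_size)]
  grid <- expand.grid(rep = seq_len(repeats), size = sizes,
                      val_set = seq_len(n_validation_sets))
  seeds <- .childSeeds(seed + 1L, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    trIdx <- .withSeed(seeds[i], sample(pool, g$size))
    mcfg <- model_config; mcfg$seed <- seeds[i]
    tcfg <- train_config; tcfg$seed <- seeds[i]
    res <- .trainAndScore(cohort[trIdx], cohort[valSets[[g$val_set]]],
                          channels, mcfg, tcfg, augment)
    data.frame(val_set = g$val_set, size = g$size, rep = g$rep,
               mean_dice = mean(res$dice))
  })
  runs <- do.call(rbind, rows)
  summary <- stats::aggregate(mean_dice ~ size, runs, mean)
  list(runs = runs, summary = summary)
}

#' Mann-Whitney rank-sum test
#'
#' U from midranks; the two-sided p-value is exact (full enumeration of
#' all group assignments via the shift-algorithm distribution of the rank
#' sum, valid under ties) when `n_a * n_b <= 400`, and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param a,b numeric vectors (both non-empty), e.g. per-patient Dice
#'   coefficients of two subgroups.
#' @return A list with `U` (statistic of the first group) and `p.value`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  wa <- sum(r[seq_len(na)])
  U <- wa - na * (na + 1) / 2
  if (na * nb <= 400) {
    # exact distribution of the rank sum over all choose(na+nb, na)
    # assignments; doubled midranks keep sums integral
    r2 <- as.integer(round(2 * r))
    maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
    # f[j+1, s+1] = #subsets of size j with doubled-rank sum s
    f <- matrix(0, na + 1, maxS + 1)
    f[1, 1] <- 1
    for (item in r2) {
      for (j in seq(na, 1)) {      # reverse so each item is used once
        nz <- which(f[j, ] > 0)
        if (!length(nz)) next
        f[j + 1, nz + item] <- f[j + 1, nz + item] + f[j, nz]
      }
    }
    dist <- f[na + 1, ]
    total <- sum(dist)
    w2 <- as.integer(round(2 * wa))
    pLe <- sum(dist[seq_len(w2 + 1)]) / total        # rank sums <= observed
    pGe <- sum(dist[(w2 + 1):(maxS + 1)]) / total    # rank sums >= observed
    p <- min(1, 2 * min(pLe, pGe))
  } else {
    mu <- na * nb / 2
    nt <- na + nb
    ties <- table(r)
    sig2 <- na * nb / 12 * ((nt + 1) - sum(ties^3 - ties) /
                              (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(U = U, p.value = p)
}

#' Cross-validated comparison of preprocessing configurations
#'
#' Runs [crossValidate()] once per preprocessing preset (with matched
#' seeds) and tabulates fold-mean Dice summaries, reproducing the
#' preprocessing-comparison design at whatever cohort scale is supplied.
#'
#' @param cohort list of exams.
#' @param presets character vector of [preprocPreset()] names, optionally
#'   with a `"-1ch"` suffix for single-channel variants.
#' @inheritParams crossValidate
#' @return A data.frame with one row per configuration.
#' @export
comparePreprocessing <- function(cohort,
                                 presets = c("simple-single", "simple-multi",
                                             "uniform-full", "uniform-clip"),
                                 k = 10, model_config = modelConfig(),
                                 train_config = trainConfig(),
                                 augment = augmentationConfig(), seed = 1) {
  rows <- lapply(presets, function(p) {
    ch <- preprocPreset(sub("-1ch$", "", p),
                        n_channels = if (grepl("-1ch$", p)) 1 else 3)
    mcfg <- model_config
    mcfg$in_channels <- ch$n_channels
    cv <- crossValidate(cohort, k, ch, mcfg, train_config, augment, seed)
    dice <- unlist(lapply(cv, function(f) f$results$dice))
    data.frame(configuration = p, mean = mean(dice), sd = sd(dice),
               min = min(dice), max = max(dice))
  })
  do.call(rbind, rows)
}
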