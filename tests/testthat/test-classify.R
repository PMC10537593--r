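# small labelled crop set with a deterministic class difference: class
# "modified" carries a bright square at a class-specific position
toy_crops <- function(n_per_class, seed = 1, signal = 120, h = 120L,
                      w = 150L) {
  n <- 2L * n_per_class
  px <- array(0, c(h, w, 3L, n))
  lab <- rep(c("native", "modified"), each = n_per_class)
  set.seed(seed)
  for (i in seq_len(n)) {
    base <- array(abs(rnorm(h * w * 3, 8, 4)), c(h, w, 3))
    if (lab[i] == "modified") base[40:70, 60:90, ] <- signal
    else base[40:70, 20:50, ] <- signal
    px[, , , i] <- pmin(base, 255)
  }
  new("CellCropSet", pixels = px,
      info = data.frame(clipId = sprintf("t%03d", seq_len(n)),
                        section = "narrow", label = lab,
                        stringsAsFactors = FALSE))
}

test_that("dataset assembly shuffles deterministically and splits 80/20", {
  crops <- toy_crops(10)
  ds1 <- assembleDataset(crops, seed = 7)
  ds2 <- assembleDataset(crops, seed = 7)
  expect_identical(ds1$order, ds2$order)
  expect_identical(cropInfo(ds1$crops)$clipId, cropInfo(ds2$crops)$clipId)
  expect_equal(ds1$nTrain, 16)
  expect_equal(ds1$nVal, 4)
  # class counts preserved by the shuffle
  expect_equal(sum(cropInfo(ds1$crops)$label == "native"), 10)
  ds3 <- assembleDataset(crops, seed = 8)
  expect_false(identical(ds1$order, ds3$order))
})

test_that("assembly rejects unlabelled or single-class data", {
  crops <- toy_crops(4)
  crops@info$label[2] <- NA
  expect_error(assembleDataset(crops), "label")
  one <- toy_crops(4)[1:4]
  expect_error(assembleDataset(one), "both classes")
})

test_that("the network has the mandated topology and output head", {
  spec <- classifierSpec(seed = 3L)
  clf <- buildClassifier(spec)
  expect_equal(dim(clf@weights$W1), c(16L, 27L))     # 16 filters on 3x3x3
  expect_equal(dim(clf@weights$W2), c(64L, 144L))    # 64 filters on 3x3x16
  expect_equal(dim(clf@weights$W3), c(128L, 64512L)) # dense over 28*36*64
  expect_equal(dim(clf@weights$W4), c(2L, 128L))     # two output classes
  expect_error(classifierSpec(nClasses = 3L), "nClasses")
  expect_error(classifierSpec(valFraction = 1.2), "valFraction")
})

test_that("probabilities normalise, are finite on degenerate input, and tie
           towards native", {
  clf <- buildClassifier(classifierSpec(seed = 5L))
  x <- array(runif(120 * 150 * 3 * 4) * 255, c(120, 150, 3, 4))
  pr <- predict(clf, x)
  expect_true(all(abs(pr$pNative + pr$pModified - 1) < 1e-6))
  expect_true(all(pr$pNative >= 0 & pr$pModified >= 0))
  z <- predict(clf, array(0, c(120, 150, 3, 2)))
  expect_true(all(is.finite(unlist(z[, 1:2]))))
  # all-zero input gives identical logits across samples; argmax is stable
  expect_equal(z$predicted[1], z$predicted[2])
})

test_that("an untrained model scores chance on a balanced set", {
  # label-free inputs (pure noise) with balanced labels: the untrained
  # network's predictions are independent of the labels, so accuracy sits
  # in the binomial chance band
  set.seed(8)
  n <- 200L
  px <- array(runif(120 * 150 * 3 * n) * 80, c(120, 150, 3, n))
  lab <- rep(c("native", "modified"), n / 2)
  clf <- buildClassifier(classifierSpec(seed = 11L))
  pr <- predict(clf, px)
  acc <- mean(pr$predicted == lab)
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("training separates a deterministic shape difference", {
  crops <- toy_crops(32, signal = 150)
  ds <- assembleDataset(crops, seed = 2)
  spec <- classifierSpec(seed = 2L, epochs = 4L)
  fit <- trainClassifier(spec, ds)
  h <- trainingHistory(fit$report)
  expect_equal(nrow(h), 4L)
  expect_lt(h[4, "loss"], h[1, "loss"])
  expect_equal(fit$report@nTrain, 52L)
  expect_equal(fit$report@nValidation, 12L)
  test <- toy_crops(10, seed = 99, signal = 150)
  ev <- evaluateClassifier(fit$classifier, test, checkDisjoint = FALSE)
  expect_equal(accuracy(ev), 1.0)
  expect_named(ev@perClass, c("modified", "native"))
})

test_that("identical images with random labels train to chance", {
  n <- 32L
  px <- array(rep(array(runif(120 * 150 * 3) * 100, c(120, 150, 3)), n),
              c(120, 150, 3, n))
  set.seed(13)
  lab <- sample(rep(c("native", "modified"), n / 2))
  crops <- new("CellCropSet", pixels = px,
               info = data.frame(clipId = sprintf("n%02d", 1:n),
                                 section = "narrow", label = lab,
                                 stringsAsFactors = FALSE))
  ds <- assembleDataset(crops, seed = 3, valFraction = 0.5)
  fit <- trainClassifier(classifierSpec(seed = 3L, epochs = 5L,
                                        valFraction = 0.5), ds)
  va <- trainingHistory(fit$report)[5, "val_accuracy"]
  # identical inputs force a constant prediction: accuracy equals the class
  # share of the validation half
  share <- mean(ds$labels[(ds$nTrain + 1):n] == 0)
  expect_true(abs(va - max(share, 1 - share)) < 1e-9 ||
                abs(va - min(share, 1 - share)) < 1e-9)
  expect_gte(va, 0.2)
  expect_lte(va, 0.8)
})

test_that("evaluation enforces clip-level disjointness", {
  crops <- toy_crops(8)
  ds <- assembleDataset(crops, seed = 1)
  fit <- trainClassifier(classifierSpec(seed = 1L, epochs = 1L), ds)
  expect_error(evaluateClassifier(fit$classifier, crops[1:4]), "clip")
  fresh <- toy_crops(3, seed = 50)
  fresh@info$clipId <- paste0("new", 1:6)
  expect_silent(ev <- evaluateClassifier(fit$classifier, fresh))
  expect_s4_class(ev, "EvaluationReport")
})

test_that("training reproduces itself for a fixed seed", {
  crops <- toy_crops(16)
  ds <- assembleDataset(crops, seed = 4)
  spec <- classifierSpec(seed = 4L, epochs = 2L)
  h1 <- trainingHistory(trainClassifier(spec, ds)$report)
  h2 <- trainingHistory(trainClassifier(spec, ds)$report)
  expect_equal(h1[, "accuracy"], h2[, "accuracy"], tolerance = 0.02)
  expect_equal(h1[, "val_accuracy"], h2[, "val_accuracy"], tolerance = 0.02)
})

test_that("the leakage audit rejects degenerate input", {
  expect_error(leakageAudit(toy_crops(2)[1:2]), "both classes")
  empty <- new("CellCropSet", pixels = array(0, c(120, 150, 3, 0)),
               info = data.frame(clipId = character(0),
                                 section = character(0),
                                 label = character(0)))
  expect_error(leakageAudit(empty), "empty")
})
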