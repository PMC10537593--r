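label_levels <- c("native", "modified")

label_to_int <- function(labels) {
  if (any(!labels %in% label_levels))
    stop("labels must be 'native' or 'modified'")
  as.integer(labels == "modified")  # native = 0, modified = 1
}

#' Assemble a shuffled, labelled training dataset
#'
#' Pairs every crop with its label, shuffles the pairs deterministically for
#' the given seed, and marks a positional 80/20 train/validation split: after
#' shuffling, the last `floor(n * valFraction)` crops are the validation set.
#'
#' @param crops a [CellCropSet-class]; every crop must be labelled and both
#'   classes must be present
#' @param seed integer shuffle seed
#' @param valFraction validation fraction (default 0.2)
#' @return a list of class `rbcDataset`: `crops` (the shuffled
#'   [CellCropSet-class]), `labels` (integer, native = 0), `nTrain`, `nVal`
#' @examples
#' \donttest{
#' st <- generateStudy(1, 1, 5, seed = 11)
#' crops <- studyCrops(st$clips)
#' ds <- assembleDataset(crops, seed = 1)
#' c(ds$nTrain, ds$nVal)
#' }
#' @export
assembleDataset <- function(crops, seed = 1L, valFraction = 0.2) {
  info <- cropInfo(crops)
  if (!nrow(info)) stop("cannot assemble an empty dataset")
  if (any(is.na(info$label)))
    stop("every crop must carry a label")
  if (length(unique(info$label)) < 2)
    stop("both classes must be present in the training data")
  n <- length(crops)
  ord <- with_seed(seed, sample.int(n))
  shuffled <- crops[ord]
  nVal <- floor(n * valFraction)
  structure(list(crops = shuffled,
                 labels = label_to_int(cropInfo(shuffled)$label),
                 order = ord, nTrain = n - nVal, nVal = nVal),
            class = "rbcDataset")
}

#' @export
print.rbcDataset <- function(x, ...) {
  cat(sprintf("rbcDataset: %d labelled pairs (%d train / %d validation)\n",
              length(x$crops), x$nTrain, x$nVal))
  invisible(x)
}

#' Build an untrained crop classifier
#'
#' Instantiates the network of [ClassifierSpec-class] with Glorot-uniform
#' weights, deterministic for the spec's seed.
#'
#' @param spec a [ClassifierSpec-class]
#' @return an untrained [RBCClassifier-class]
#' @examples
#' clf <- buildClassifier(classifierSpec(seed = 1L))
#' clf
#' @export
buildClassifier <- function(spec = classifierSpec()) {
  stopifnot(is(spec, "ClassifierSpec"))
  w <- cpp_cnn_init(spec@inputShape[1], spec@inputShape[2],
                    spec@inputShape[3], spec@conv1Filters,
                    spec@conv2Filters, spec@denseUnits, spec@nClasses,
                    spec@seed)
  new("RBCClassifier", spec = spec, weights = w, trained = FALSE,
      history = matrix(numeric(0), 0, 4,
                       dimnames = list(NULL, c("loss", "accuracy",
                                               "val_loss", "val_accuracy"))),
      trainClipIds = character(0))
}

#' Train the crop classifier
#'
#' Optimises softmax cross-entropy with Adam for exactly `spec@epochs`
#' epochs in shuffled mini-batches of `spec@batchSize`, recording training
#' loss/accuracy (running over batches) and validation loss/accuracy per
#' epoch.
#'
#' @param classifier an [RBCClassifier-class] (or a [ClassifierSpec-class],
#'   which is built first)
#' @param dataset an `rbcDataset` from [assembleDataset()]
#' @return list with `classifier` (trained [RBCClassifier-class]) and
#'   `report` (a [TrainingReport-class])
#' @export
trainClassifier <- function(classifier, dataset) {
  if (is(classifier, "ClassifierSpec")) classifier <- buildClassifier(classifier)
  stopifnot(is(classifier, "RBCClassifier"),
            inherits(dataset, "rbcDataset"))
  spec <- classifier@spec
  px <- cropPixels(dataset$crops)
  if (!identical(dim(px)[1:3], as.integer(spec@inputShape)))
    stop("crop shape ", paste(dim(px)[1:3], collapse = "x"),
         " does not match the classifier input shape")
  n <- dim(px)[4]
  trainIdx <- seq_len(dataset$nTrain) - 1L
  valIdx <- if (dataset$nVal > 0) dataset$nTrain + seq_len(dataset$nVal) - 1L
            else integer(0)
  fit <- cpp_cnn_train(px, dataset$labels, classifier@weights, trainIdx,
                       valIdx, spec@epochs, spec@batchSize,
                       spec@learningRate, spec@rescaleFactor, spec@seed)
  trained <- new("RBCClassifier", spec = spec, weights = fit$weights,
                 trained = TRUE, history = fit$history,
                 trainClipIds = unique(cropInfo(dataset$crops)$clipId))
  list(classifier = trained,
       report = new("TrainingReport", history = fit$history,
                    nTrain = as.integer(dataset$nTrain),
                    nValidation = as.integer(dataset$nVal)))
}

#' @describeIn RBCClassifier-class class probabilities for new crops; returns
#'   a data.frame with columns pNative, pModified, predicted and (when the
#'   crops are labelled) label. Ties are broken towards "native".
#' @param object an [RBCClassifier-class]
#' @param newdata a [CellCropSet-class] or a (height, width, 3, n) array
#' @param ... unused
#' @export
setMethod("predict", "RBCClassifier", function(object, newdata, ...) {
  if (is(newdata, "CellCropSet")) {
    px <- cropPixels(newdata)
    labs <- cropInfo(newdata)$label
  } else {
    px <- newdata
    labs <- NULL
  }
  pr <- cpp_cnn_predict(px, object@weights, object@spec@rescaleFactor)
  out <- data.frame(pNative = pr[, 1], pModified = pr[, 2])
  out$predicted <- ifelse(out$pNative >= out$pModified, "native", "modified")
  if (!is.null(labs)) out$label <- labs
  out
})

#' Evaluate a trained classifier on held-out crops
#'
#' Scores every crop and reports overall, per-class and per-section
#' accuracies. Unless disabled, the test crops are required to come from
#' clips the classifier never saw during training (clip-level disjointness).
#'
#' @param classifier a trained [RBCClassifier-class]
#' @param crops a labelled [CellCropSet-class]
#' @param checkDisjoint verify clip-level train/test disjointness
#' @return an [EvaluationReport-class]
#' @export
evaluateClassifier <- function(classifier, crops, checkDisjoint = TRUE) {
  stopifnot(is(classifier, "RBCClassifier"), is(crops, "CellCropSet"))
  info <- cropInfo(crops)
  if (!nrow(info)) stop("empty evaluation set")
  if (checkDisjoint && length(classifier@trainClipIds)) {
    overlap <- intersect(info$clipId, classifier@trainClipIds)
    if (length(overlap))
      stop("evaluation crops share ", length(overlap),
           " clip(s) with the training set (e.g. ", overlap[1], ")")
  }
  pred <- predict(classifier, crops)
  pred$clipId <- info$clipId
  pred$section <- info$section
  pred$correct <- pred$predicted == pred$label
  acc <- mean(pred$correct)
  perSection <- vapply(split(pred$correct, pred$section), mean, numeric(1))
  perClass <- vapply(split(pred$correct, pred$label), mean, numeric(1))
  new("EvaluationReport",
      predictions = pred[, c("clipId", "section", "label", "pNative",
                             "pModified", "predicted", "correct")],
      accuracy = acc, perSection = perSection, perClass = perClass)
}

#' Confound (leakage) audit on background-only crops
#'
#' Trains the same architecture on crops that contain no cell — background
#' regions processed by the full pipeline, labelled with the class of the
#' clip they came from — and reports the held-out accuracy. A pipeline free
#' of confounds (focal planes mixed across classes, background removed)
#' cannot beat chance here; accuracy well above chance exposes a leak such
#' as a class-correlated focal plane.
#'
#' @param crops a labelled [CellCropSet-class] of background-only crops
#' @param spec a [ClassifierSpec-class]
#' @param nTest held-out crops (balanced, taken per class before shuffling)
#' @param seed split/shuffle seed
#' @return list with `accuracy` (held-out), `report`
#'   (a [TrainingReport-class]) and `evaluation`
#'   (an [EvaluationReport-class])
#' @export
leakageAudit <- function(crops, spec = classifierSpec(), nTest = 200L,
                         seed = 1L) {
  stopifnot(is(crops, "CellCropSet"))
  info <- cropInfo(crops)
  if (!nrow(info)) stop("empty audit set")
  if (length(unique(info$label)) < 2)
    stop("audit set must contain both classes")
  byClass <- split(seq_len(nrow(info)), info$label)
  nTestPer <- min(lengths(byClass) - 2L, ceiling(nTest / 2))
  if (nTestPer < 1) stop("audit set too small to hold out a test split")
  testIdx <- unlist(lapply(byClass, function(ix) ix[seq_len(nTestPer)]))
  trainPool <- setdiff(seq_len(nrow(info)), testIdx)
  ds <- assembleDataset(crops[trainPool], seed = seed,
                        valFraction = spec@valFraction)
  fit <- trainClassifier(spec, ds)
  ev <- evaluateClassifier(fit$classifier, crops[testIdx],
                           checkDisjoint = FALSE)
  list(accuracy = accuracy(ev), report = fit$report, evaluation = ev)
}
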