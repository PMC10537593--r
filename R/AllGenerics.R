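#' @name zigzagRBC-accessors
#' @title Accessors for zigzagRBC classes
#' @description Small accessor generics for the package's S4 classes.
#' @param x an object
#' @return the corresponding slot content (see the individual class pages)
NULL

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("clipLabel", function(x) standardGeneric("clipLabel"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("clipMeta", function(x) standardGeneric("clipMeta"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("cropPixels", function(x) standardGeneric("cropPixels"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("cropInfo", function(x) standardGeneric("cropInfo"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname zigzagRBC-accessors
#' @export
setGeneric("periodPx", function(x) standardGeneric("periodPx"))

# ---- methods ---------------------------------------------------------------

#' @describeIn ClipRecording-class pixel array as integers (height, width, 3,
#'   frames)
#' @param x a `ClipRecording`
#' @export
setMethod("frames", "ClipRecording", function(x) {
  a <- as.integer(x@frames)
  dim(a) <- x@dims
  a
})

#' @describeIn ClipRecording-class number of frames
#' @export
setMethod("nFrames", "ClipRecording", function(x) x@dims[4])

#' @describeIn ClipRecording-class clip label ("native", "modified" or NA)
#' @export
setMethod("clipLabel", "ClipRecording", function(x) {
  lb <- x@meta$label
  if (is.null(lb)) NA_character_ else lb
})

#' @describeIn ClipRecording-class per-clip metadata list
#' @export
setMethod("clipMeta", "ClipRecording", function(x) x@meta)

#' @describeIn ClipRecording-class ground-truth list (masks, clean
#'   background, centroids, shape), empty for real recordings
#' @export
setMethod("groundTruth", "ClipRecording", function(x) x@truth)

setMethod("show", "ClipRecording", function(object) {
  d <- object@dims
  cat(sprintf("ClipRecording: %d frames of %d x %d x 3 (8-bit)\n",
              d[4], d[1], d[2]))
  cat(sprintf("  clip id: %s  label: %s\n",
              object@meta$clipId %||% "<none>", clipLabel(object)))
  if (length(object@truth))
    cat("  ground truth: masks, clean background, centroids\n")
})

#' @describeIn ChannelGeometry-class oscillation period in pixels
#' @param x a `ChannelGeometry`
#' @export
setMethod("periodPx", "ChannelGeometry",
          function(x) x@periodicityUm * x@pxPerUm)

setMethod("show", "ChannelGeometry", function(object) {
  cat(sprintf(
    "ChannelGeometry: period %g um, openings %g/%g um, %g px/um\n",
    object@periodicityUm, object@narrowWidthUm, object@wideWidthUm,
    object@pxPerUm))
})

#' @describeIn CellCropSet-class numeric crop array (height, width, 3, n)
#' @param x a `CellCropSet`
#' @export
setMethod("cropPixels", "CellCropSet", function(x) x@pixels)

#' @describeIn CellCropSet-class per-crop metadata data.frame
#' @export
setMethod("cropInfo", "CellCropSet", function(x) x@info)

#' @describeIn CellCropSet-class number of crops
#' @export
setMethod("length", "CellCropSet", function(x) dim(x@pixels)[4])

#' @describeIn CellCropSet-class subset crops (`i` indexes crops)
#' @param i crop indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "CellCropSet", function(x, i, j, ..., drop = FALSE) {
  new("CellCropSet", pixels = x@pixels[, , , i, drop = FALSE],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "CellCropSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CellCropSet: %d crops of %d x %d x 3\n", d[4], d[1], d[2]))
  if (d[4] > 0) {
    tab <- table(object@info$label, object@info$section)
    print(tab)
  }
})

setMethod("show", "ClassifierSpec", function(object) {
  s <- object@inputShape
  cat(sprintf(
    paste0("ClassifierSpec: (%d,%d,%d) -> conv(%d) -> pool -> conv(%d) -> ",
           "pool -> dense(%d) -> dense(%d, softmax)\n"),
    s[1], s[2], s[3], object@conv1Filters, object@conv2Filters,
    object@denseUnits, object@nClasses))
  cat(sprintf("  %d epochs, batch %d, val fraction %g, Adam lr %g, seed %d\n",
              object@epochs, object@batchSize, object@valFraction,
              object@learningRate, object@seed))
})

#' @describeIn RBCClassifier-class per-epoch training history matrix
#' @param x an `RBCClassifier`
#' @export
setMethod("trainingHistory", "RBCClassifier", function(x) x@history)

setMethod("show", "RBCClassifier", function(object) {
  cat(sprintf("RBCClassifier (%s)\n",
              if (object@trained) "trained" else "untrained"))
  show(object@spec)
  if (object@trained) {
    h <- object@history
    cat(sprintf("  final epoch: acc %.3f, val acc %.3f\n",
                h[nrow(h), "accuracy"], h[nrow(h), "val_accuracy"]))
  }
})

#' @describeIn TrainingReport-class per-epoch history matrix
#' @param x a `TrainingReport`
#' @export
setMethod("trainingHistory", "TrainingReport", function(x) x@history)

setMethod("show", "TrainingReport", function(object) {
  cat(sprintf("TrainingReport: %d epochs, %d train / %d validation\n",
              nrow(object@history), object@nTrain, object@nValidation))
})

#' @describeIn EvaluationReport-class per-crop prediction data.frame
#' @param x an `EvaluationReport`
#' @export
setMethod("predictions", "EvaluationReport", function(x) x@predictions)

#' @describeIn EvaluationReport-class overall held-out accuracy
#' @export
setMethod("accuracy", "EvaluationReport", function(x) x@accuracy)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: accuracy %.4f on %d crops\n",
              object@accuracy, nrow(object@predictions)))
  if (length(object@perSection)) {
    cat("  per section:",
        paste(names(object@perSection),
              sprintf("%.4f", object@perSection), collapse = ", "), "\n")
  }
  if (length(object@perClass)) {
    cat("  per class:  ",
        paste(names(object@perClass),
              sprintf("%.4f", object@perClass), collapse = ", "), "\n")
  }
})

setMethod("show", "FlowConditions", function(object) {
  cat(sprintf(
    "FlowConditions: v = %g mm/s, w_av = %g um, eta = %g mPa s\n",
    object@vRbcMmPerS, object@wAvUm, object@etaMPaS))
  cat(sprintf("  gamma_eff = %g 1/s, tau_eff = %g Pa\n",
              object@gammaEffPerS, object@tauEffPa))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
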