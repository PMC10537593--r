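#' Physical geometry of the zigzag channel
#'
#' Dimensions of the periodically oscillating ("zigzag") microchannel and the
#' pixel scale used to render it and to place finishing lines. Defaults match
#' the device this package models: 20 um periodicity, 20 um amplitude, 10 um
#' narrow and 20 um wide openings, 10 um height.
#'
#' @slot periodicityUm period of the width oscillation (um)
#' @slot amplitudeUm zigzag amplitude (um); retained as metadata, the wall
#'   profile is parameterised by the opening widths
#' @slot narrowWidthUm channel opening in the narrow sections (um)
#' @slot wideWidthUm channel opening in the wide sections (um)
#' @slot heightUm channel depth (um); metadata only
#' @slot pxPerUm pixel scale of the rendered frames (px/um)
#' @exportClass ChannelGeometry
setClass("ChannelGeometry",
  representation(periodicityUm = "numeric", amplitudeUm = "numeric",
                 narrowWidthUm = "numeric", wideWidthUm = "numeric",
                 heightUm = "numeric", pxPerUm = "numeric"),
  validity = function(object) {
    v <- c(object@periodicityUm, object@amplitudeUm, object@narrowWidthUm,
           object@wideWidthUm, object@heightUm, object@pxPerUm)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all geometry fields must be finite and > 0")
    if (object@narrowWidthUm > object@wideWidthUm)
      return("narrowWidthUm must be <= wideWidthUm")
    TRUE
  })

#' @param periodicityUm,amplitudeUm,narrowWidthUm,wideWidthUm,heightUm,pxPerUm
#'   see the corresponding slots
#' @return `channelGeometry()` returns a `ChannelGeometry` object.
#' @examples
#' geom <- channelGeometry()
#' periodPx(geom)
#' @rdname ChannelGeometry-class
#' @export
channelGeometry <- function(periodicityUm = 20, amplitudeUm = 20,
                            narrowWidthUm = 10, wideWidthUm = 20,
                            heightUm = 10, pxPerUm = 5) {
  new("ChannelGeometry", periodicityUm = periodicityUm,
      amplitudeUm = amplitudeUm, narrowWidthUm = narrowWidthUm,
      wideWidthUm = wideWidthUm, heightUm = heightUm, pxPerUm = pxPerUm)
}

#' Phenomenological single-cell model
#'
#' A deformable cell blob. `stiffness` interpolates between a fully compliant
#' cell whose elongation tracks the local channel width (0) and a rigid cell
#' whose shape ignores it (1); `relaxationFrames` is the first-order lag with
#' which the shape adapts, the stand-in for the viscoelastic relaxation time.
#'
#' @slot radiusUm rest radius of the blob (um)
#' @slot stiffness dimensionless in [0, 1]
#' @slot relaxationFrames shape-adaptation lag (frames, >= 0)
#' @slot speedUmPerFrame advection speed along the channel (um/frame)
#' @slot contrast peak intensity the cell adds over the background
#'   (8-bit units, per-channel scaling is fixed by the fluorescence colour)
#' @slot startXPx x-coordinate of the centroid in the first frame (px, 0-based)
#' @slot yOffsetPx centroid offset from the channel centreline (px)
#' @exportClass CellModel
setClass("CellModel",
  representation(radiusUm = "numeric", stiffness = "numeric",
                 relaxationFrames = "numeric", speedUmPerFrame = "numeric",
                 contrast = "numeric", startXPx = "numeric",
                 yOffsetPx = "numeric"),
  validity = function(object) {
    if (object@stiffness < 0 || object@stiffness > 1)
      return("stiffness must be in [0, 1]")
    if (object@relaxationFrames < 0)
      return("relaxationFrames must be >= 0")
    if (object@speedUmPerFrame <= 0)
      return("speedUmPerFrame must be > 0")
    if (object@radiusUm <= 0) return("radiusUm must be > 0")
    TRUE
  })

#' @param radiusUm,stiffness,relaxationFrames,speedUmPerFrame,contrast,startXPx,yOffsetPx
#'   see the corresponding slots
#' @return `cellModel()` returns a `CellModel` object.
#' @rdname CellModel-class
#' @export
cellModel <- function(radiusUm = 3.5, stiffness = 0.2, relaxationFrames = 6,
                      speedUmPerFrame = 2.55, contrast = 120,
                      startXPx = 30, yOffsetPx = 0) {
  new("CellModel", radiusUm = radiusUm, stiffness = stiffness,
      relaxationFrames = relaxationFrames,
      speedUmPerFrame = speedUmPerFrame, contrast = contrast,
      startXPx = startXPx, yOffsetPx = yOffsetPx)
}

#' Rendering configuration for synthetic clips
#'
#' @slot frameSizePx (height, width) of the rendered frames; height >= 120
#'   and width large enough for both finishing lines plus the 250 px
#'   detection extent
#' @slot framesPerSequence frames per triggered cell sequence (>= 3 so that
#'   the cell is outside the crop region in the first and last frames and the
#'   background splice is exact)
#' @slot noiseSigma pixel noise standard deviation (8-bit units)
#' @slot backgroundTextureSeed integer seed of the static background texture
#' @slot focalBlurSigma Gaussian defocus sigma (px; 0 = in focus)
#' @slot rngSeed integer seed of the pixel-noise stream
#' @exportClass RenderConfig
setClass("RenderConfig",
  representation(frameSizePx = "integer", framesPerSequence = "integer",
                 noiseSigma = "numeric", backgroundTextureSeed = "integer",
                 focalBlurSigma = "numeric", rngSeed = "integer"),
  validity = function(object) {
    if (length(object@frameSizePx) != 2 || any(object@frameSizePx < 1))
      return("frameSizePx must be (height, width)")
    if (object@framesPerSequence < 3)
      return("framesPerSequence must be >= 3")
    if (object@noiseSigma < 0 || object@focalBlurSigma < 0)
      return("noiseSigma and focalBlurSigma must be >= 0")
    TRUE
  })

#' @param frameSizePx,framesPerSequence,noiseSigma,backgroundTextureSeed,focalBlurSigma,rngSeed
#'   see the corresponding slots
#' @return `renderConfig()` returns a `RenderConfig` object.
#' @rdname RenderConfig-class
#' @export
renderConfig <- function(frameSizePx = c(120L, 460L),
                         framesPerSequence = 40L, noiseSigma = 2,
                         backgroundTextureSeed = 1L, focalBlurSigma = 0,
                         rngSeed = 1L) {
  new("RenderConfig", frameSizePx = as.integer(frameSizePx),
      framesPerSequence = as.integer(framesPerSequence),
      noiseSigma = noiseSigma,
      backgroundTextureSeed = as.integer(backgroundTextureSeed),
      focalBlurSigma = focalBlurSigma, rngSeed = as.integer(rngSeed))
}

#' One triggered single-cell video sequence
#'
#' An ordered stack of 8-bit, 3-channel frames for one cell, stored compactly
#' as a raw vector with dimensions `dim(x)` = (height, width, 3, frames),
#' plus per-clip metadata and (for synthetic clips) the ground truth: the
#' clean background, per-frame binary cell masks and centroids.
#'
#' @slot frames raw pixel store, column-major (height, width, 3, frames)
#' @slot dims integer dimensions of `frames`
#' @slot meta list: clipId, label ("native"/"modified" or NA), finishing
#'   lines, blur sigma, and the generating cell parameters when synthetic
#' @slot truth list with elements `masks` (raw, height x width x frames),
#'   `clean` (raw, height x width x 3), `centroids` (frames x 2, 0-based
#'   x/y), `shape` (frames x 2 semi-axes) — or empty for real recordings
#' @exportClass ClipRecording
setClass("ClipRecording",
  representation(frames = "raw", dims = "integer", meta = "list",
                 truth = "list"),
  validity = function(object) {
    if (length(object@dims) != 4)
      return("dims must be (height, width, 3, frames)")
    if (object@dims[3] != 3) return("clips must have 3 channels")
    if (length(object@frames) != prod(object@dims))
      return("frame store does not match dims")
    TRUE
  })

#' Soft-trigger detection configuration
#'
#' The detection window at a finishing line spans x in
#' [line, line + detectXExtent] and y in `detectYRange` (inclusive, 0-based);
#' a cell triggers in the first frame whose largest foreground contour
#' encloses an area strictly greater than `minContourAreaPx2`.
#'
#' @slot finishLineNarrowPx x-coordinate of the narrow-section finishing line
#' @slot finishLineWidePx x-coordinate of the wide-section finishing line
#' @slot detectYRange inclusive y-range of the detection window (default 10, 110)
#' @slot detectXExtent window length beyond the finishing line (default 250 px)
#' @slot minContourAreaPx2 contour-area gate (default 20 px^2, strict >)
#' @slot segmentationHistory history of the Gaussian-mixture background model
#'   (default 100 frames; learning rate is 1/history)
#' @slot segmentationVarThreshold squared-distance threshold in units of the
#'   mode variance (default 20)
#' @slot nModes number of mixture modes per pixel (default 5)
#' @slot varInit,varMin initial and minimum mode variance
#' @slot backgroundRatio cumulative weight of modes treated as background
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(finishLineNarrowPx = "integer", finishLineWidePx = "integer",
                 detectYRange = "integer", detectXExtent = "integer",
                 minContourAreaPx2 = "numeric", segmentationHistory = "integer",
                 segmentationVarThreshold = "numeric", nModes = "integer",
                 varInit = "numeric", varMin = "numeric",
                 backgroundRatio = "numeric"),
  validity = function(object) {
    if (object@detectYRange[1] >= object@detectYRange[2])
      return("detectYRange must be increasing")
    if (object@minContourAreaPx2 <= 0)
      return("minContourAreaPx2 must be > 0")
    if (object@segmentationHistory < 1) return("history must be >= 1")
    TRUE
  })

#' @param finishLineNarrowPx,finishLineWidePx,detectYRange,detectXExtent,minContourAreaPx2,segmentationHistory,segmentationVarThreshold,nModes,varInit,varMin,backgroundRatio
#'   see the corresponding slots
#' @return `detectionConfig()` returns a `DetectionConfig` object.
#' @rdname DetectionConfig-class
#' @export
detectionConfig <- function(finishLineNarrowPx = 150L,
                            finishLineWidePx = 200L,
                            detectYRange = c(10L, 110L),
                            detectXExtent = 250L,
                            minContourAreaPx2 = 20,
                            segmentationHistory = 100L,
                            segmentationVarThreshold = 20,
                            nModes = 5L, varInit = 15, varMin = 4,
                            backgroundRatio = 0.9) {
  new("DetectionConfig",
      finishLineNarrowPx = as.integer(finishLineNarrowPx),
      finishLineWidePx = as.integer(finishLineWidePx),
      detectYRange = as.integer(detectYRange),
      detectXExtent = as.integer(detectXExtent),
      minContourAreaPx2 = minContourAreaPx2,
      segmentationHistory = as.integer(segmentationHistory),
      segmentationVarThreshold = segmentationVarThreshold,
      nModes = as.integer(nModes), varInit = varInit, varMin = varMin,
      backgroundRatio = backgroundRatio)
}

#' Crop geometry around a finishing line
#'
#' Crops are `height` rows starting at `yStart` and 150 columns spanning
#' [line - xBeforePx, line + xAfterPx - 1]; the spliced background takes the
#' columns left of `spliceCol` from the per-pixel median of the last
#' `nEdgeFrames` frames and the rest from the first `nEdgeFrames` frames.
#'
#' @slot yStart first cropped row (0-based)
#' @slot height,width crop size in px (120 x 150)
#' @slot xBeforePx columns kept left of the finishing line (default 80)
#' @slot xAfterPx columns kept right of it (default 70)
#' @slot spliceCol first column (0-based) taken from the leading frames
#' @slot nEdgeFrames frames aggregated per half (per-pixel median)
#' @exportClass CropSpec
setClass("CropSpec",
  representation(yStart = "integer", height = "integer", width = "integer",
                 xBeforePx = "integer", xAfterPx = "integer",
                 spliceCol = "integer", nEdgeFrames = "integer"),
  validity = function(object) {
    if (object@xBeforePx + object@xAfterPx != object@width)
      return("xBeforePx + xAfterPx must equal the crop width")
    if (object@spliceCol < 0 || object@spliceCol > object@width)
      return("spliceCol outside the crop")
    if (object@nEdgeFrames < 1) return("nEdgeFrames must be >= 1")
    TRUE
  })

#' @param yStart,height,width,xBeforePx,xAfterPx,spliceCol,nEdgeFrames see
#'   the corresponding slots
#' @return `cropSpec()` returns a `CropSpec` object.
#' @rdname CropSpec-class
#' @export
cropSpec <- function(yStart = 0L, height = 120L, width = 150L,
                     xBeforePx = 80L, xAfterPx = 70L, spliceCol = 75L,
                     nEdgeFrames = 5L) {
  new("CropSpec", yStart = as.integer(yStart), height = as.integer(height),
      width = as.integer(width), xBeforePx = as.integer(xBeforePx),
      xAfterPx = as.integer(xAfterPx), spliceCol = as.integer(spliceCol),
      nEdgeFrames = as.integer(nEdgeFrames))
}

#' A set of background-subtracted single-cell crops
#'
#' Pixels are non-negative absolute differences in 8-bit units, stored as a
#' numeric array (height, width, 3, n). `cropInfo()` carries one row per
#' crop: clipId, section ("narrow"/"wide"), label, trigger frame and the
#' generating parameters when synthetic.
#'
#' @slot pixels numeric array (height, width, 3, n), values in [0, 255]
#' @slot info data.frame with n rows
#' @exportClass CellCropSet
setClass("CellCropSet",
  representation(pixels = "array", info = "data.frame"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 4) return("pixels must be (height, width, 3, n)")
    if (d[3] != 3) return("crops must have 3 channels")
    if (nrow(object@info) != d[4])
      return("info rows must match the number of crops")
    if (length(object@pixels) && min(object@pixels) < 0)
      return("crop pixels must be non-negative")
    TRUE
  })

#' Architecture and training hyper-parameters of the crop classifier
#'
#' The network is: rescale (x `rescaleFactor`) -> conv(16, 3x3, stride 1,
#' relu) -> max-pool 2x2 -> conv(64, 3x3, stride 1, relu) -> max-pool 2x2 ->
#' flatten -> dense(128, relu) -> dense(2, softmax), trained with softmax
#' cross-entropy and Adam for 10 epochs in shuffled mini-batches of 32.
#'
#' @slot inputShape (height, width, channels), default (120, 150, 3)
#' @slot rescaleFactor multiplicative pixel normalisation (default 1/255)
#' @slot conv1Filters,conv2Filters filters of the two convolution stages
#' @slot kernel,stride convolution kernel and stride (fixed 3x3 / 1x1)
#' @slot poolSize max-pooling window (fixed 2)
#' @slot denseUnits width of the hidden dense layer
#' @slot nClasses number of output classes (2)
#' @slot epochs,batchSize,valFraction training schedule (10 / 32 / 0.2)
#' @slot learningRate Adam step size (default 1e-3)
#' @slot seed integer seed for weight initialisation and batch shuffling
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  representation(inputShape = "integer", rescaleFactor = "numeric",
                 conv1Filters = "integer", conv2Filters = "integer",
                 kernel = "integer", stride = "integer", poolSize = "integer",
                 denseUnits = "integer", nClasses = "integer",
                 epochs = "integer", batchSize = "integer",
                 valFraction = "numeric", learningRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nClasses != 2L) return("nClasses must be 2")
    if (object@valFraction <= 0 || object@valFraction >= 1)
      return("valFraction must be in (0, 1)")
    if (object@epochs < 1) return("epochs must be >= 1")
    if (!identical(object@kernel, c(3L, 3L)))
      return("kernel is fixed at (3, 3)")
    if (!identical(object@stride, c(1L, 1L)))
      return("stride is fixed at (1, 1)")
    TRUE
  })

#' @param inputShape,rescaleFactor,conv1Filters,conv2Filters,kernel,stride,poolSize,denseUnits,nClasses,epochs,batchSize,valFraction,learningRate,seed
#'   see the corresponding slots
#' @return `classifierSpec()` returns a `ClassifierSpec` object.
#' @examples
#' spec <- classifierSpec(seed = 7L)
#' spec
#' @rdname ClassifierSpec-class
#' @export
classifierSpec <- function(inputShape = c(120L, 150L, 3L),
                           rescaleFactor = 1 / 255,
                           conv1Filters = 16L, conv2Filters = 64L,
                           kernel = c(3L, 3L), stride = c(1L, 1L),
                           poolSize = 2L, denseUnits = 128L, nClasses = 2L,
                           epochs = 10L, batchSize = 32L, valFraction = 0.2,
                           learningRate = 1e-3, seed = 1L) {
  new("ClassifierSpec", inputShape = as.integer(inputShape),
      rescaleFactor = rescaleFactor, conv1Filters = as.integer(conv1Filters),
      conv2Filters = as.integer(conv2Filters), kernel = as.integer(kernel),
      stride = as.integer(stride), poolSize = as.integer(poolSize),
      denseUnits = as.integer(denseUnits), nClasses = as.integer(nClasses),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      valFraction = valFraction, learningRate = learningRate,
      seed = as.integer(seed))
}

#' Trained crop classifier
#'
#' @slot spec the `ClassifierSpec`
#' @slot weights list of layer weight matrices/vectors
#' @slot trained logical
#' @slot history per-epoch matrix (loss, accuracy, val_loss, val_accuracy)
#' @slot trainClipIds clip ids seen during training (used to enforce
#'   clip-level disjointness at evaluation)
#' @exportClass RBCClassifier
setClass("RBCClassifier",
  representation(spec = "ClassifierSpec", weights = "list",
                 trained = "logical", history = "matrix",
                 trainClipIds = "character"))

#' Per-epoch training record
#'
#' @slot history matrix with one row per epoch and columns loss, accuracy,
#'   val_loss, val_accuracy
#' @slot nTrain,nValidation sizes of the 80/20 positional split
#' @exportClass TrainingReport
setClass("TrainingReport",
  representation(history = "matrix", nTrain = "integer",
                 nValidation = "integer"),
  validity = function(object) {
    acc <- object@history[, c("accuracy", "val_accuracy")]
    if (any(acc < 0 | acc > 1, na.rm = TRUE))
      return("accuracies must lie in [0, 1]")
    TRUE
  })

#' Held-out evaluation of a trained classifier
#'
#' @slot predictions data.frame with one row per crop: clipId, section,
#'   label, pNative, pModified, predicted, correct
#' @slot accuracy overall held-out accuracy
#' @slot perSection named accuracies for narrow/wide crops present
#' @slot perClass named accuracies for native/modified
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(predictions = "data.frame", accuracy = "numeric",
                 perSection = "numeric", perClass = "numeric"))

#' Flow-condition estimates in the channel
#'
#' @slot vRbcMmPerS mean cell velocity (mm/s)
#' @slot wAvUm average channel width (um), the mean of the narrow and wide
#'   openings
#' @slot etaMPaS suspension viscosity (mPa s)
#' @slot gammaEffPerS effective shear rate 2 v / w (1/s)
#' @slot tauEffPa effective shear stress eta * gamma (Pa)
#' @slot pressureMbar,densityGPerMl,osmolarityMOsmPerL recorded experiment
#'   conditions (metadata)
#' @exportClass FlowConditions
setClass("FlowConditions",
  representation(vRbcMmPerS = "numeric", wAvUm = "numeric",
                 etaMPaS = "numeric", gammaEffPerS = "numeric",
                 tauEffPa = "numeric", pressureMbar = "numeric",
                 densityGPerMl = "numeric", osmolarityMOsmPerL = "numeric"),
  validity = function(object) {
    v <- c(object@vRbcMmPerS, object@wAvUm, object@etaMPaS,
           object@pressureMbar, object@densityGPerMl,
           object@osmolarityMOsmPerL)
    if (any(v <= 0)) return("all flow-condition fields must be > 0")
    TRUE
  })
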