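crop_x0 <- function(line, crop) line - crop@xBeforePx

#' Spliced cell-free background for a crop region
#'
#' Because the cell crosses the crop region from left to right, the left half
#' of the region is cell-free in a clip's final frames and the right half in
#' its first frames. The background is therefore spliced at the crop midline:
#' columns left of `spliceCol` are the per-pixel median over the last
#' `nEdgeFrames` frames, the remaining columns over the first `nEdgeFrames`.
#'
#' @param clip a [ClipRecording-class] with at least `2 * nEdgeFrames` frames
#' @param line finishing-line x-coordinate (0-based px)
#' @param crop a [CropSpec-class]
#' @return numeric array (height, width, 3) in 8-bit units
#' @examples
#' st <- generateStudy(1, 0, 1, seed = 5,
#'                     render = renderConfig(noiseSigma = 0))
#' bg <- buildBackground(st$clips[[1]], 150L)
#' dim(bg)
#' @export
buildBackground <- function(clip, line, crop = cropSpec()) {
  stopifnot(is(clip, "ClipRecording"), is(crop, "CropSpec"))
  if (nFrames(clip) < 2 * crop@nEdgeFrames)
    stop("clip has ", nFrames(clip), " frames; background splicing needs ",
         2 * crop@nEdgeFrames)
  x0 <- crop_x0(line, crop)
  if (x0 < 0 || x0 + crop@width > clip@dims[2])
    stop("crop region [", x0, ", ", x0 + crop@width - 1,
         "] falls outside the frame")
  cpp_spliced_background(clip@frames, clip@dims, x0, crop@yStart,
                         crop@height, crop@width, crop@nEdgeFrames,
                         crop@spliceCol)
}

#' Crop one frame of a clip around a finishing line
#'
#' @param clip a [ClipRecording-class]
#' @param frameIndex 1-based frame index
#' @param line finishing-line x-coordinate (0-based px)
#' @param crop a [CropSpec-class]
#' @return numeric array (height, width, 3) in 8-bit units
#' @export
cropFrame <- function(clip, frameIndex, line, crop = cropSpec()) {
  x0 <- crop_x0(line, crop)
  cpp_crop_frame(clip@frames, clip@dims, as.integer(frameIndex) - 1L,
                 as.integer(x0), crop@yStart, crop@height, crop@width)
}

#' Absolute-difference background subtraction
#'
#' Subtracts the spliced background from a cropped frame per channel in
#' floating point and takes the absolute value, yielding the non-negative
#' cell image the classifier consumes.
#'
#' @param frameCrop numeric array (height, width, 3), e.g. from [cropFrame()]
#' @param background numeric array of identical shape, from
#'   [buildBackground()]
#' @return numeric array (height, width, 3) of |frame - background|, values
#'   in [0, 255]
#' @export
subtractBackground <- function(frameCrop, background) {
  if (!identical(dim(frameCrop), dim(background)))
    stop("frame crop and background shapes differ: ",
         paste(dim(frameCrop), collapse = "x"), " vs ",
         paste(dim(background), collapse = "x"))
  abs(frameCrop - background)
}

#' Extract the background-subtracted cell crop for a trigger event
#'
#' Composes [buildBackground()], [cropFrame()] at the trigger frame and
#' [subtractBackground()] for one `TriggerEvent`.
#'
#' @param clip the [ClipRecording-class] the event came from
#' @param event a `TriggerEvent` from [findTriggerFrame()]
#' @param config the [DetectionConfig-class] (provides the finishing lines)
#' @param crop a [CropSpec-class]
#' @return numeric array (height, width, 3); attributes carry the event
#' @export
extractCellCrop <- function(clip, event, config = detectionConfig(),
                            crop = cropSpec()) {
  line <- switch(event$section, narrow = config@finishLineNarrowPx,
                 wide = config@finishLineWidePx)
  bg <- buildBackground(clip, line, crop)
  px <- subtractBackground(cropFrame(clip, event$frameIndex, line, crop), bg)
  attr(px, "event") <- event
  px
}

#' Process one clip into its per-section cell crops
#'
#' Runs the soft trigger at both finishing lines and extracts one
#' background-subtracted crop per detected section.
#'
#' @param clip a [ClipRecording-class]
#' @param config a [DetectionConfig-class]
#' @param crop a [CropSpec-class]
#' @return named list (narrow/wide) of crop arrays; sections without a
#'   qualifying event are dropped
#' @export
processClip <- function(clip, config = detectionConfig(), crop = cropSpec()) {
  ev <- detectTriggers(clip, config)
  out <- list()
  for (section in names(ev)) {
    if (is.null(ev[[section]])) next
    out[[section]] <- extractCellCrop(clip, ev[[section]], config, crop)
  }
  out
}

#' Bundle crop arrays into a CellCropSet
#'
#' @param crops list of (height, width, 3) numeric arrays
#' @param info data.frame with one row per crop (clipId, section, label, ...)
#' @return a [CellCropSet-class]
#' @export
cellCropSet <- function(crops, info) {
  stopifnot(length(crops) == nrow(info))
  if (!length(crops)) {
    return(new("CellCropSet",
               pixels = array(0, c(cropSpec()@height, cropSpec()@width, 3, 0)),
               info = info))
  }
  d <- dim(crops[[1]])
  px <- array(0, c(d, length(crops)))
  for (i in seq_along(crops)) px[, , , i] <- crops[[i]]
  rownames(info) <- NULL
  new("CellCropSet", pixels = px, info = info)
}
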