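detect_window <- function(clip, config, section) {
  line <- switch(section,
                 narrow = config@finishLineNarrowPx,
                 wide = config@finishLineWidePx,
                 stop("section must be 'narrow' or 'wide'"))
  x0 <- line
  x1 <- line + config@detectXExtent
  y0 <- config@detectYRange[1]
  y1 <- config@detectYRange[2]
  if (x1 >= clip@dims[2] || y1 >= clip@dims[1])
    stop("detection window [", x0, ",", x1, "] x [", y0, ",", y1,
         "] does not fit the ", clip@dims[1], " x ", clip@dims[2], " frame")
  list(line = line, x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

#' Per-frame foreground segmentation in the detection window
#'
#' Runs the Gaussian-mixture background/foreground model (history 100,
#' variance threshold 20, 5 modes, no shadow class) over the detection window
#' of one finishing line. The model is seeded from the first frame; from the
#' second frame on, a pixel is foreground when its squared distance to every
#' background mode exceeds `varThreshold * variance`.
#'
#' @param clip a [ClipRecording-class] with >= 2 frames
#' @param config a [DetectionConfig-class]
#' @param section "narrow" or "wide"
#' @return raw array (windowHeight, windowWidth, frames) of 0/1 foreground
#'   flags, with attributes `window` (list x0, x1, y0, y1, line) and
#'   `section`
#' @examples
#' st <- generateStudy(1, 0, 1, seed = 3)
#' fg <- segmentForeground(st$clips[[1]], detectionConfig(), "narrow")
#' dim(fg)
#' @export
segmentForeground <- function(clip, config = detectionConfig(),
                              section = c("narrow", "wide")) {
  section <- match.arg(section)
  stopifnot(is(clip, "ClipRecording"))
  if (nFrames(clip) < 2)
    stop("foreground segmentation needs at least 2 frames")
  win <- detect_window(clip, config, section)
  masks <- cpp_segment_window(clip@frames, clip@dims, win$x0, win$x1,
                              win$y0, win$y1, config@segmentationHistory,
                              config@segmentationVarThreshold,
                              config@nModes, config@varInit, config@varMin,
                              config@backgroundRatio)
  attr(masks, "window") <- win
  attr(masks, "section") <- section
  masks
}

#' Find the trigger frame in a foreground mask stack
#'
#' Extracts contours from each frame's foreground mask and reports the first
#' frame (lowest index) whose largest contour encloses an area strictly
#' greater than the gate. Contour area is the enclosed-polygon (shoelace)
#' area of the traced outer boundary, not a pixel count.
#'
#' @param masks output of [segmentForeground()]
#' @param config a [DetectionConfig-class]
#' @param section "narrow" or "wide" (defaults to the stack's own tag)
#' @param clipId identifier recorded in the event
#' @return a list of class `TriggerEvent` (clipId, section, frameIndex
#'   [1-based], contourAreaPx2, contourBbox [frame coordinates, 0-based
#'   x0, y0, x1, y1]) or `NULL` when no frame qualifies
#' @export
findTriggerFrame <- function(masks, config = detectionConfig(),
                             section = attr(masks, "section"),
                             clipId = NA_character_) {
  win <- attr(masks, "window")
  stats <- cpp_contour_stats(masks, dim(masks))
  hit <- which(stats[, 1] > config@minContourAreaPx2)
  if (!length(hit)) return(NULL)
  t <- hit[1]
  structure(list(clipId = clipId, section = section, frameIndex = t,
                 contourAreaPx2 = stats[t, 1],
                 contourBbox = c(x0 = stats[t, 2] + win$x0,
                                 y0 = stats[t, 3] + win$y0,
                                 x1 = stats[t, 4] + win$x0,
                                 y1 = stats[t, 5] + win$y0)),
            class = "TriggerEvent")
}

#' @export
print.TriggerEvent <- function(x, ...) {
  cat(sprintf("TriggerEvent: clip %s, %s line, frame %d, area %.1f px^2\n",
              x$clipId, x$section, x$frameIndex, x$contourAreaPx2))
  invisible(x)
}

#' Run the soft trigger at both finishing lines
#'
#' Segments and gates the clip independently at the narrow and wide finishing
#' lines; at most one event per section is reported (the first qualifying
#' frame wins; later crossings are ignored).
#'
#' @param clip a [ClipRecording-class]
#' @param config a [DetectionConfig-class]
#' @return list with elements `narrow` and `wide`, each a `TriggerEvent` or
#'   `NULL` when the cell never qualifies at that line
#' @examples
#' st <- generateStudy(1, 0, 1, seed = 3)
#' ev <- detectTriggers(st$clips[[1]])
#' ev$narrow$frameIndex <= ev$wide$frameIndex
#' @export
detectTriggers <- function(clip, config = detectionConfig()) {
  out <- list()
  for (section in c("narrow", "wide")) {
    fg <- segmentForeground(clip, config, section)
    out[[section]] <- findTriggerFrame(fg, config, section,
                                       clipId = clip@meta$clipId)
  }
  out
}

#' Ground-truth trigger oracle
#'
#' Brute-force reference for the soft trigger: using the generator's
#' ground-truth masks (not the segmentation), finds the first frame whose
#' mask, restricted to the detection window, encloses a contour area
#' strictly greater than the gate. On noise-free clips the soft trigger must
#' agree with this exactly.
#'
#' @param clip a synthetic [ClipRecording-class] with ground truth
#' @param config a [DetectionConfig-class]
#' @param section "narrow" or "wide"
#' @param areaFun function(mask matrix) -> enclosed contour area; defaults to
#'   the package's tracer, and tests substitute an independent one
#' @return 1-based frame index, or `NA` when no frame qualifies
#' @export
triggerOracle <- function(clip, config = detectionConfig(),
                          section = c("narrow", "wide"),
                          areaFun = NULL) {
  section <- match.arg(section)
  truth <- groundTruth(clip)
  if (!length(truth)) stop("clip has no ground truth")
  win <- detect_window(clip, config, section)
  m <- truth$masks
  sub <- m[win$y0:win$y1 + 1L, win$x0:win$x1 + 1L, , drop = FALSE]
  if (is.null(areaFun)) {
    stats <- cpp_contour_stats(as.raw(sub), dim(sub))
    areas <- stats[, 1]
  } else {
    areas <- vapply(seq_len(dim(sub)[3]), function(t) {
      areaFun(matrix(as.integer(sub[, , t]), nrow = dim(sub)[1]))
    }, numeric(1))
  }
  hit <- which(areas > config@minContourAreaPx2)
  if (!length(hit)) NA_integer_ else hit[1]
}
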