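#' Process a list of clips into a CellCropSet
#'
#' Runs the soft trigger and background subtraction on every clip and stacks
#' the resulting per-section crops.
#'
#' @param clips list of [ClipRecording-class]
#' @param config a [DetectionConfig-class]
#' @param crop a [CropSpec-class]
#' @return a [CellCropSet-class] (narrow and wide crops interleaved per clip)
#' @export
studyCrops <- function(clips, config = detectionConfig(),
                       crop = cropSpec()) {
  arrs <- list()
  rows <- list()
  for (clip in clips) {
    cs <- processClip(clip, config, crop)
    for (section in names(cs)) {
      ev <- attr(cs[[section]], "event")
      arrs[[length(arrs) + 1]] <- cs[[section]]
      rows[[length(rows) + 1]] <- data.frame(
        clipId = clip@meta$clipId %||% NA_character_,
        section = section, label = clipLabel(clip),
        triggerFrame = ev$frameIndex,
        blurSigma = clip@meta$blurSigma %||% NA_real_,
        stiffness = clip@meta$stiffness %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  cellCropSet(arrs, do.call(rbind, rows) %||%
                data.frame(clipId = character(0), section = character(0),
                           label = character(0)))
}

#' Rendered-shape separation between the two classes
#'
#' Distance between the class-mean crops in units of the pixel-noise
#' standard deviation: the maximum absolute difference between the mean
#' native and mean modified crop, divided by `noiseSigma`. Values well above
#' 5 indicate that the rendered shape difference dominates the noise floor.
#'
#' @param crops a labelled [CellCropSet-class]
#' @param noiseSigma pixel noise sd of the generating study (8-bit units)
#' @return separation in noise sigmas
#' @export
shapeSeparation <- function(crops, noiseSigma) {
  info <- cropInfo(crops)
  px <- cropPixels(crops)
  mN <- apply(px[, , , info$label == "native", drop = FALSE], 1:3, mean)
  mM <- apply(px[, , , info$label == "modified", drop = FALSE], 1:3, mean)
  max(abs(mN - mM)) / noiseSigma
}

#' Full synthetic-twin classification experiment
#'
#' The package's end-to-end protocol on generated data: render a two-
#' population study, run the soft trigger and background splicing/
#' subtraction at both finishing lines, hold out a balanced clip-level test
#' set, train one classifier per channel section on the remaining clips
#' (shuffled 80/20 train/validation split, 10 epochs, batch 32) and evaluate
#' on the held-out crops.
#'
#' Clips are processed in a streaming fashion, so studies of many hundreds of
#' clips fit comfortably in memory.
#'
#' @param seed integer seed governing the whole experiment
#' @param nPerClass clips generated per class
#' @param nTestPerClass clips per class held out for testing (balanced test
#'   set of `2 * nTestPerClass` crops per section)
#' @param geometry,render,detection,crop,pop pipeline configuration
#' @param spec a [ClassifierSpec-class]; its seed is re-derived from `seed`
#' @param sections channel sections to train/evaluate
#' @return list with one element per section, each containing `evaluation`
#'   (an [EvaluationReport-class]), `report` (a [TrainingReport-class]) and
#'   `accuracy`; plus `table` (per-clip parameters) and `separation`
#'   (rendered-shape separation of the test crops, in noise sigmas)
#' @examples
#' \donttest{
#' res <- twinExperiment(seed = 1, nPerClass = 12, nTestPerClass = 4)
#' res$narrow$accuracy
#' }
#' @export
twinExperiment <- function(seed, nPerClass = 160L, nTestPerClass = 100L,
                           geometry = channelGeometry(),
                           render = renderConfig(),
                           detection = detectionConfig(),
                           crop = cropSpec(),
                           pop = populationParams(),
                           spec = classifierSpec(),
                           sections = c("narrow", "wide")) {
  stopifnot(nTestPerClass < nPerClass)
  n <- 2L * nPerClass
  d <- c(crop@height, crop@width, 3L)
  pxN <- if ("narrow" %in% sections) array(0, c(d, n))
  pxW <- if ("wide" %in% sections) array(0, c(d, n))
  rowsN <- vector("list", n)
  rowsW <- vector("list", n)
  kN <- 0L
  kW <- 0L

  crop_row <- function(row, s, ev) {
    data.frame(clipId = row$clipId, section = s, label = row$label,
               triggerFrame = ev$frameIndex, blurSigma = row$blurSigma,
               stiffness = row$stiffness, stringsAsFactors = FALSE)
  }
  collect <- function(clip, row) {
    cs <- processClip(clip, detection, crop)
    if (!is.null(cs$narrow) && "narrow" %in% sections) {
      kN <<- kN + 1L
      pxN[, , , kN] <<- cs$narrow
      rowsN[[kN]] <<- crop_row(row, "narrow", attr(cs$narrow, "event"))
    }
    if (!is.null(cs$wide) && "wide" %in% sections) {
      kW <<- kW + 1L
      pxW[, , , kW] <<- cs$wide
      rowsW[[kW]] <<- crop_row(row, "wide", attr(cs$wide, "event"))
    }
  }

  study <- generateStudy(1L, 1L, nPerClass, geometry, render, detection,
                         pop, seed = seed, callback = collect)

  out <- list(table = study$table)
  for (s in sections) {
    k <- if (s == "narrow") kN else kW
    info <- do.call(rbind, (if (s == "narrow") rowsN else rowsW)[seq_len(k)])
    px <- (if (s == "narrow") pxN else pxW)[, , , seq_len(k), drop = FALSE]
    crops <- new("CellCropSet", pixels = px, info = info)

    # balanced clip-level split: the last nTestPerClass clips of each class
    # (generation order is independent of the drawn cell parameters)
    byClass <- split(seq_len(nrow(info)), info$label)
    testIdx <- sort(unlist(lapply(byClass, function(ix)
      utils::tail(ix, nTestPerClass))))
    trainIdx <- setdiff(seq_len(nrow(info)), testIdx)

    specS <- spec
    specS@seed <- as.integer((seed * 131L + match(s, sections)) %% 2147483647L)
    ds <- assembleDataset(crops[trainIdx], seed = specS@seed,
                          valFraction = spec@valFraction)
    fit <- trainClassifier(specS, ds)
    ev <- evaluateClassifier(fit$classifier, crops[testIdx])
    out[[s]] <- list(evaluation = ev, report = fit$report,
                     accuracy = accuracy(ev),
                     classifier = fit$classifier)
    if (s == sections[1])
      out$separation <- shapeSeparation(crops[testIdx], render@noiseSigma)
  }
  out
}

#' Background-only crop sets for the confound audit
#'
#' Generates a study and extracts crops that contain no cell, labelled with
#' their clip's class. Two variants are produced per clip:
#' with `subtract = TRUE` the full pipeline is applied (spliced background
#' subtracted from an early cell-free frame); with `subtract = FALSE` the raw
#' cell-free crop is returned — pairing the latter with `confoundBlur = TRUE`
#' (focal blur drawn as a deterministic function of the class) reconstructs
#' the failure mode the audit is designed to detect.
#'
#' @param nPerClass clips per class
#' @param seed integer seed
#' @param subtract apply background splicing/subtraction
#' @param confoundBlur make the focal-blur level depend on the label
#'   (native in focus, modified defocused) instead of being mixed
#' @param geometry,render,detection,crop,pop pipeline configuration
#' @param section finishing line whose crop region is used
#' @return a labelled [CellCropSet-class] of background-only crops
#' @export
backgroundCrops <- function(nPerClass, seed = 1L, subtract = TRUE,
                            confoundBlur = FALSE,
                            geometry = channelGeometry(),
                            render = renderConfig(),
                            detection = detectionConfig(),
                            crop = cropSpec(),
                            pop = populationParams(),
                            section = "narrow") {
  if (confoundBlur) pop$blurLevels <- 0  # overridden per class below
  line <- switch(section, narrow = detection@finishLineNarrowPx,
                 wide = detection@finishLineWidePx)
  arrs <- vector("list", 2L * nPerClass)
  rows <- vector("list", 2L * nPerClass)
  k <- 0L
  collect <- function(clip, row) {
    k <<- k + 1L
    # frame 1 is guaranteed cell-free inside the crop region
    raw1 <- cropFrame(clip, 1L, line, crop)
    px <- if (subtract)
      subtractBackground(raw1, buildBackground(clip, line, crop))
    else raw1
    arrs[[k]] <<- px
    rows[[k]] <<- data.frame(clipId = row$clipId, section = section,
                             label = row$label, triggerFrame = 1L,
                             blurSigma = clip@meta$blurSigma,
                             stiffness = row$stiffness,
                             stringsAsFactors = FALSE)
  }
  if (confoundBlur) {
    # render the two classes separately with class-specific blur
    tabs <- list()
    for (cls in c("native", "modified")) {
      popC <- pop
      popC$blurLevels <- if (cls == "native") 0 else 1.5
      nb <- if (cls == "native") c(1L, 0L) else c(0L, 1L)
      st <- generateStudy(nb[1], nb[2], nPerClass, geometry, render,
                          detection, popC,
                          seed = seed + match(cls, label_levels),
                          callback = collect)
      tabs[[cls]] <- st$table
    }
  } else {
    generateStudy(1L, 1L, nPerClass, geometry, render, detection, pop,
                  seed = seed, callback = collect)
  }
  cellCropSet(arrs[seq_len(k)], do.call(rbind, rows[seq_len(k)]))
}
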