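frames_to_list <- function(clip) {
  d <- clip@dims
  arr <- frames(clip) / 255
  lapply(seq_len(d[4]), function(t) arr[, , , t])
}

list_to_raw <- function(imgs) {
  d1 <- dim(imgs[[1]])
  h <- d1[1]; w <- d1[2]
  out <- raw(h * w * 3 * length(imgs))
  npf <- h * w * 3
  for (t in seq_along(imgs)) {
    img <- imgs[[t]]
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(h, w, 3))
    if (dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
    if (dim(img)[3] == 1) img <- array(rep(img, 3), c(h, w, 3))
    if (!identical(dim(img)[1:2], d1[1:2]))
      stop("frame ", t, " has inconsistent size")
    out[(t - 1) * npf + seq_len(npf)] <-
      as.raw(pmin(pmax(round(img * 255), 0), 255))
  }
  list(frames = out, dims = c(h, w, 3L, length(imgs)))
}

#' Write a clip to disk
#'
#' Multi-page TIFF (one page per frame) or a directory of numbered PNG
#' frames; both dialects are 8-bit, 3-channel.
#'
#' @param clip a [ClipRecording-class]
#' @param path output file (`.tif`/`.tiff`) or directory (PNG dialect)
#' @param format "tiff" or "png"; inferred from `path` by default
#' @return `path`, invisibly
#' @export
writeClip <- function(clip, path, format = c("auto", "tiff", "png")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  imgs <- frames_to_list(clip)
  if (format == "tiff") {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_along(imgs))
      png::writePNG(imgs[[t]], file.path(path, sprintf("frame%04d.png", t)))
  }
  invisible(path)
}

#' Read a clip from disk
#'
#' Accepts a multi-page TIFF or a directory of numbered PNG frames; frame
#' order is preserved, grayscale input is promoted to 3 channels by
#' replication.
#'
#' @param path clip file or frame directory
#' @param meta optional metadata list stored on the clip
#' @return a [ClipRecording-class] (without ground truth)
#' @export
readClip <- function(path, meta = list()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path)
    imgs <- lapply(files, png::readPNG)
  } else {
    if (!file.exists(path)) stop("clip not found: ", path)
    imgs <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop("failed to read TIFF clip ", path, ": ",
                            conditionMessage(e)))
    if (!is.list(imgs)) imgs <- list(imgs)
  }
  rawdat <- list_to_raw(imgs)
  new("ClipRecording", frames = rawdat$frames,
      dims = as.integer(rawdat$dims), meta = meta, truth = list())
}

#' Write a generated study to disk
#'
#' One TIFF clip per sequence plus a manifest CSV (clip id, path, label,
#' batch, frames per sequence, finishing lines, blur sigma, stiffness) and a
#' clean-background PNG per clip.
#'
#' @param study result of [generateStudy()] (with clips kept)
#' @param dir output directory
#' @param detection a [DetectionConfig-class] providing the finishing lines
#'   recorded in the manifest
#' @return path of the manifest CSV, invisibly
#' @export
writeStudy <- function(study, dir, detection = detectionConfig()) {
  if (is.null(study$clips)) stop("study was generated in streaming mode")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- study$table
  tab$path <- file.path(dir, paste0(tab$clipId, ".tif"))
  tab$frames_per_sequence <-
    vapply(study$clips, nFrames, integer(1))
  tab$finish_line_narrow_px <- detection@finishLineNarrowPx
  tab$finish_line_wide_px <- detection@finishLineWidePx
  for (i in seq_along(study$clips)) {
    clip <- study$clips[[i]]
    writeClip(clip, tab$path[i], format = "tiff")
    truth <- groundTruth(clip)
    if (length(truth)) {
      bg <- array(as.integer(truth$clean), clip@dims[c(1, 2, 3)]) / 255
      png::writePNG(bg, file.path(dir, paste0(tab$clipId[i], "_bg.png")))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(tab, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a study manifest and its clips
#'
#' @param manifest path to a manifest CSV written by [writeStudy()] (or of
#'   the same shape for real recordings)
#' @return list with `clips` (list of [ClipRecording-class]) and `table`
#' @export
readStudy <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("clipId", "path", "label")
  if (!all(need %in% names(tab)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$clipId))
    stop("duplicate clip ids in manifest")
  base <- dirname(manifest)
  clips <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$path[i]
    if (!file.exists(p) && !dir.exists(p)) {
      p2 <- file.path(base, basename(p))
      if (!file.exists(p2) && !dir.exists(p2))
        stop("manifest row ", i, " (", tab$clipId[i],
             "): clip path not found: ", tab$path[i])
      p <- p2
    }
    clips[[i]] <- readClip(p, meta = list(clipId = tab$clipId[i],
                                          label = tab$label[i]))
    clips[[i]]@meta$blurSigma <- if ("blurSigma" %in% names(tab))
      tab$blurSigma[i] else NA_real_
    clips[[i]]@meta$stiffness <- if ("stiffness" %in% names(tab))
      tab$stiffness[i] else NA_real_
  }
  list(clips = clips, table = tab)
}

#' Write a crop set as PNG files plus a manifest
#'
#' @param crops a [CellCropSet-class]
#' @param dir output directory
#' @return path of the manifest CSV, invisibly
#' @export
writeCrops <- function(crops, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- cropInfo(crops)
  px <- cropPixels(crops)
  info$path <- file.path(dir, sprintf("%s_%s.png", info$clipId, info$section))
  for (i in seq_len(nrow(info)))
    png::writePNG(pmin(px[, , , i] / 255, 1), info$path[i])
  manifest <- file.path(dir, "crops.csv")
  write.csv(info, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a crop set written by [writeCrops()]
#'
#' @param manifest path to the crop manifest CSV
#' @return a [CellCropSet-class]
#' @export
readCrops <- function(manifest) {
  info <- read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  arrs <- lapply(seq_len(nrow(info)), function(i) {
    p <- info$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img * 255
  })
  info$path <- NULL
  cellCropSet(arrs, info)
}

#' Write trigger events to CSV
#'
#' @param events list of `TriggerEvent`s (NULLs are dropped)
#' @param path output CSV
#' @return the events as a data.frame, invisibly
#' @export
writeEvents <- function(events, path) {
  events <- Filter(Negate(is.null), events)
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(clipId = e$clipId, section = e$section,
               frameIndex = e$frameIndex, areaPx2 = e$contourAreaPx2,
               bboxX0 = e$contourBbox[1], bboxY0 = e$contourBbox[2],
               bboxX1 = e$contourBbox[3], bboxY1 = e$contourBbox[4],
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(clipId = character(0), section = character(0),
                     frameIndex = integer(0), areaPx2 = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Pipeline configuration document
#'
#' One YAML-serialisable document holding every stage's parameters; it
#' round-trips losslessly through [writePipelineConfig()] /
#' [readPipelineConfig()] and is copied into every pipeline output directory.
#'
#' @param geometry,render,detection,crop,classifier,pop stage configurations
#' @param study list(nBatchesNative, nBatchesModified, sequencesPerBatch,
#'   nTestPerClass)
#' @param seed master seed
#' @return a named list of class `pipelineConfig`
#' @export
pipelineConfig <- function(geometry = channelGeometry(),
                           render = renderConfig(),
                           detection = detectionConfig(),
                           crop = cropSpec(),
                           classifier = classifierSpec(),
                           pop = populationParams(),
                           study = list(nBatchesNative = 1L,
                                        nBatchesModified = 1L,
                                        sequencesPerBatch = 40L,
                                        nTestPerClass = 10L),
                           seed = 1L) {
  structure(list(geometry = s4_to_list(geometry),
                 render = s4_to_list(render),
                 detection = s4_to_list(detection),
                 crop = s4_to_list(crop),
                 classifier = s4_to_list(classifier),
                 pop = pop, study = study, seed = seed),
            class = "pipelineConfig")
}

s4_to_list <- function(obj) {
  out <- lapply(slotNames(obj), function(s) slot(obj, s))
  names(out) <- slotNames(obj)
  out
}

list_to_s4 <- function(lst, class, intSlots) {
  for (s in intSlots) lst[[s]] <- as.integer(lst[[s]])
  do.call(new, c(list(class), lst))
}

config_objects <- function(cfg) {
  list(
    geometry = list_to_s4(cfg$geometry, "ChannelGeometry", character(0)),
    render = list_to_s4(cfg$render, "RenderConfig",
                        c("frameSizePx", "framesPerSequence",
                          "backgroundTextureSeed", "rngSeed")),
    detection = list_to_s4(cfg$detection, "DetectionConfig",
                           c("finishLineNarrowPx", "finishLineWidePx",
                             "detectYRange", "detectXExtent",
                             "segmentationHistory", "nModes")),
    crop = list_to_s4(cfg$crop, "CropSpec",
                      c("yStart", "height", "width", "xBeforePx", "xAfterPx",
                        "spliceCol", "nEdgeFrames")),
    classifier = list_to_s4(cfg$classifier, "ClassifierSpec",
                            c("inputShape", "conv1Filters", "conv2Filters",
                              "kernel", "stride", "poolSize", "denseUnits",
                              "nClasses", "epochs", "batchSize", "seed")),
    pop = do.call(populationParams, lapply(cfg$pop, unlist)),
    study = cfg$study, seed = cfg$seed)
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`
#' @param path YAML file path
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  structure(yaml::read_yaml(path), class = "pipelineConfig")
}
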