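#' Channel opening profile in pixels
#'
#' Width of the channel opening at every x-coordinate of a rendered frame.
#' The wall profile interpolates triangularly (zigzag) between the narrow and
#' wide openings with the geometry's period; `phasePx` is the x-coordinate of
#' a narrow section.
#'
#' @param geometry a [ChannelGeometry-class]
#' @param widthPx frame width in pixels
#' @param phasePx x-coordinate (0-based px) of a narrowest point; by default
#'   1.5 periods into the frame
#' @return numeric vector of channel opening widths (px), one per column
#' @examples
#' w <- channelProfile(channelGeometry(), 460L)
#' range(w)  # 50 (narrow, 10 um) to 100 (wide, 20 um) at 5 px/um
#' @export
channelProfile <- function(geometry, widthPx,
                           phasePx = 1.5 * periodPx(geometry)) {
  stopifnot(is(geometry, "ChannelGeometry"))
  p <- periodPx(geometry)
  x <- seq_len(widthPx) - 1
  tri <- tri_wave(x - phasePx, p)  # 0 at narrow sections, 1 at wide
  (geometry@narrowWidthUm +
     (geometry@wideWidthUm - geometry@narrowWidthUm) * tri) * geometry@pxPerUm
}

# triangle wave: 0 at multiples of the period, 1 at half-periods; the
# modulo form keeps exactly periodic values for integer-valued inputs
tri_wave <- function(d, period) {
  r <- d %% period
  1 - abs(r - period / 2) / (period / 2)
}

#' Binary interior mask of the zigzag channel
#'
#' Renders the channel interior as a logical matrix. The vertical opening at
#' column x spans exactly `channelProfile(...)` rows, centred on `centerY`,
#' so the opening alternates between `narrowWidthUm * pxPerUm` and
#' `wideWidthUm * pxPerUm` pixels with the stated period.
#'
#' @param geometry a [ChannelGeometry-class]
#' @param frameSizePx integer (height, width) of the mask
#' @param phasePx x-coordinate of a narrowest point (see [channelProfile()])
#' @param centerY channel centreline (default: frame height / 2)
#' @return logical matrix (height x width); `TRUE` inside the channel
#' @examples
#' m <- channelMask(channelGeometry(pxPerUm = 10), c(256L, 400L))
#' range(colSums(m))  # 100 and 200 px openings
#' @export
channelMask <- function(geometry, frameSizePx,
                        phasePx = 1.5 * periodPx(geometry),
                        centerY = frameSizePx[1] / 2) {
  stopifnot(is(geometry, "ChannelGeometry"))
  h <- as.integer(frameSizePx[1]); w <- as.integer(frameSizePx[2])
  if (w < periodPx(geometry))
    stop("frame width (", w, " px) is smaller than one channel period (",
         periodPx(geometry), " px)")
  prof <- channelProfile(geometry, w, phasePx)
  if (h < max(prof))
    stop("frame height (", h, " px) cannot contain the wide opening (",
         max(prof), " px)")
  y <- seq_len(h) - 1
  # half-open band [centerY - w/2, centerY + w/2): exactly `prof` rows
  outer(y, prof, function(yy, pp) yy >= centerY - pp / 2 & yy < centerY + pp / 2)
}

#' Simulate a cell trajectory through the channel
#'
#' The centroid advances `speedUmPerFrame * pxPerUm` pixels per frame along
#' the channel axis at a fixed lateral position. The blob's elongation `e`
#' relaxes towards a target that mixes the rest shape (weight `stiffness`)
#' with the shape dictated by the local channel width (weight
#' `1 - stiffness`): the width-dictated target is
#' `wideWidthUm / localWidthUm`, i.e. 1 in wide sections and 2 in narrow
#' sections for the default geometry. The relaxation is first order with lag
#' `relaxationFrames`; the rendered semi-axes are `a = r * sqrt(e)` (flow
#' direction) and `b = r / sqrt(e)` (area-preserving elongation).
#'
#' @param cell a [CellModel-class]
#' @param geometry a [ChannelGeometry-class]
#' @param nFrames number of frames (>= 1)
#' @param phasePx x-coordinate of a narrowest point (see [channelProfile()])
#' @param centerY channel centreline in px
#' @return matrix `nFrames` x 5 with columns cx, cy, a, b, e (px, 0-based)
#' @examples
#' cell <- cellModel(stiffness = 0, relaxationFrames = 0)
#' tr <- simulateTrajectory(cell, channelGeometry(), 10L)
#' tr[1:3, ]
#' @export
simulateTrajectory <- function(cell, geometry, nFrames,
                               phasePx = 1.5 * periodPx(geometry),
                               centerY = 60) {
  stopifnot(is(cell, "CellModel"), is(geometry, "ChannelGeometry"),
            nFrames >= 1)
  pxv <- cell@speedUmPerFrame * geometry@pxPerUm
  r <- cell@radiusUm * geometry@pxPerUm
  p <- periodPx(geometry)
  k <- if (cell@relaxationFrames > 0) 1 - exp(-1 / cell@relaxationFrames) else 1
  out <- matrix(0, nFrames, 5,
                dimnames = list(NULL, c("cx", "cy", "a", "b", "e")))
  e <- NA_real_
  for (t in seq_len(nFrames)) {
    cx <- cell@startXPx + (t - 1) * pxv
    localW <- geometry@narrowWidthUm +
      (geometry@wideWidthUm - geometry@narrowWidthUm) * tri_wave(cx - phasePx, p)
    target <- cell@stiffness * 1 + (1 - cell@stiffness) *
      (geometry@wideWidthUm / localW)
    e <- if (is.na(e)) target else e + k * (target - e)
    out[t, ] <- c(cx, centerY + cell@yOffsetPx, r * sqrt(e), r / sqrt(e), e)
  }
  out
}

#' Render a synthetic clip
#'
#' Composites a static textured background (low-frequency filtered noise,
#' darker outside the channel walls), a hard-edged superellipse cell blob
#' following `trajectory`, optional Gaussian defocus of background and cell,
#' and per-pixel Gaussian noise. Identical seeds give bit-identical frames.
#' Ground truth (pre-blur cell masks, clean background, centroids) is stored
#' in the returned clip.
#'
#' @param trajectory matrix from [simulateTrajectory()]
#' @param geometry a [ChannelGeometry-class]
#' @param render a [RenderConfig-class]
#' @param cell the [CellModel-class] that produced `trajectory` (provides
#'   the contrast); its metadata is recorded in the clip
#' @param label "native", "modified" or NA
#' @param clipId identifier string
#' @param phasePx,centerY channel placement (as in [simulateTrajectory()])
#' @param blobExp superellipse exponent of the blob outline (2 = ellipse)
#' @param cellRgbScale per-channel scaling of the cell contrast (fluorescent
#'   green by default)
#' @return a [ClipRecording-class] with ground truth
#' @examples
#' geom <- channelGeometry()
#' cell <- cellModel(startXPx = 40)
#' tr <- simulateTrajectory(cell, geom, 12L)
#' clip <- renderClip(tr, geom, renderConfig(framesPerSequence = 12L), cell)
#' clip
#' @export
renderClip <- function(trajectory, geometry, render, cell,
                       label = NA_character_, clipId = "clip",
                       phasePx = 1.5 * periodPx(geometry),
                       centerY = render@frameSizePx[1] / 2,
                       blobExp = 2.5,
                       cellRgbScale = c(0.35, 1, 0.45)) {
  stopifnot(is(render, "RenderConfig"))
  if (nrow(trajectory) != render@framesPerSequence)
    stop("trajectory length must equal framesPerSequence")
  h <- render@frameSizePx[1]; w <- render@frameSizePx[2]
  halfw <- channelProfile(geometry, w, phasePx) / 2
  res <- cpp_render_clip(h, w, trajectory[, 1:4, drop = FALSE], blobExp,
                         cell@contrast * cellRgbScale, halfw, centerY,
                         wall_atten = 0.45, tex_base = 70, tex_amp = 12,
                         tex_scale_px = 24,
                         tex_seed = render@backgroundTextureSeed,
                         noise_sigma = render@noiseSigma,
                         blur_sigma = render@focalBlurSigma,
                         noise_seed = render@rngSeed)
  dims <- c(h, w, 3L, render@framesPerSequence)
  masks <- res$masks
  dim(masks) <- dims[-3]
  new("ClipRecording", frames = res$frames, dims = as.integer(dims),
      meta = list(clipId = clipId, label = label,
                  blurSigma = render@focalBlurSigma,
                  noiseSigma = render@noiseSigma,
                  stiffness = cell@stiffness,
                  speedUmPerFrame = cell@speedUmPerFrame,
                  relaxationFrames = cell@relaxationFrames,
                  phasePx = phasePx, centerY = centerY),
      truth = list(masks = masks, clean = res$clean,
                   centroids = trajectory[, 1:2, drop = FALSE],
                   shape = trajectory[, 3:4, drop = FALSE]))
}

#' Population parameters of the two cell classes
#'
#' Defaults encode the study conditions the generator emulates: native cells
#' are compliant (stiffness ~ 0.2), chemically stiffened cells are rigid
#' (stiffness ~ 0.8); speeds correspond to the measured 5.1 +/- 2.0 mm/s at
#' the recording frame rate, truncated so that each cell traverses both
#' finishing lines within one sequence; the focal-blur level of a clip is
#' drawn independently of its label (the confound-mixing control).
#'
#' @param stiffnessMean,stiffnessSd per-class normal parameters (truncated to
#'   [0, 1]); length-2 vectors ordered (native, modified)
#' @param relaxationFrames shape-relaxation lag per class (frames)
#' @param radiusMeanUm,radiusSdUm blob rest radius distribution (um)
#' @param speedMean,speedSd,speedRange advection speed (um/frame)
#' @param blurLevels focal-blur sigmas sampled uniformly per clip (px)
#' @param contrast cell peak contrast (8-bit units)
#' @return a named list of population parameters
#' @export
populationParams <- function(stiffnessMean = c(0.2, 0.8),
                             stiffnessSd = c(0.06, 0.06),
                             relaxationFrames = c(6, 6),
                             radiusMeanUm = 3.5, radiusSdUm = 0.25,
                             speedMean = 2.55, speedSd = 0.4,
                             speedRange = c(1.7, 3.4),
                             blurLevels = c(0, 0.6, 1.2),
                             contrast = 120) {
  list(stiffnessMean = unname(stiffnessMean), stiffnessSd = stiffnessSd,
       relaxationFrames = relaxationFrames, radiusMeanUm = radiusMeanUm,
       radiusSdUm = radiusSdUm, speedMean = speedMean, speedSd = speedSd,
       speedRange = speedRange, blurLevels = blurLevels, contrast = contrast)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Draw per-clip cell and imaging parameters for a study
#'
#' Samples every per-clip quantity (stiffness, speed, radius, lateral offset,
#' focal blur, texture and noise seeds) for a batch-structured study without
#' rendering any pixels. Used by [generateStudy()] and useful on its own for
#' cheap metadata-level checks (e.g. that blur is uncorrelated with label).
#'
#' @param nBatchesNative,nBatchesModified number of batches per class
#' @param sequencesPerBatch clips per batch
#' @param pop population parameters from [populationParams()]
#' @param seed integer seed
#' @return data.frame with one row per clip: clipId, batch, label,
#'   stiffness, speedUmPerFrame, radiusUm, relaxationFrames, yOffsetPx,
#'   blurSigma, textureSeed, noiseSeed
#' @examples
#' tab <- samplePopulation(1, 1, 10, seed = 1)
#' table(tab$label)
#' @export
samplePopulation <- function(nBatchesNative, nBatchesModified,
                             sequencesPerBatch, pop = populationParams(),
                             seed = 1L) {
  nN <- nBatchesNative * sequencesPerBatch
  nM <- nBatchesModified * sequencesPerBatch
  n <- nN + nM
  with_seed(seed, {
    lab <- rep(c("native", "modified"), c(nN, nM))
    cls <- ifelse(lab == "native", 1L, 2L)
    data.frame(
      clipId = sprintf("clip%05d", seq_len(n)),
      batch = c(rep(seq_len(max(nBatchesNative, 1)), each = sequencesPerBatch,
                    length.out = nN),
                rep(seq_len(max(nBatchesModified, 1)),
                    each = sequencesPerBatch, length.out = nM) +
                  nBatchesNative),
      label = lab,
      stiffness = rtrunc_norm(n, pop$stiffnessMean[cls],
                              pop$stiffnessSd[cls], 0, 1),
      speedUmPerFrame = rtrunc_norm(n, pop$speedMean, pop$speedSd,
                                    pop$speedRange[1], pop$speedRange[2]),
      radiusUm = rtrunc_norm(n, pop$radiusMeanUm, pop$radiusSdUm,
                             pop$radiusMeanUm - 3 * pop$radiusSdUm,
                             pop$radiusMeanUm + 3 * pop$radiusSdUm),
      relaxationFrames = pop$relaxationFrames[cls],
      yOffsetPx = runif(n, -4, 4),
      blurSigma = sample(pop$blurLevels, n, replace = TRUE),
      textureSeed = draw_seed(n),
      noiseSeed = draw_seed(n),
      stringsAsFactors = FALSE
    )
  })
}

# start position such that the blob is outside the narrow-line crop window in
# the first frames and beyond the wide-line crop window in the last ones
study_start_x <- function(radiusPx, speedPx, cropMinX) {
  cropMinX - radiusPx - 4 - 2 * speedPx
}

#' Generate a seeded synthetic study
#'
#' Renders one clip per sequence for a batch-structured two-population study.
#' Per-cell stiffness and speed are drawn from class-specific distributions;
#' the per-clip focal-blur sigma is drawn independently of the label. Cells
#' start left of the narrow-line crop window and cross both finishing lines,
#' so the first and last frames of each clip are cell-free inside the crop
#' regions and the background splice is exact. Fully reproducible for a given
#' seed.
#'
#' @param nBatchesNative,nBatchesModified,sequencesPerBatch study structure
#' @param geometry a [ChannelGeometry-class]
#' @param render a [RenderConfig-class] (per-clip seeds and blur are
#'   overridden from the sampled population table)
#' @param detection a [DetectionConfig-class]; used only to place the cells
#'   relative to the finishing lines
#' @param pop population parameters from [populationParams()]
#' @param seed integer seed
#' @param callback optional `function(clip, row)` invoked per rendered clip;
#'   when given, clips are not accumulated (streaming mode) and only the
#'   population table is returned
#' @return a list with elements `clips` (list of [ClipRecording-class], or
#'   NULL in streaming mode) and `table` (the population data.frame)
#' @examples
#' st <- generateStudy(1, 1, 2, seed = 42,
#'                     render = renderConfig(framesPerSequence = 30L))
#' length(st$clips)
#' @export
generateStudy <- function(nBatchesNative, nBatchesModified, sequencesPerBatch,
                          geometry = channelGeometry(),
                          render = renderConfig(),
                          detection = detectionConfig(),
                          pop = populationParams(), seed = 1L,
                          callback = NULL) {
  stopifnot(sequencesPerBatch >= 1)
  tab <- samplePopulation(nBatchesNative, nBatchesModified, sequencesPerBatch,
                          pop, seed)
  crop <- cropSpec()
  cropMinX <- detection@finishLineNarrowPx - crop@xBeforePx
  keep <- is.null(callback)
  clips <- if (keep) vector("list", nrow(tab)) else NULL
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    cell <- cellModel(radiusUm = row$radiusUm, stiffness = row$stiffness,
                      relaxationFrames = row$relaxationFrames,
                      speedUmPerFrame = row$speedUmPerFrame,
                      contrast = pop$contrast,
                      startXPx = study_start_x(
                        row$radiusUm * geometry@pxPerUm,
                        row$speedUmPerFrame * geometry@pxPerUm, cropMinX),
                      yOffsetPx = row$yOffsetPx)
    rc <- new("RenderConfig", frameSizePx = render@frameSizePx,
              framesPerSequence = render@framesPerSequence,
              noiseSigma = render@noiseSigma,
              backgroundTextureSeed = as.integer(row$textureSeed),
              focalBlurSigma = row$blurSigma,
              rngSeed = as.integer(row$noiseSeed))
    tr <- simulateTrajectory(cell, geometry, rc@framesPerSequence,
                             centerY = rc@frameSizePx[1] / 2)
    clip <- renderClip(tr, geometry, rc, cell, label = row$label,
                       clipId = row$clipId,
                       centerY = rc@frameSizePx[1] / 2)
    if (keep) clips[[i]] <- clip else callback(clip, row)
  }
  list(clips = clips, table = tab)
}
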