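test_that("spliced background equals the clean background exactly when
           edge frames are cell-free and noise is off", {
  st <- clean_study(2, seed = 41)
  for (clip in st$clips) {
    clean <- array(as.integer(groundTruth(clip)$clean), clip@dims[1:3])
    for (line in c(150L, 200L)) {
      bg <- buildBackground(clip, line)
      expect_identical(dim(bg), c(120L, 150L, 3L))
      ref <- clean[1:120, (line - 80 + 1):(line + 70), , drop = FALSE]
      expect_equal(bg, array(as.numeric(ref), dim(bg)))
    }
  }
})

test_that("static clips make the background equal any frame crop", {
  geom <- channelGeometry()
  cell <- cellModel(startXPx = -500)
  rc <- renderConfig(framesPerSequence = 12L, noiseSigma = 0)
  clip <- renderClip(simulateTrajectory(cell, geom, 12L), geom, rc, cell)
  bg <- buildBackground(clip, 150L)
  expect_equal(bg, cropFrame(clip, 7L, 150L))
  # with no temporal variation the edge-frame count is irrelevant
  bg1 <- buildBackground(clip, 150L, cropSpec(nEdgeFrames = 1L))
  expect_equal(bg, bg1)
})

test_that("subtraction is |frame - background| with the mandated shape", {
  clip <- default_clip()
  bg <- buildBackground(clip, 150L)
  fr <- cropFrame(clip, 10L, 150L)
  out <- subtractBackground(fr, bg)
  expect_identical(dim(out), c(120L, 150L, 3L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  expect_equal(subtractBackground(bg, bg), array(0, dim(bg)))
  expect_error(subtractBackground(fr[1:60, , , drop = FALSE], bg), "shape")
})

test_that("subtracted energy concentrates on the ground-truth cell mask", {
  st <- clean_study(1, seed = 43)
  clip <- st$clips[[1]]
  ev <- detectTriggers(clip)$narrow
  px <- extractCellCrop(clip, ev)
  # ground-truth mask restricted to the crop, dilated by 3 px
  m <- groundTruth(clip)$masks[, , ev$frameIndex]
  m <- matrix(as.integer(m), nrow = dim(m)[1])
  crop_m <- m[1:120, (150 - 80 + 1):(150 + 70)]
  dil <- crop_m
  for (dx in -3:3) for (dy in -3:3) {
    sh <- crop_m
    sh <- sh[pmin(pmax(seq_len(120) + dy, 1), 120),
             pmin(pmax(seq_len(150) + dx, 1), 150)]
    dil <- pmax(dil, sh)
  }
  energy <- sum(px^2)
  inside <- sum((px * array(rep(dil, 3), dim(px)))^2)
  expect_gte(inside / energy, 0.9)
})

test_that("cell-free subtracted crops sit at the noise floor", {
  sigma <- 2
  st <- clean_study(1, seed = 44, noise = sigma)
  clip <- st$clips[[1]]
  bg <- buildBackground(clip, 150L)
  sub <- subtractBackground(cropFrame(clip, 1L, 150L), bg)  # frame 1: no cell
  expect_lte(mean(sub), 2 * sigma)
})

test_that("short clips are rejected", {
  geom <- channelGeometry()
  cell <- cellModel(speedUmPerFrame = 12, startXPx = 30)
  rc <- renderConfig(framesPerSequence = 6L, noiseSigma = 0)
  clip <- renderClip(simulateTrajectory(cell, geom, 6L), geom, rc, cell)
  expect_error(buildBackground(clip, 150L), "needs 10")
})
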