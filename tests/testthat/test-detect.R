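test_that("a static clip yields all-zero foreground after the first frame", {
  geom <- channelGeometry()
  cell <- cellModel(startXPx = -500)
  rc <- renderConfig(framesPerSequence = 6L, noiseSigma = 0)
  clip <- renderClip(simulateTrajectory(cell, geom, 6L), geom, rc, cell)
  fg <- segmentForeground(clip, detectionConfig(), "narrow")
  expect_equal(sum(as.integer(fg)), 0)
})

test_that("an extreme variance threshold suppresses all foreground", {
  clip <- default_clip()
  cfg <- detectionConfig(segmentationVarThreshold = 1e9)
  fg <- segmentForeground(clip, cfg, "narrow")
  expect_equal(sum(as.integer(fg)), 0)
  expect_null(findTriggerFrame(fg, cfg))
})

test_that("segmented foreground overlaps the ground-truth mask", {
  clip <- default_clip()
  cfg <- detectionConfig()
  fg <- segmentForeground(clip, cfg, "narrow")
  ev <- findTriggerFrame(fg, cfg, clipId = "x")
  t <- ev$frameIndex
  win <- attr(fg, "window")
  truth <- groundTruth(clip)$masks[win$y0:win$y1 + 1L,
                                   win$x0:win$x1 + 1L, t]
  a <- as.integer(fg[, , t]) > 0
  b <- as.integer(truth) > 0
  jaccard <- sum(a & b) / sum(a | b)
  expect_gte(jaccard, 0.5)
})

test_that("trigger frame equals the ground-truth crossing frame exactly on
           noise-free clips (independent contour oracle)", {
  skip_if_not_installed("EBImage")
  st <- clean_study(3, seed = 31)
  cfg <- detectionConfig()
  for (clip in st$clips) {
    for (section in c("narrow", "wide")) {
      fg <- segmentForeground(clip, cfg, section)
      ev <- findTriggerFrame(fg, cfg, section, clipId = "c")
      oracle <- triggerOracle(clip, cfg, section, areaFun = ebimage_area)
      expect_equal(ev$frameIndex, oracle)
    }
  }
})

test_that("contours below the area gate do not trigger", {
  # frame stack with one 4 x 4 square: enclosed polygon area 9 < 20
  m <- array(as.raw(0), c(40L, 40L, 3L))
  m[10:13, 10:13, 2] <- as.raw(1)
  stats <- zigzagRBC:::cpp_contour_stats(m, dim(m))
  expect_equal(stats[2, 1], 9)
  masks <- structure(m, window = list(x0 = 0L, x1 = 39L, y0 = 0L, y1 = 39L,
                                      line = 0L))
  expect_null(findTriggerFrame(masks, detectionConfig(), "narrow"))
  # a 7 x 7 square (area 36) does trigger, at its first frame
  m[10:16, 10:16, 3] <- as.raw(1)
  masks <- structure(m, window = list(x0 = 0L, x1 = 39L, y0 = 0L, y1 = 39L,
                                      line = 0L))
  ev <- findTriggerFrame(masks, detectionConfig(), "narrow")
  expect_equal(ev$frameIndex, 3L)
  expect_equal(ev$contourAreaPx2, 36)
})

test_that("contour area matches the EBImage polygon oracle on varied blobs", {
  skip_if_not_installed("EBImage")
  set.seed(42)
  for (i in 1:8) {
    m <- matrix(0L, 60, 60)
    cx <- runif(1, 15, 45); cy <- runif(1, 15, 45)
    a <- runif(1, 3, 12); b <- runif(1, 3, 12)
    m[(((col(m) - cx) / a)^2 + ((row(m) - cy) / b)^2) <= 1] <- 1L
    stk <- array(as.raw(m), c(60L, 60L, 1L))
    stats <- zigzagRBC:::cpp_contour_stats(stk, dim(stk))
    expect_equal(stats[1, 1], ebimage_area(m), tolerance = 1e-9)
  }
})

test_that("raising the area gate never lowers the trigger frame", {
  clip <- default_clip()
  frames_at <- vapply(c(20, 100, 400, 1000), function(thr) {
    cfg <- detectionConfig(minContourAreaPx2 = thr)
    ev <- findTriggerFrame(segmentForeground(clip, cfg, "narrow"), cfg)
    ev$frameIndex
  }, numeric(1))
  expect_true(all(diff(frames_at) >= 0))
})

test_that("both finishing lines fire in order; events carry valid geometry", {
  clip <- default_clip()
  ev <- detectTriggers(clip)
  expect_false(is.null(ev$narrow))
  expect_false(is.null(ev$wide))
  # narrow line sits upstream of the wide line in the default layout
  expect_lte(ev$narrow$frameIndex, ev$wide$frameIndex)
  for (e in ev) {
    expect_gt(e$contourAreaPx2, 20)
    expect_gte(e$contourBbox["x0"], 0)
  }
  # agreement with ground-truth centroid crossing times (within 2 frames)
  truth <- groundTruth(clip)
  cfg <- detectionConfig()
  crossN <- which(truth$centroids[, 1] + truth$shape[, 1] >=
                    cfg@finishLineNarrowPx)[1]
  expect_lte(abs(ev$narrow$frameIndex - crossN), 2)
})

test_that("trigger frames are robust to pixel noise", {
  cfg <- detectionConfig()
  n_ok <- 0L
  n <- 20L
  for (i in seq_len(n)) {
    st0 <- clean_study(1, seed = 500 + i, noise = 0, frames = 40L)
    ref <- detectTriggers(st0$clips[[1]], cfg)
    stN <- clean_study(1, seed = 500 + i, noise = 5, frames = 40L)
    noisy <- detectTriggers(stN$clips[[1]], cfg)
    if (!is.null(noisy$narrow) &&
        abs(noisy$narrow$frameIndex - ref$narrow$frameIndex) <= 2)
      n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("degenerate inputs are rejected", {
  clip <- default_clip()
  one <- new("ClipRecording",
             frames = clip@frames[seq_len(prod(clip@dims[1:3]))],
             dims = c(clip@dims[1:3], 1L), meta = list(), truth = list())
  expect_error(segmentForeground(one, detectionConfig(), "narrow"),
               "at least 2 frames")
  small <- detectionConfig(finishLineWidePx = 400L)
  expect_error(segmentForeground(clip, small, "wide"), "window")
})
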