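test_that("channel mask openings match the geometry at pixel scale", {
  # 10 px/um: narrow 10 um -> 100 px opening, wide 20 um -> 200 px
  m <- channelMask(channelGeometry(pxPerUm = 10), c(256L, 400L))
  op <- colSums(m)
  expect_equal(min(op), 100)
  expect_equal(max(op), 200)
  # periodicity: identical columns one period (200 px) apart
  expect_equal(m[, 1:200], m[, 201:400])
})

test_that("degenerate geometry gives a straight channel", {
  g <- channelGeometry(narrowWidthUm = 15, wideWidthUm = 15)
  m <- channelMask(g, c(200L, 220L))
  expect_equal(unname(range(colSums(m))), c(75, 75))
})

test_that("too-small frames are rejected with an explanatory error", {
  expect_error(channelMask(channelGeometry(), c(120L, 50L)), "period")
  expect_error(channelMask(channelGeometry(pxPerUm = 20), c(120L, 500L)),
               "height")
})

test_that("rigid cells keep their shape; compliant cells track the width", {
  geom <- channelGeometry()
  rigid <- simulateTrajectory(cellModel(stiffness = 1), geom, 30L)
  expect_equal(diff(range(rigid[, "e"])), 0)
  soft <- simulateTrajectory(
    cellModel(stiffness = 0, relaxationFrames = 0, speedUmPerFrame = 2),
    geom, 30L)
  # elongation equals the width-dictated target at every frame
  p <- periodPx(geom)
  u <- (soft[, "cx"] - 1.5 * p) / p
  w <- 10 + 10 * 2 * abs(u - round(u))
  expect_equal(unname(soft[, "e"]), unname(20 / w))
  # and spans the full [1, 2] range as the cell crosses sections
  expect_gt(max(soft[, "e"]), 1.9)
  expect_lt(min(soft[, "e"]), 1.1)
})

test_that("centroid advances speed * pxPerUm pixels per frame", {
  tr <- simulateTrajectory(
    cellModel(speedUmPerFrame = 0.5),
    channelGeometry(pxPerUm = 10), 10L)
  expect_equal(unname(diff(tr[, "cx"])), rep(5, 9))
})

test_that("rendering is bit-identical for identical seeds", {
  st1 <- clean_study(1, seed = 5, noise = 2)
  st2 <- clean_study(1, seed = 5, noise = 2)
  expect_identical(st1$clips[[1]]@frames, st2$clips[[1]]@frames)
  expect_identical(st1$table$stiffness, st2$table$stiffness)
})

test_that("no-cell clips are background plus noise only", {
  geom <- channelGeometry()
  rc <- renderConfig(framesPerSequence = 6L, noiseSigma = 2)
  cell <- cellModel(startXPx = -500)  # cell never enters the frame
  tr <- simulateTrajectory(cell, geom, 6L)
  clip <- renderClip(tr, geom, rc, cell)
  fr <- frames(clip)
  expect_equal(sum(as.integer(groundTruth(clip)$masks)), 0)
  mad <- mean(abs(fr[, , , 2] - fr[, , , 1]))
  expect_lte(mad, 3 * 2)
  # noise-free, blur-free, cell-free: all frames identical
  rc0 <- renderConfig(framesPerSequence = 4L, noiseSigma = 0)
  clip0 <- renderClip(simulateTrajectory(cell, geom, 4L), geom, rc0, cell)
  fr0 <- frames(clip0)
  expect_identical(fr0[, , , 1], fr0[, , , 4])
})

test_that("mask centroid agrees with the trajectory centroid within 1 px", {
  clip <- default_clip()
  truth <- groundTruth(clip)
  m <- truth$masks
  for (t in c(5L, 15L, 25L)) {
    mt <- matrix(as.integer(m[, , t]), nrow = dim(m)[1])
    if (sum(mt) == 0) next
    cx <- sum(col(mt) * mt) / sum(mt) - 1  # to 0-based
    cy <- sum(row(mt) * mt) / sum(mt) - 1
    expect_lt(abs(cx - truth$centroids[t, 1]), 1)
    expect_lt(abs(cy - truth$centroids[t, 2]), 1)
  }
})

test_that("study structure mirrors the batch design and is reproducible", {
  tab1 <- samplePopulation(3, 2, 8, seed = 9)
  expect_equal(nrow(tab1), 40)
  expect_equal(sum(tab1$label == "native"), 24)
  expect_equal(sum(tab1$label == "modified"), 16)
  tab2 <- samplePopulation(3, 2, 8, seed = 9)
  expect_identical(tab1$stiffness, tab2$stiffness)
  st <- generateStudy(1, 0, 1, seed = 2)
  expect_length(st$clips, 1)
  expect_equal(clipLabel(st$clips[[1]]), st$table$label[1])
})

test_that("focal blur is drawn independently of the class label", {
  tab <- samplePopulation(1, 1, 150, seed = 21)
  expect_gte(nrow(tab), 200)
  r <- cor(tab$blurSigma, as.integer(tab$label == "modified"))
  expect_lt(abs(r), 0.1)
})
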