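test_that("background estimation is a robust low-order statistic", {
  expect_equal(estimateBackground(matrix(7, 10, 10)), 7)
  prof <- c(rep(20, 3), 60, 150, 200, 180, 90, 30, rep(20, 3))
  expect_equal(estimateBackground(prof), 20)
  expect_equal(estimateBackground(rep(0, 50)), 0)
  expect_error(estimateBackground(numeric(0)), "empty")
})

test_that("the 50% dip rule classifies worked examples correctly", {
  # dot peak 180, valley 80, adjacent peak 220 over background 20:
  # bg-sub valley 60 <= 0.5 * 160 -> out
  expect_equal(classifyDotOut(c(20, 180, 80, 220, 20),
                              background = 20), "out")
  # shallow valley close to the lower peak: no dip
  expect_equal(classifyDotOut(c(20, 180, 170, 220, 20),
                              background = 20), "not_out")
  # valley at exactly background: 100% dip
  expect_equal(classifyDotOut(c(20, 180, 20, 220, 20),
                              background = 20), "out")
  # boundary: dip of exactly 50% counts as out
  expect_equal(classifyDotOut(c(0, 100, 50, 100, 0), background = 0),
               "out")
  expect_equal(classifyDotOut(c(0, 100, 51, 100, 0), background = 0),
               "not_out")
  # fewer than two detectable peaks
  expect_equal(classifyDotOut(c(0, 10, 20, 30, 40), background = 0),
               "abnormal")
})

test_that("dip classifier agrees with a brute-force per-sample scan", {
  set.seed(202)
  agree <- 0L
  for (i in 1:1000) {
    n <- sample(7:50, 1)
    bg <- runif(1, 0, 40)
    prof <- randomTwoPeakProfile(n, bg)
    got <- classifyDotOut(prof, background = bg)
    want <- oracleDipDecision(prof, background = bg)
    expect_identical(got, want)
    agree <- agree + 1L
  }
  expect_equal(agree, 1000L)
})

test_that("dip classification is monotone in valley depth and background", {
  # lowering the valley never flips out -> not_out
  base <- c(10, 210, 150, 230, 10)
  prev <- classifyDotOut(base, background = 10)
  for (v in seq(150, 10, by = -10)) {
    prof <- base; prof[3] <- v
    lab <- classifyDotOut(prof, background = 10)
    if (prev == "out") expect_equal(lab, "out")
    prev <- lab
  }
  # raising the background deepens the relative dip ((v - bg) falls
  # twice as fast as the half-reference), so it never flips out ->
  # not_out with fixed raw peaks
  prof <- c(10, 210, 60, 230, 10)
  expect_equal(classifyDotOut(prof, background = 10), "out")
  for (bg in seq(10, 100, by = 10)) {
    lab <- classifyDotOut(prof, background = bg)
    expect_true(lab %in% c("out", "abnormal"))
  }
})

test_that("outer-edge XY distance follows the stated convention", {
  a <- makeBlob(c(10, 10))
  b <- makeBlob(c(10, 110))
  expect_equal(xyDistance(a, b, pixelSizeXY = 0.054), 102 * 0.054)
  expect_equal(xyDistance(a, b), xyDistance(b, a))
  expect_warning(d0 <- xyDistance(a, a), "overlap")
  expect_equal(d0, 0)
})

test_that("outer-edge distance of drawn disks matches construction", {
  img <- matrix(0, 80, 200)
  img <- drawDisk(img, c(40, 40), 10)
  img <- drawDisk(img, c(40, 160), 15)
  blobs <- segmentBlobs(img, threshold = 0.5, pixelSizeXY = 1)
  expect_length(blobs, 2)
  d <- xyDistance(blobs[[2]], blobs[[1]], pixelSizeXY = 1)
  # centre span 120 plus both radii plus the one-pixel outer faces
  expect_lt(abs(d - (120 + 10 + 15 + 2)), 1.5)
})

test_that("3D distance obeys the Pythagorean theorem and its bounds", {
  expect_equal(compute3dDistance(3, 8, 0.5), 5)
  expect_equal(compute3dDistance(7.2, 0, 0.5), 7.2)
  expect_equal(compute3dDistance(6, 5, 0.4), sqrt(40))
  expect_error(compute3dDistance(-1, 2, 0.5), "non-negative")
  expect_error(compute3dDistance(1, 2, 0), "positive")
  set.seed(5)
  for (i in 1:50) {
    dxy <- runif(1, 0, 10); k <- sample(0:10, 1); dz <- runif(1, 0.1, 1)
    d <- compute3dDistance(dxy, k, dz)
    expect_gte(d + 1e-12, max(dxy, k * dz))
  }
})

test_that("blob segmentation finds disks with faithful centroids and areas", {
  img <- matrix(0, 60, 60)
  img <- drawDisk(img, c(30, 30), 8)
  blobs <- segmentBlobs(img, threshold = 0.5, pixelSizeXY = 1)
  expect_length(blobs, 1)
  expect_lt(max(abs(blobs[[1]]$centroid - c(30, 30))), 0.5)

  expect_length(segmentBlobs(matrix(0, 20, 20)), 0)

  img2 <- matrix(0, 80, 80)
  img2 <- drawDisk(img2, c(25, 25), 12)
  img2 <- drawDisk(img2, c(60, 60), 5)
  blobs2 <- segmentBlobs(img2, threshold = 0.5, pixelSizeXY = 1)
  expect_length(blobs2, 2)
  expect_lt(abs(blobs2[[1]]$areaPx - pi * 144) / (pi * 144), 0.1)
  expect_lt(abs(blobs2[[2]]$areaPx - pi * 25) / (pi * 25), 0.1)
  # the small blob is a dot candidate under the 25% rule
  expect_false(blobs2[[1]]$isDot)
  expect_true(blobs2[[2]]$isDot)
})

test_that("area measurement scales with pixel count and pixel size", {
  expect_equal(measureArea(makeBlob(c(5, 5)), 0.054), 0.054^2)
  img <- matrix(0, 40, 40)
  img <- drawDisk(img, c(20, 20), 10)
  blob <- segmentBlobs(img, threshold = 0.5, pixelSizeXY = 0.054)[[1]]
  expect_lt(abs(measureArea(blob, 0.054) - pi * 100 * 0.054^2) /
            (pi * 100 * 0.054^2), 0.1)
  expect_equal(measureArea(blob, 0.108), 4 * measureArea(blob, 0.054))
  expect_error(measureArea(list(pixels = matrix(0, 0, 2))), "empty")
})

test_that("Z offset counts sections between light-cone centres", {
  v <- array(0, c(24, 40, 40))
  v[11, 9:11, 9:11] <- 100    # section 10, 0-based
  v[19, 29:31, 29:31] <- 100  # section 18
  ba <- makeBlob(as.matrix(expand.grid(9:11, 9:11)))
  bb <- makeBlob(as.matrix(expand.grid(29:31, 29:31)))
  expect_equal(zOffsetSections(v, ba, bb), 8L)
  v2 <- v; v2[19, , ] <- 0; v2[11, 29:31, 29:31] <- 100
  expect_equal(zOffsetSections(v2, ba, bb), 0L)
  expect_error(zOffsetSections(array(0, c(4, 40, 40)), ba, bb),
               "no intensity")
})

test_that("configuration triage follows the exclusion rules", {
  bothOut <- classifyConfiguration(
    data.frame(out = c(TRUE, TRUE), side = c(-1, 1)))
  expect_equal(bothOut$configuration, "both_out")
  expect_true(bothOut$distanceEligible)
  expect_true(bothOut$anyOut)

  same <- classifyConfiguration(
    data.frame(out = c(TRUE, TRUE), side = c(1, 1)))
  expect_equal(same$configuration, "both_same_side")
  expect_false(same$distanceEligible)
  expect_true(same$anyOut)   # still counted in the proportion out

  oneOut <- classifyConfiguration(
    data.frame(out = c(TRUE, FALSE), side = c(-1, 1)))
  expect_equal(oneOut$configuration, "one_out_other_locatable")
  expect_true(oneOut$distanceEligible)

  extra <- classifyConfiguration(
    data.frame(out = c(TRUE, TRUE, TRUE), side = c(-1, 1, 1)))
  expect_equal(extra$configuration, "extra_nonexchange")
  expect_false(extra$distanceEligible)
  expect_true(extra$anyOut)

  none <- classifyConfiguration(
    data.frame(out = logical(0), side = numeric(0)))
  expect_equal(none$configuration, "none_out")
  expect_false(none$anyOut)

  lone <- classifyConfiguration(
    data.frame(out = TRUE, side = 1), otherLocatable = FALSE)
  expect_equal(lone$configuration, "abnormal")
  expect_true(lone$anyOut)
})

test_that("proportion out is the exact quotient with guarded inputs", {
  expect_equal(round(proportionOut(71, 147), 2), 0.48)
  expect_equal(round(100 * proportionOut(14, 115)), 12)
  expect_equal(proportionOut(0, 50), 0)
  expect_error(proportionOut(1, 0), "> 0")
  expect_error(proportionOut(5, 3), "between")
  # complement identity
  expect_equal(proportionOut(30, 100), 1 - proportionOut(70, 100))
})
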