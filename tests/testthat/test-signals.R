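test_that("background removal separates tissue from near-white ground", {
  white <- asNormRoi(flatImage(32, 32, c(255, 255, 255)))
  expect_false(any(removeBackground(white)))
  # degenerate thresholds: above the white point everything is tissue,
  # at zero everything is background
  expect_true(all(removeBackground(white, 1.01)))
  expect_false(any(removeBackground(white, 0)))

  sc <- simulateRoi(syntheticSpec(imageSize = c(256L, 256L), nNuclei = 1L,
                                  her2PerNucleus = fixedCount(0),
                                  cep17PerNucleus = fixedCount(0),
                                  seed = 8))
  fg <- removeBackground(asNormRoi(pixels(sc$image)))
  planted <- length(truthMasks(sc$truth)[[1]])
  expect_lt(abs(sum(fg) - planted) / planted, 0.05)
})

test_that("blank images yield no spots on either channel", {
  white <- asNormRoi(flatImage(64, 64, c(255, 255, 255)))
  expect_equal(nrow(detectSpots(white, "HER2")), 0)
  expect_equal(nrow(detectSpots(white, "CEP17")), 0)
})

test_that("planted isolated dots are recovered with centroids within 2 px", {
  cols <- sceneColors()
  px <- flatImage(200, 200, cols$background)
  px <- paintDiskPx(px, 60, 60, 30, cols$nucleus)
  hPos <- rbind(c(40, 150), c(80, 150), c(120, 150), c(160, 150),
                c(160, 40))
  cPos <- rbind(c(30, 100), c(120, 30), c(170, 100))
  for (i in 1:5) px <- paintDiskPx(px, hPos[i, 1], hPos[i, 2], 2.6, cols$her2)
  for (i in 1:3) px <- paintDiskPx(px, cPos[i, 1], cPos[i, 2], 2.6, cols$cep17)
  roi <- asNormRoi(px)
  h <- detectSpots(roi, "HER2")
  c17 <- detectSpots(roi, "CEP17")
  expect_equal(nrow(h), 5)
  expect_equal(nrow(c17), 3)
  for (i in 1:5) {
    dd <- sqrt((h$row - hPos[i, 1])^2 + (h$col - hPos[i, 2])^2)
    expect_lt(min(dd), 2)
  }
  for (i in 1:3) {
    dd <- sqrt((c17$row - cPos[i, 1])^2 + (c17$col - cPos[i, 2])^2)
    expect_lt(min(dd), 2)
  }
  expect_true(all(h$signal_count == 1L))
})

test_that("a blob of triple singleton area decomposes to signal_count 3", {
  cols <- sceneColors()
  px <- flatImage(160, 300, cols$background)
  r <- 2.6
  for (c0 in c(30, 70, 110, 150, 190)) # 5 singletons
    px <- paintDiskPx(px, 40, c0, r, cols$her2)
  # chain of three merged disks at 1.9 r spacing: union about 3 singles
  for (k in 0:2)
    px <- paintDiskPx(px, 110, 120 + k * 1.9 * r, r, cols$her2)
  sp <- detectSpots(asNormRoi(px), "HER2")
  expect_equal(nrow(sp), 6)
  expect_equal(sort(sp$signal_count), c(1, 1, 1, 1, 1, 3))
  # with decomposition off the blob counts once
  sp1 <- detectSpots(asNormRoi(px), "HER2",
                     config = list(cluster_split = FALSE))
  expect_true(all(sp1$signal_count == 1L))
})

test_that("faint-signal removal drops exactly the low-contrast spots", {
  spots <- data.frame(channel = "HER2", row = 1:4, col = 1:4,
                      area_px = 20L, signal_count = 1L,
                      contrast = c(0.9, 0.4, 0.85, 0.2))
  expect_equal(removeFaint(spots, 0), spots)
  expect_equal(nrow(removeFaint(spots, 1)), 0)
  kept <- removeFaint(spots, 0.5)
  expect_equal(kept$contrast, c(0.9, 0.85))

  # planted contrasts: strong and deliberately faint dots on white ground
  cols <- sceneColors()
  px <- flatImage(120, 240, cols$background)
  for (c0 in c(30, 70, 110, 150)) px <- paintDiskPx(px, 40, c0, 2.6, cols$her2)
  for (c0 in c(60, 140)) px <- paintDiskPx(px, 90, c0, 2.6, c(64, 58, 61))
  sp <- detectSpots(asNormRoi(px), "HER2")
  expect_equal(nrow(sp), 6)
  strong <- removeFaint(sp, 0.8)  # between the two contrast levels
  expect_equal(nrow(strong), 4)
  expect_true(all(strong$row < 60))
})

test_that("raising thresholds never increases the spot count", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(384L, 384L), nNuclei = 6L,
                                  her2PerNucleus = fixedCount(4),
                                  cep17PerNucleus = fixedCount(2),
                                  seed = 17))
  norm <- normalizeRoi(sc$image)
  nBase <- nrow(detectSpots(norm, "HER2"))
  for (vmax in c(0.3, 0.25, 0.2)) {
    n <- nrow(detectSpots(norm, "HER2", config = list(her2_value_max = vmax)))
    expect_lte(n, nBase)
    nBase <- n
  }
  sp <- detectSpots(norm, "CEP17")
  for (thr in c(0, 0.3, 0.6, 0.9)) {
    expect_true(all(removeFaint(sp, thr)$contrast %in% sp$contrast))
    expect_lte(nrow(removeFaint(sp, thr)), nrow(sp))
  }
})

test_that("no planted dot is reported on the wrong channel", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(384L, 384L), nNuclei = 6L,
                                  her2PerNucleus = fixedCount(3),
                                  cep17PerNucleus = fixedCount(3),
                                  seed = 23))
  norm <- normalizeRoi(sc$image)
  sp <- rbind(detectSpots(norm, "HER2"), detectSpots(norm, "CEP17"))
  dots <- sc$truth@dots
  for (i in seq_len(nrow(dots))) {
    dd <- sqrt((sp$row - dots$row[i])^2 + (sp$col - dots$col[i])^2)
    expect_equal(sp$channel[which.min(dd)], dots$channel[i])
  }
})

test_that("detection on a side-by-side concatenation equals per-ROI detection", {
  scA <- simulateRoi(syntheticSpec(imageSize = c(320L, 320L), nNuclei = 4L,
                                   her2PerNucleus = fixedCount(3),
                                   cep17PerNucleus = fixedCount(2),
                                   seed = 31))
  scB <- simulateRoi(syntheticSpec(imageSize = c(320L, 320L), nNuclei = 4L,
                                   her2PerNucleus = fixedCount(2),
                                   cep17PerNucleus = fixedCount(2),
                                   seed = 32))
  pxA <- pixels(scA$image); pxB <- pixels(scB$image)
  joint <- array(0, dim = c(320, 640, 3))
  joint[, 1:320, ] <- pxA; joint[, 321:640, ] <- pxB
  for (chan in c("HER2", "CEP17")) {
    a <- detectSpots(asNormRoi(pxA), chan)
    b <- detectSpots(asNormRoi(pxB), chan)
    j <- detectSpots(asNormRoi(joint), chan)
    expect_equal(nrow(j), nrow(a) + nrow(b))
    expect_equal(sum(j$signal_count), sum(a$signal_count) + sum(b$signal_count))
  }
})
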