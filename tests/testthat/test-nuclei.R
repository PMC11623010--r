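test_that("blank images segment to an all-zero label map", {
  white <- asNormRoi(flatImage(48, 48, c(255, 255, 255)))
  lab <- segmentNuclei(white)
  expect_true(all(lab == 0L))
  expect_equal(dim(lab), c(48L, 48L))
})

test_that("well-separated planted nuclei segment to one label each", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(512L, 512L), nNuclei = 12L,
                                  her2PerNucleus = fixedCount(2),
                                  cep17PerNucleus = fixedCount(2),
                                  seed = 41))
  lab <- segmentNuclei(normalizeRoi(sc$image))
  expect_equal(max(lab), 12L)
  nuc <- sc$truth@nuclei
  at <- lab[cbind(round(nuc$row) + 1, round(nuc$col) + 1)]
  expect_true(all(at > 0L))
  expect_equal(length(unique(at)), 12L)
})

test_that("watershed separates a touching nucleus pair", {
  cols <- sceneColors()
  px <- flatImage(200, 260, cols$background)
  r <- 25
  # centers 1.5 radii apart: masks merge into one blob
  px <- paintDiskPx(px, 100, 100, r, cols$nucleus)
  px <- paintDiskPx(px, 100, 100 + 1.5 * r, r, cols$nucleus)
  lab <- segmentNuclei(asNormRoi(px))
  expect_equal(max(lab), 2L)
  expect_true(lab[101, 101] != lab[101, 101 + round(1.5 * r)])
})

test_that("segmentation is deterministic", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(384L, 384L), nNuclei = 6L,
                                  seed = 47, noiseSd = 3))
  norm <- normalizeRoi(sc$image)
  expect_identical(segmentNuclei(norm), segmentNuclei(norm))
})

test_that("spots contribute their signal_count to the covering nucleus", {
  lab <- matrix(0L, 40, 40)
  lab[5:15, 5:15] <- 1L
  lab[25:35, 20:35] <- 2L
  spots <- data.frame(
    channel = c("HER2", "HER2", "CEP17", "HER2"),
    row = c(10, 30, 30, 1), col = c(10, 25, 30, 1),
    area_px = 20L, signal_count = c(1L, 3L, 1L, 1L),
    contrast = 0.8)
  rec <- assignSpots(lab, spots)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$her2_count, c(1L, 3L))   # cluster adds 3 to nucleus 2
  expect_equal(rec$cep17_count, c(0L, 1L))  # background spot ignored
  expect_equal(rec$differentiation, rec$her2_count - rec$cep17_count)
  expect_error(assignSpots(lab, transform(spots, row = 100)),
               "dimension mismatch")
})

test_that("planted per-nucleus counts are recovered through assignment", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(448L, 448L), nNuclei = 8L,
                                  her2PerNucleus = fixedCount(6),
                                  cep17PerNucleus = fixedCount(2),
                                  seed = 53))
  norm <- normalizeRoi(sc$image)
  spots <- rbind(detectSpots(norm, "HER2"), detectSpots(norm, "CEP17"))
  lab <- segmentNuclei(norm)
  rec <- assignSpots(lab, spots)
  nuc <- sc$truth@nuclei
  at <- lab[cbind(round(nuc$row) + 1, round(nuc$col) + 1)]
  m <- merge(data.frame(label = at, ph = nuc$her2, pc = nuc$cep17),
             rec, by = "label")
  expect_equal(m$her2_count, m$ph)
  expect_equal(m$cep17_count, m$pc)
})

test_that("border-touching nuclei are excluded as truncated", {
  lab <- matrix(0L, 30, 30)
  lab[1:5, 10:14] <- 1L    # includes row 1: truncated
  lab[10:15, 10:15] <- 2L  # interior
  lab[26:30, 20:24] <- 3L  # includes last row: truncated
  rec <- assignSpots(lab, data.frame(channel = character(),
                                     row = numeric(), col = numeric(),
                                     area_px = integer(),
                                     signal_count = integer(),
                                     contrast = numeric()))
  kept <- filterTruncated(rec, lab)
  expect_equal(kept$label, 2L)
})

test_that("planted truncation flags are reproduced from the rendered image", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(640L, 640L), nNuclei = 13L,
                                  edgeClipFraction = 3 / 13, seed = 59))
  nuc <- sc$truth@nuclei
  expect_equal(sum(nuc$truncated), 3)
  norm <- normalizeRoi(sc$image)
  lab <- segmentNuclei(norm)
  rec <- assignSpots(lab, data.frame(channel = character(),
                                     row = numeric(), col = numeric(),
                                     area_px = integer(),
                                     signal_count = integer(),
                                     contrast = numeric()))
  kept <- filterTruncated(rec, lab)
  at <- lab[cbind(round(nuc$row) + 1, round(nuc$col) + 1)]
  interior <- at[!nuc$truncated]
  clipped <- at[nuc$truncated]
  expect_equal(sum(!nuc$truncated), 10)
  expect_true(all(interior %in% kept$label))
  expect_false(any(clipped %in% kept$label))
})

test_that("overlap exclusion applies the 50 percent own-area rule", {
  rec <- recTable(c(2, 2), c(2, 2))
  # A: 100 px with 60 shared; B: 300 px with the same 60 shared
  outlines <- list(`1` = 1:100, `2` = c(41:100, 1000:1239))
  out <- filterOverlapping(rec, outlines, 0.5)
  expect_equal(out$label, 2L)
  expect_equal(out$max_overlap_fraction, 60 / 300)
  # disjoint instances both survive
  out2 <- filterOverlapping(rec, list(`1` = 1:100, `2` = 201:300), 0.5)
  expect_equal(out2$label, c(1L, 2L))
  # label-map instances pass trivially
  expect_equal(filterOverlapping(rec, NULL)$label, c(1L, 2L))
})

test_that("overlap removal matches a brute-force rasterization oracle", {
  set.seed(61)
  for (rep in 1:100) {
    h <- 60; w <- 60
    n <- 3
    cr <- runif(n, 15, 45); cc <- runif(n, 15, 45)
    a <- runif(n, 6, 14); b <- runif(n, 6, 14)
    sets <- lapply(seq_len(n), function(i) {
      g <- expand.grid(r = 0:(h - 1), c = 0:(w - 1))
      which((g$r - cr[i])^2 / a[i]^2 + (g$c - cc[i])^2 / b[i]^2 <= 1)
    })
    names(sets) <- as.character(1:n)
    rec <- recTable(rep(2, n), rep(2, n))
    got <- filterOverlapping(rec, sets, 0.5)$label
    # oracle: static pairwise fractions, remove every instance whose
    # largest fraction exceeds the bound
    frac <- sapply(1:n, function(i) {
      max(c(0, sapply(setdiff(1:n, i), function(j)
        length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]]))))
    })
    expect_equal(got, which(frac <= 0.5))
  }
})

test_that("planted overlap-pair members are rejected from truth masks", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(640L, 640L), nNuclei = 14L,
                                  overlapPairFraction = 4 / 14, seed = 67))
  tr <- sc$truth
  expect_equal(sum(tr@nuclei$overlapped), 4)
  rec <- truthRecords(tr)
  out <- filterOverlapping(rec, truthMasks(tr), 0.5)
  expect_equal(sort(out$label), tr@nuclei$label[!tr@nuclei$overlapped])
})

test_that("the CEP17 rule filters and falls back as specified", {
  rec <- recTable(c(4, 4, 4, 4), c(0, 1, 2, 3))
  strict <- filterByCep17(rec)
  expect_equal(strict$records$cep17_count, c(2L, 3L))
  expect_false(strict$fallbackUsed)

  rec1 <- recTable(rep(6, 5), rep(1, 5))
  fb <- filterByCep17(rec1)
  expect_equal(nrow(fb$records), 5)
  expect_true(fb$fallbackUsed)

  rec0 <- recTable(rep(6, 5), rep(0, 5))
  fb0 <- filterByCep17(rec0)
  expect_equal(nrow(fb0$records), 0)
  expect_true(fb0$fallbackUsed)

  expect_equal(nrow(filterByCep17(rec1, allowFallback = FALSE)$records), 0)
})

test_that("qualification is invariant to instance relabeling", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(512L, 512L), nNuclei = 9L,
                                  edgeClipFraction = 2 / 9, seed = 71))
  norm <- normalizeRoi(sc$image)
  lab <- segmentNuclei(norm)
  spots <- rbind(detectSpots(norm, "HER2"), detectSpots(norm, "CEP17"))
  q1 <- qualifyNuclei(assignSpots(lab, spots), lab)
  # permute the instance identifiers
  perm <- sample(max(lab))
  lab2 <- lab
  lab2[lab > 0L] <- perm[lab[lab > 0L]]
  q2 <- qualifyNuclei(assignSpots(lab2, spots), lab2)
  k1 <- q1$records[order(q1$records$row), c("her2_count", "cep17_count")]
  k2 <- q2$records[order(q2$records$row), c("her2_count", "cep17_count")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
  expect_equal(q1$stageCounts, q2$stageCounts)
})

test_that("assignment conserves total detected signal mass", {
  sc <- simulateRoi(syntheticSpec(imageSize = c(448L, 448L), nNuclei = 7L,
                                  her2PerNucleus = fixedCount(5),
                                  cep17PerNucleus = fixedCount(2),
                                  seed = 73))
  norm <- normalizeRoi(sc$image)
  spots <- rbind(detectSpots(norm, "HER2"), detectSpots(norm, "CEP17"))
  lab <- segmentNuclei(norm)
  rec <- assignSpots(lab, spots)
  onBg <- lab[cbind(round(spots$row) + 1, round(spots$col) + 1)] == 0L
  expect_equal(sum(rec$her2_count) +
                 sum(spots$signal_count[onBg & spots$channel == "HER2"]),
               sum(spots$signal_count[spots$channel == "HER2"]))
  expect_equal(sum(rec$cep17_count) +
                 sum(spots$signal_count[onBg & spots$channel == "CEP17"]),
               sum(spots$signal_count[spots$channel == "CEP17"]))
})
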