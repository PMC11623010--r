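test_that("ranking orders by differentiation with deterministic tie-breaks", {
  rec <- recTable(c(6, 2, 9), c(2, 2, 2))  # differentiations 4, 0, 7
  expect_equal(rankNuclei(rec)$differentiation, c(7, 4, 0))

  tie <- recTable(c(6, 4), c(4, 2))  # both differentiation 2
  expect_equal(rankNuclei(tie)$her2_count, c(6, 4))

  tie2 <- recTable(c(4, 4), c(2, 2), label = c(9L, 3L))
  expect_equal(rankNuclei(tie2)$label, c(3L, 9L))
})

test_that("ranking agrees with a brute-force comparison sort", {
  set.seed(81)
  rec <- recTable(sample(0:12, 50, TRUE), sample(0:4, 50, TRUE),
                  label = sample(1000L, 50))
  got <- rankNuclei(rec)
  # oracle: repeated extraction of the maximum under the stated key
  before <- function(a, b) {
    if (a$differentiation != b$differentiation)
      return(a$differentiation > b$differentiation)
    if (a$her2_count != b$her2_count) return(a$her2_count > b$her2_count)
    a$label < b$label
  }
  pool <- split(rec, seq_len(nrow(rec)))
  ordered <- list()
  while (length(pool)) {
    best <- 1
    for (i in seq_along(pool))
      if (before(pool[[i]], pool[[best]])) best <- i
    ordered[[length(ordered) + 1]] <- pool[[best]]
    pool[[best]] <- NULL
  }
  want <- do.call(rbind, ordered)
  rownames(want) <- rownames(got) <- NULL
  expect_equal(got, want)
})

test_that("selection takes the top n and flags shortfalls", {
  rec <- rankNuclei(recTable(sample(1:40, 35, TRUE), rep(2, 35)))
  sel <- selectNuclei(rec, 20)
  expect_equal(nrow(sel), 20)
  expect_false(attr(sel, "lowConfidence"))

  few <- rankNuclei(recTable(rep(3, 12), rep(2, 12)))
  sel2 <- selectNuclei(few, 20)
  expect_equal(nrow(sel2), 12)
  expect_true(attr(sel2, "lowConfidence"))

  expect_error(selectNuclei(recTable(integer(), integer())),
               "no quantifiable nuclei")
})

test_that("ratio reproduces printed totals at 2-decimal rounding", {
  mk <- function(h, c) recTable(h, c)
  expect_equal(roundHalfAway(computeRatio(mk(217, 126)), 2), 1.72)
  expect_equal(roundHalfAway(computeRatio(mk(1690, 183)), 2), 9.23)
  expect_equal(computeRatio(mk(c(10, 5), c(10, 5))), 1)
  expect_error(computeRatio(mk(5, 0)), "fallback")
})

test_that("copies per nucleus divides totals by the selection size", {
  expect_equal(copiesPerNucleus(recTable(rep(2, 20), rep(2, 20))), 2)
  expect_equal(copiesPerNucleus(recTable(rep(0, 7), rep(2, 7))), 0)
  set.seed(82)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    h <- sample(0:15, n, TRUE)
    sel <- recTable(h, rep(2, n))
    tot <- 0
    for (i in seq_len(n)) tot <- tot + sel$her2_count[i]
    expect_equal(copiesPerNucleus(sel), tot / n)
  }
})

test_that("ratio is invariant to uniform scaling of per-nucleus counts", {
  set.seed(83)
  rec <- recTable(sample(1:9, 25, TRUE), sample(1:4, 25, TRUE))
  r1 <- computeRatio(rec)
  for (k in c(2L, 5L)) {
    sc <- recTable(rec$her2_count * k, rec$cep17_count * k)
    expect_equal(computeRatio(sc), r1)
  }
})

test_that("status calls follow the configured mode", {
  expect_equal(classifyStatus(2.59), "Positive")
  expect_equal(classifyStatus(1.19), "Negative")
  expect_equal(classifyStatus(1.90), "Negative")
  expect_equal(classifyStatus(2.0), "Positive")  # cutoff inclusive

  thr3 <- statusThresholds(mode = "three_way_ratio")
  expect_equal(classifyStatus(1.7, thresholds = thr3), "Negative")
  expect_equal(classifyStatus(1.9, thresholds = thr3), "Equivocal")
  expect_equal(classifyStatus(2.3, thresholds = thr3), "Positive")

  thrF <- statusThresholds(mode = "asco_full")
  expect_equal(classifyStatus(1.5, copies = 6.5, thresholds = thrF),
               "Positive")
  expect_equal(classifyStatus(1.5, copies = 5.0, thresholds = thrF),
               "Equivocal")
  expect_equal(classifyStatus(1.5, copies = 3.0, thresholds = thrF),
               "Negative")

  # monotone in ratio: raising the ratio never moves the call toward
  # Negative
  lvl <- c(Negative = 1, Equivocal = 2, Positive = 3)
  for (thr in list(statusThresholds(), thr3)) {
    calls <- sapply(seq(0, 4, by = 0.05), classifyStatus, copies = 2,
                    thresholds = thr)
    expect_true(all(diff(lvl[calls]) >= 0))
  }
})

test_that("scoring homogeneous scenes reproduces the planted arithmetic", {
  amp <- scoreNuclei(recTable(rep(6, 30), rep(2, 30)))
  expect_equal(her2Ratio(amp), 3)
  expect_equal(amplificationStatus(amp), "Positive")

  normal <- scoreNuclei(recTable(rep(2, 25), rep(2, 25)))
  expect_equal(her2Ratio(normal), 1)
  expect_equal(normal@copiesPerNucleus, 2)
  expect_equal(amplificationStatus(normal), "Negative")
  expect_false(normal@extraSetCounted)
  expect_equal(nQuantified(normal), 20)
})

test_that("copy numbers in the recount band trigger the extra set", {
  border <- scoreNuclei(recTable(rep(5, 45), rep(3, 45)))
  expect_true(border@extraSetCounted)
  expect_equal(nQuantified(border), 40)
  expect_equal(border@copiesPerNucleus, 5)

  # 40 ranked nuclei: the second set is records 21-40
  rec40 <- recTable(rep(5, 40), rep(3, 40))
  r40 <- scoreNuclei(rec40)
  expect_equal(nQuantified(r40), 40)

  # no recount when the copy number sits outside the band
  low <- scoreNuclei(recTable(rep(2, 45), rep(2, 45)))
  expect_false(low@extraSetCounted)
  high <- scoreNuclei(recTable(rep(7, 45), rep(2, 45)))
  expect_false(high@extraSetCounted)
})

test_that("scores with fewer than 20 nuclei carry the low-confidence flag", {
  few <- scoreNuclei(recTable(rep(4, 17), rep(2, 17)))
  expect_true(few@lowConfidence)
  expect_equal(nQuantified(few), 17)
  expect_equal(her2Ratio(few), 2)
})
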