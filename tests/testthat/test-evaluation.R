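test_that("identical measurement vectors give zero bias and zero-width limits", {
  x <- c(1.2, 2.5, 0.7, 3.3)
  mc <- blandAltman(x, x)
  expect_equal(bias(mc), 0)
  expect_equal(unname(limitsOfAgreement(mc)), c(0, 0))
  expect_equal(mc@tStatistic, 0)
  expect_equal(mc@pValue, 1)  # two-sided with the null exactly true
})

test_that("limits of agreement are symmetric and translation-equivariant", {
  set.seed(91)
  m <- rnorm(30, 2, 1); r <- rnorm(30, 2, 1)
  mc <- blandAltman(m, r)
  expect_equal(mc@loaHigh - bias(mc), bias(mc) - mc@loaLow)
  shifted <- blandAltman(m + 0.7, r)
  expect_equal(bias(shifted), bias(mc) + 0.7)
  expect_equal(shifted@loaLow, mc@loaLow + 0.7)
  expect_equal(shifted@loaHigh, mc@loaHigh + 0.7)
  expect_equal(shifted@sdDiff, mc@sdDiff)
})

test_that("paired t-test follows the mean/sd formula and its conventions", {
  set.seed(92)
  m <- rnorm(25); r <- rnorm(25)
  got <- pairedTTest(m, r)
  ref <- t.test(m, r, paired = TRUE)  # independent route
  expect_equal(got[["t_statistic"]], unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(got[["p_value"]], ref$p.value, tolerance = 1e-12)

  # two-sided p equals twice the smaller one-sided p
  g <- pairedTTest(m, r, "greater")[["p_value"]]
  l <- pairedTTest(m, r, "less")[["p_value"]]
  expect_equal(got[["p_value"]], 2 * min(g, l), tolerance = 1e-12)

  # degenerate cases
  z <- rep(1, 5)
  expect_equal(pairedTTest(z, z)[["t_statistic"]], 0)
  expect_equal(pairedTTest(z, z, "greater")[["p_value"]], 0.5)
  expect_equal(pairedTTest(z, z)[["p_value"]], 1)
  expect_equal(pairedTTest(z + 1, z)[["p_value"]], 0)
})

test_that("one-sided type-I error is calibrated at the nominal level", {
  set.seed(93)
  nrep <- 10000
  rej <- 0
  for (i in seq_len(nrep)) {
    d <- rnorm(10, 0, 1)
    if (pairedTTest(d, rep(0, 10), "greater")[["p_value"]] < 0.05)
      rej <- rej + 1
  }
  expect_lt(abs(rej / nrep - 0.05), 0.01)
})

test_that("misclassification tabulates threshold disagreements", {
  ratios <- c(2.4, 1.1, 1.9, 3.0)
  status <- c("Neg", "Pos", "Neg", "Pos")
  got <- misclassificationTable(ratios, status, ids = c("a", "b", "c", "d"))
  expect_equal(got$misclassified, 2)
  expect_equal(got$false_positives, "a")
  expect_equal(got$false_negatives, "b")

  # thresholding the reference-derived calls against themselves is clean
  derived <- ifelse(ratios >= 2, "Pos", "Neg")
  self <- misclassificationTable(ratios, derived)
  expect_equal(self$misclassified, 0)

  expect_error(misclassificationTable(ratios, c("Neg", "Pos", "??", "Pos")),
               "unknown reference status '\\?\\?' in row 3")
})

test_that("misclassification count shrinks toward the best separating cutoff", {
  ref <- referenceScores()
  grid <- seq(0.5, 9.5, by = 0.05)
  # on separable calls (status derived from the ratios themselves) the
  # sweep is strictly monotone toward the separating value from both sides
  derived <- ifelse(ref$method_ratio >= 2, "Pos", "Neg")
  cnt <- sapply(grid, function(cut) misclassificationTable(
    ref$method_ratio, derived, cutoff = cut)$misclassified)
  best <- grid[which.min(cnt)]
  expect_equal(min(cnt), 0)
  expect_true(all(diff(cnt[grid <= best]) <= 0))
  expect_true(all(diff(cnt[grid >= best]) >= 0))
  # on the real expert calls the classes overlap; the sweep minimum (two
  # disagreements) is still attained at the clinical cutoff of 2.0
  counts <- sapply(grid, function(cut) misclassificationTable(
    ref$method_ratio, ref$expert_status, cutoff = cut)$misclassified)
  expect_equal(min(counts), 2)
  expect_equal(counts[grid == 2.0], min(counts))
})

test_that("pearson correlation matches a from-scratch oracle", {
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x + 1), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  set.seed(94)
  for (rep in 1:100) {
    m <- rnorm(20); r <- rnorm(20)
    num <- sum((m - mean(m)) * (r - mean(r)))
    den <- sqrt(sum((m - mean(m))^2) * sum((r - mean(r))^2))
    expect_lt(abs(pearsonCorrelation(m, r) - num / den), 1e-12)
  }
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("the bundled reference table reproduces the published agreement", {
  ref <- referenceScores()
  expect_equal(nrow(ref), 33)
  mc <- compareMethods(ref$method_ratio, ref$expert_ratio,
                       ids = ref$image_id,
                       referenceStatus = ref$expert_status)
  expect_equal(roundHalfAway(bias(mc), 2), 0.09)
  expect_equal(roundHalfAway(mc@loaHigh, 2), 3.10)
  expect_equal(roundHalfAway(mc@loaLow, 2), -2.91)
  expect_gt(mc@pValue, 0.05)
  expect_equal(mc@misclassified, 2L)
})

test_that("the Bland-Altman plot renders to file", {
  ref <- referenceScores()
  f <- tempfile(fileext = ".png")
  mc <- plotBlandAltman(ref$method_ratio, ref$expert_ratio, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_s4_class(mc, "MethodComparison")
})
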