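#' Bland-Altman agreement statistics
#'
#' Computes the differences `method - reference`, their mean (bias),
#' sample (n-1) standard deviation, and the 1.96-SD limits of agreement —
#' the standard Bland-Altman summary of agreement between two
#' measurements of the same quantity. The paired t-test and
#' misclassification fields of the returned object are filled by
#' [compareMethods()]; `blandAltman` itself fills them with the t-test at
#' the requested sidedness and an empty misclassification table.
#'
#' @param method numeric vector of automated measurements.
#' @param reference numeric vector of reference measurements, same
#'   length, `n >= 2`.
#' @param sidedness t-test sidedness, `"two_sided"` (default),
#'   `"greater"` or `"less"`.
#' @return A [MethodComparison-class].
#' @export
blandAltman <- function(method, reference, sidedness = "two_sided") {
  if (length(method) != length(reference))
    stop("method and reference must have equal length")
  n <- length(method)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- method - reference
  b <- mean(d)
  s <- stats::sd(d)
  tt <- pairedTTest(method, reference, sidedness)
  new("MethodComparison", nPairs = as.integer(n), bias = b, sdDiff = s,
      loaLow = b - 1.96 * s, loaHigh = b + 1.96 * s,
      tStatistic = tt[["t_statistic"]], pValue = tt[["p_value"]],
      sidedness = sidedness, misclassified = 0L,
      falsePositives = character(), falseNegatives = character())
}

#' Paired t-test on method-minus-reference differences
#'
#' `t = bias / (sd_diff / sqrt(n))` with `n - 1` degrees of freedom.
#' Degenerate inputs follow the convention: zero-variance differences
#' with nonzero bias give `p = 0`; zero bias with zero variance gives
#' `t = 0` (one-sided `p = 0.5`, two-sided `p = 1`).
#'
#' @inheritParams blandAltman
#' @param sidedness `"two_sided"`, `"greater"` (method exceeds
#'   reference) or `"less"`.
#' @return Named numeric vector `c(t_statistic, p_value)`.
#' @export
pairedTTest <- function(method, reference,
                        sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (length(method) != length(reference))
    stop("method and reference must have equal length")
  n <- length(method)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- method - reference
  b <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (b == 0) 0 else sign(b) * Inf
  } else {
    t <- b / (s / sqrt(n))
  }
  df <- n - 1
  p <- switch(sidedness,
    two_sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df))
  c(t_statistic = t, p_value = p)
}

#' Misclassification table at a ratio cutoff
#'
#' Thresholds the method ratios at `cutoff` and tabulates disagreements
#' with the reference status: a false positive is a method ratio at or
#' above the cutoff for a reference-negative case; a false negative is a
#' sub-cutoff ratio for a reference-positive case.
#'
#' @param methodRatios numeric vector of method HER2/CEP17 ratios.
#' @param referenceStatus reference calls, `"Pos"`/`"Neg"` (or
#'   `"Positive"`/`"Negative"`).
#' @param ids identifiers aligned with the vectors; default row numbers.
#' @param cutoff ratio cutoff (default 2.0).
#' @return `list(misclassified, false_positives, false_negatives)`.
#' @export
misclassificationTable <- function(methodRatios, referenceStatus,
                                   ids = seq_along(methodRatios),
                                   cutoff = 2.0) {
  stopifnot(length(methodRatios) == length(referenceStatus),
            length(ids) == length(methodRatios))
  st <- as.character(referenceStatus)
  pos <- st %in% c("Pos", "Positive", "pos", "positive")
  neg <- st %in% c("Neg", "Negative", "neg", "negative")
  bad <- which(!(pos | neg))
  if (length(bad))
    stop("unknown reference status '", st[bad[1]], "' in row ", bad[1],
         " (id ", ids[bad[1]], ")")
  fp <- ids[methodRatios >= cutoff & neg]
  fn <- ids[methodRatios < cutoff & pos]
  list(misclassified = length(fp) + length(fn),
       false_positives = as.character(fp),
       false_negatives = as.character(fn))
}

#' Pearson product-moment correlation
#'
#' @param method,reference equal-length numeric vectors, `n >= 2`, both
#'   non-constant.
#' @return Single correlation coefficient.
#' @export
pearsonCorrelation <- function(method, reference) {
  if (length(method) != length(reference))
    stop("method and reference must have equal length")
  if (length(method) < 2L) stop("at least 2 pairs are required")
  if (stats::sd(method) == 0 || stats::sd(reference) == 0)
    stop("correlation is undefined for a constant vector")
  stats::cor(method, reference)
}

#' Full method comparison
#'
#' Combines [blandAltman()], [pairedTTest()] and, when a reference status
#' is supplied, [misclassificationTable()] into one
#' [MethodComparison-class].
#'
#' @inheritParams blandAltman
#' @param ids case identifiers.
#' @param referenceStatus optional reference Pos/Neg calls.
#' @param cutoff ratio cutoff for misclassification (default 2.0).
#' @return A [MethodComparison-class].
#' @export
compareMethods <- function(method, reference, ids = seq_along(method),
                           referenceStatus = NULL, cutoff = 2.0,
                           sidedness = "two_sided") {
  mc <- blandAltman(method, reference, sidedness)
  if (!is.null(referenceStatus)) {
    mt <- misclassificationTable(method, referenceStatus, ids, cutoff)
    mc@misclassified <- as.integer(mt$misclassified)
    mc@falsePositives <- mt$false_positives
    mc@falseNegatives <- mt$false_negatives
  }
  mc
}

#' Bland-Altman plot
#'
#' Scatter of per-case differences against per-case means, with the bias
#' (red), the limits of agreement (blue/green) and their 95% confidence
#' bands (shaded).
#'
#' @param method,reference paired measurement vectors.
#' @param file optional PNG/SVG path; `NULL` plots to the active device.
#' @param main plot title.
#' @return The [MethodComparison-class], invisibly.
#' @export
plotBlandAltman <- function(method, reference, file = NULL,
                            main = "Bland-Altman agreement") {
  mc <- blandAltman(method, reference)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      png = grDevices::png(file, width = 900, height = 700, res = 120),
      svg = grDevices::svg(file, width = 7.5, height = 5.8),
      stop("unsupported plot format '.", ext, "'"))
    on.exit(grDevices::dev.off())
  }
  avg <- (method + reference) / 2
  d <- method - reference
  n <- mc@nPairs
  seBias <- mc@sdDiff / sqrt(n)
  seLoa <- mc@sdDiff * sqrt(3 / n)
  tq <- stats::qt(0.975, n - 1)
  ylim <- range(d, mc@loaLow - tq * seLoa, mc@loaHigh + tq * seLoa)
  plot(avg, d, pch = 19, col = "grey30", xlab = "Mean of methods",
       ylab = "Difference (method - reference)", main = main,
       ylim = ylim)
  band <- function(center, se, col) {
    graphics::rect(graphics::par("usr")[1], center - tq * se,
                   graphics::par("usr")[2], center + tq * se,
                   col = col, border = NA)
  }
  band(mc@bias, seBias, grDevices::adjustcolor("red", 0.12))
  band(mc@loaLow, seLoa, grDevices::adjustcolor("green4", 0.10))
  band(mc@loaHigh, seLoa, grDevices::adjustcolor("blue", 0.10))
  graphics::abline(h = mc@bias, col = "red", lwd = 2)
  graphics::abline(h = mc@loaHigh, col = "blue", lwd = 2, lty = 2)
  graphics::abline(h = mc@loaLow, col = "green4", lwd = 2, lty = 2)
  graphics::points(avg, d, pch = 19, col = "grey30")
  invisible(mc)
}

#' Bundled method-vs-expert reference scores
#'
#' Loads the packaged comparison dataset of 33 SISH regions: per-region
#' detected-nucleus counts, CEP17-qualified nucleus counts, summed HER2
#' and CEP17 signals, the automated HER2/CEP17 ratio, and the expert's
#' manual ratio and amplification call. Two region identifiers appear
#' twice with differing totals, as printed in the source material; all 33
#' rows are retained because the agreement statistics only reproduce over
#' the full set.
#'
#' @return `data.frame` with columns `image_id`, `group`,
#'   `detected_nuclei`, `nuclei_with_2_cep17`, `her2_signals`,
#'   `cep17_signals`, `method_ratio`, `expert_ratio`, `expert_status`.
#' @export
referenceScores <- function() {
  path <- system.file("extdata", "reference_scores.csv",
                      package = "SISHscore", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(image_id = "character"))
}
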