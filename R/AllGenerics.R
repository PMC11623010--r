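#' Accessors for package classes
#'
#' `pixels`, `resolutionUm` and `imageId` read the slots of a
#' [RoiImage-class]; `her2Ratio`, `amplificationStatus` and `nQuantified`
#' read a [ScoreResult-class]; `bias` and `limitsOfAgreement` read a
#' [MethodComparison-class].
#'
#' @param x object.
#' @return The corresponding slot value; `limitsOfAgreement` returns a
#'   named numeric vector `c(low, high)`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("resolutionUm", function(x) standardGeneric("resolutionUm"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("her2Ratio", function(x) standardGeneric("her2Ratio"))
#' @rdname accessors
#' @export
setGeneric("amplificationStatus",
           function(x) standardGeneric("amplificationStatus"))
#' @rdname accessors
#' @export
setGeneric("nQuantified", function(x) standardGeneric("nQuantified"))
#' @rdname accessors
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))
#' @rdname accessors
#' @export
setGeneric("limitsOfAgreement",
           function(x) standardGeneric("limitsOfAgreement"))

#' @rdname accessors
setMethod("pixels", "RoiImage", function(x) x@pixels)
#' @rdname accessors
setMethod("resolutionUm", "RoiImage", function(x) x@resolution)
#' @rdname accessors
setMethod("imageId", "RoiImage", function(x) x@imageId)
#' @rdname accessors
setMethod("her2Ratio", "ScoreResult", function(x) x@ratio)
#' @rdname accessors
setMethod("amplificationStatus", "ScoreResult", function(x) x@status)
#' @rdname accessors
setMethod("nQuantified", "ScoreResult", function(x) x@nQuantified)
#' @rdname accessors
setMethod("bias", "MethodComparison", function(x) x@bias)
#' @rdname accessors
setMethod("limitsOfAgreement", "MethodComparison",
          function(x) c(low = x@loaLow, high = x@loaHigh))

setMethod("show", "RoiImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RoiImage '%s': %d x %d px, %.3g um/px (%.1f x %.1f um)\n",
              object@imageId, d[1], d[2], object@resolution,
              d[1] * object@resolution, d[2] * object@resolution))
})

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf("ScoreResult '%s'\n", object@imageId))
  cat(sprintf("  nuclei quantified : %d%s\n", object@nQuantified,
              if (object@lowConfidence) " (low confidence)" else ""))
  cat(sprintf("  HER2 / CEP17      : %d / %d\n",
              as.integer(object@totalHer2), as.integer(object@totalCep17)))
  cat(sprintf("  ratio             : %.2f\n",
              roundHalfAway(object@ratio, 2)))
  cat(sprintf("  copies/nucleus    : %.2f\n",
              roundHalfAway(object@copiesPerNucleus, 2)))
  cat(sprintf("  status            : %s\n", object@status))
  flags <- c(if (object@fallbackUsed) "single-CEP17 fallback",
             if (object@extraSetCounted) "extra set counted")
  if (length(flags)) cat("  flags             :", paste(flags,
                                                        collapse = ", "), "\n")
})

setMethod("show", "MethodComparison", function(object) {
  cat(sprintf("MethodComparison over %d pairs\n", object@nPairs))
  cat(sprintf("  bias (method - reference): %.2f\n",
              roundHalfAway(object@bias, 2)))
  cat(sprintf("  limits of agreement      : %.2f to %.2f\n",
              roundHalfAway(object@loaLow, 2),
              roundHalfAway(object@loaHigh, 2)))
  cat(sprintf("  paired t-test (%s)  : t = %.3f, p = %.3f\n",
              object@sidedness, object@tStatistic, object@pValue))
  cat(sprintf("  misclassified            : %d (FP: %s; FN: %s)\n",
              object@misclassified,
              paste(object@falsePositives, collapse = ","),
              paste(object@falseNegatives, collapse = ",")))
})

setMethod("show", "SegmentationBackend", function(object) {
  cat(sprintf("SegmentationBackend '%s'\n", object@name))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d nuclei, %d dot entities, %d x %d px (seed %d)\n",
    nrow(object@nuclei), nrow(object@dots), object@imageSize[1],
    object@imageSize[2], object@seed))
  if (!is.null(object@expected$ratio))
    cat(sprintf("  expected totals %d/%d, ratio %.2f, status %s\n",
                object@expected$totalHer2, object@expected$totalCep17,
                object@expected$ratio, object@expected$status))
})
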