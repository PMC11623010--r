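#' @import methods
NULL

#' RoiImage: an RGB region of interest with physical calibration
#'
#' Container for one SISH region of interest (ROI). Pixels are stored as a
#' numeric `H x W x 3` array; freshly loaded images hold 8-bit intensities
#' in `[0, 255]`, while normalized images hold values in `[0, 1]`. The
#' physical resolution (micrometres per pixel) is required to convert the
#' physical size bounds of probe signals and nuclei into pixel areas.
#'
#' @slot pixels numeric array, `H x W x 3` (rows, columns, RGB channels).
#' @slot resolution single positive numeric, micrometres per pixel.
#' @slot imageId single character identifier.
#'
#' @seealso [RoiImage()], [readRoi()], [normalizeRoi()]
#' @exportClass RoiImage
setClass("RoiImage",
  representation(pixels = "array", resolution = "numeric",
                 imageId = "character"))

setValidity("RoiImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must have at least one row and one column")
  if (anyNA(p) || any(!is.finite(p)))
    return("pixels must be finite and non-missing")
  if (min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    return("resolution (um/pixel) must be a single positive number")
  if (length(object@imageId) != 1L || is.na(object@imageId))
    return("imageId must be a single string")
  TRUE
})

#' Construct a RoiImage
#'
#' @param pixels numeric `H x W x 3` array of channel intensities, either
#'   8-bit (`[0, 255]`) or normalized (`[0, 1]`).
#' @param resolution micrometres per pixel (default 0.13, the 40x scan
#'   resolution this pipeline is designed for).
#' @param imageId character identifier for the ROI.
#' @return A [RoiImage-class] object.
#' @examples
#' px <- array(255, dim = c(8, 8, 3))
#' roi <- RoiImage(px, resolution = 0.13, imageId = "blank")
#' dim(pixels(roi))
#' @export
RoiImage <- function(pixels, resolution = 0.13, imageId = "roi") {
  new("RoiImage", pixels = pixels, resolution = as.numeric(resolution),
      imageId = as.character(imageId))
}

#' SegmentationBackend: the nucleus segmentation contract
#'
#' A backend is any deterministic function mapping a [RoiImage-class] to an
#' integer label matrix (0 = background, k > 0 = nucleus instance k) of the
#' same height and width. The bundled classical backend
#' ([watershedBackend()]) thresholds nuclear stain, fills holes left by
#' probe dots and separates touching nuclei by a distance-transform
#' watershed; [labelBackend()] wraps a precomputed label map, e.g. the
#' output of an external deep-learning instance segmenter.
#'
#' @slot name single character backend name.
#' @slot fun function of `(image, config)` returning an integer matrix.
#' @exportClass SegmentationBackend
setClass("SegmentationBackend",
  representation(name = "character", fun = "function"))

setValidity("SegmentationBackend", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("backend name must be a non-empty string")
  TRUE
})

#' ScoreResult: per-ROI HER2 quantification result
#'
#' @slot imageId identifier of the scored ROI.
#' @slot nQuantified number of nuclei in the final selection.
#' @slot totalHer2,totalCep17 summed signal counts over the selection.
#' @slot ratio raw HER2/CEP17 ratio (unrounded; reports round to 2
#'   decimals, half away from zero).
#' @slot copiesPerNucleus mean HER2 signals per quantified nucleus.
#' @slot status one of `"Positive"`, `"Negative"`, `"Equivocal"`.
#' @slot fallbackUsed TRUE when the single-CEP17 fallback admitted nuclei.
#' @slot extraSetCounted TRUE when a second set of nuclei was counted
#'   because the copy number fell in the recount band.
#' @slot lowConfidence TRUE when fewer than the requested number of nuclei
#'   qualified.
#' @slot detectedNuclei nuclei found by the segmentation backend.
#' @slot nucleiWithMinCep17 nuclei passing the CEP17 qualification rule.
#' @exportClass ScoreResult
setClass("ScoreResult",
  representation(imageId = "character", nQuantified = "integer",
                 totalHer2 = "numeric", totalCep17 = "numeric",
                 ratio = "numeric", copiesPerNucleus = "numeric",
                 status = "character", fallbackUsed = "logical",
                 extraSetCounted = "logical", lowConfidence = "logical",
                 detectedNuclei = "integer",
                 nucleiWithMinCep17 = "integer"))

setValidity("ScoreResult", function(object) {
  if (object@nQuantified < 1L) return("nQuantified must be positive")
  if (object@totalHer2 < 0 || object@totalCep17 < 0)
    return("signal totals must be non-negative")
  if (!object@status %in% c("Positive", "Negative", "Equivocal"))
    return("status must be Positive, Negative or Equivocal")
  if (object@totalCep17 > 0 &&
      abs(object@ratio - object@totalHer2 / object@totalCep17) > 1e-9)
    return("ratio must equal totalHer2 / totalCep17")
  TRUE
})

#' MethodComparison: Bland-Altman agreement between method and reference
#'
#' Holds the paired-comparison statistics between automated and reference
#' HER2/CEP17 ratios: bias (mean difference), sample SD of the
#' differences, 1.96-SD limits of agreement, a paired t-test, and the
#' misclassification table at a ratio cutoff.
#'
#' @slot nPairs number of paired observations.
#' @slot bias mean of method minus reference.
#' @slot sdDiff sample (n-1) standard deviation of the differences.
#' @slot loaLow,loaHigh limits of agreement, `bias +/- 1.96 * sdDiff`.
#' @slot tStatistic,pValue,sidedness paired t-test of zero mean difference.
#' @slot misclassified number of status disagreements at the cutoff.
#' @slot falsePositives,falseNegatives identifiers of disagreeing cases.
#' @exportClass MethodComparison
setClass("MethodComparison",
  representation(nPairs = "integer", bias = "numeric", sdDiff = "numeric",
                 loaLow = "numeric", loaHigh = "numeric",
                 tStatistic = "numeric", pValue = "numeric",
                 sidedness = "character", misclassified = "integer",
                 falsePositives = "character",
                 falseNegatives = "character"))

setValidity("MethodComparison", function(object) {
  if (object@nPairs < 2L) return("nPairs must be at least 2")
  if (abs((object@bias - object@loaLow) - (object@loaHigh - object@bias)) >
      1e-9)
    return("limits of agreement must be symmetric about the bias")
  if (!object@sidedness %in% c("two_sided", "greater", "less"))
    return("sidedness must be two_sided, greater or less")
  if (object@misclassified !=
      length(object@falsePositives) + length(object@falseNegatives))
    return("misclassified must equal |falsePositives| + |falseNegatives|")
  TRUE
})

#' SyntheticTruth: exhaustive ground truth for a simulated ROI
#'
#' @slot nuclei data.frame with one row per planted nucleus: `label`,
#'   0-based `row`/`col` center, semi-axes `semiR`/`semiC` (pixels),
#'   `angle` (radians), planted `her2`/`cep17` signal counts, and flags
#'   `truncated` (crosses the image border) and `overlapped` (member of a
#'   planted >50 percent overlap pair).
#' @slot dots data.frame with one row per rendered dot entity: `nucleus`
#'   label, `channel`, 0-based `row`/`col`, `radiusPx`, `faint` flag and
#'   `multiplicity` (>1 for merged clusters).
#' @slot expected list with `totalHer2`, `totalCep17`, `ratio`, `status`
#'   (cutoff 2.0), `nQualifying` and `fallback` over qualifying nuclei
#'   (interior, non-overlapped, CEP17 >= 2; CEP17 >= 1 when the fallback
#'   is the only option).
#' @slot imageSize integer `(H, W)`.
#' @slot resolution micrometres per pixel.
#' @slot seed the generator seed.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(nuclei = "data.frame", dots = "data.frame",
                 expected = "list", imageSize = "integer",
                 resolution = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    return("imageSize must be two positive integers")
  if (object@resolution <= 0) return("resolution must be positive")
  if (nrow(object@dots) && any(object@dots$radiusPx <= 0))
    return("dots$radiusPx must be positive")
  if (nrow(object@nuclei) &&
      any(object@nuclei$her2 < 0 | object@nuclei$cep17 < 0))
    return("planted signal counts must be non-negative")
  TRUE
})
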