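#' Min-max or percentile intensity normalization
#'
#' Linearly rescales a numeric grid so its values fall in a target range.
#' In `"value_range"` mode each element is mapped by
#' \deqn{x_i' = \frac{x_i - \min(x)}{\max(x) - \min(x)}
#'       (upper - lower) + lower,}
#' so the output minimum equals `lower` and the output maximum equals
#' `upper` whenever the input is non-constant. In `"percentile"` mode
#' `lower` and `upper` are read as percentile ranks (e.g. 1 and 99.8): the
#' corresponding input percentiles replace the minimum and maximum, the
#' map targets `[0, 1]`, and the result is clipped to `[0, 1]`. Percentile
#' clipping makes the stretch robust to a handful of extreme pixels.
#'
#' A constant input cannot be rescaled; every element is then set to the
#' lower bound (the limit of the formula as max approaches min) and a
#' warning is emitted, so blank tiles do not abort batch runs.
#'
#' @param values numeric vector, matrix or array.
#' @param lower,upper target range bounds (`value_range`) or percentile
#'   ranks in `[0, 100]` (`percentile`); `lower < upper`.
#' @param mode `"value_range"` (the literal min-max formula, default) or
#'   `"percentile"`.
#' @return Numeric object of the same shape as `values`.
#' @examples
#' normalizeValues(c(0, 5, 10), 0, 100)
#' normalizeValues(matrix(1:12, 3), 1, 99.8, mode = "percentile")
#' @export
normalizeValues <- function(values, lower = 0, upper = 1,
                            mode = c("value_range", "percentile")) {
  mode <- match.arg(mode)
  if (length(values) == 0L) stop("values must be non-empty")
  if (!is.numeric(values) || anyNA(values))
    stop("values must be numeric and non-missing")
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("normalization bounds must satisfy lower < upper")
  out <- values
  if (mode == "value_range") {
    lo <- min(values); hi <- max(values)
    if (hi == lo) {
      warning("constant input: all values mapped to the lower bound")
      out[] <- lower
      return(out)
    }
    out[] <- (values - lo) / (hi - lo) * (upper - lower) + lower
  } else {
    if (lower < 0 || upper > 100)
      stop("percentile mode bounds must be percentile ranks in [0, 100]")
    q <- stats::quantile(values, c(lower, upper) / 100, names = FALSE)
    if (q[2] == q[1]) {
      warning("constant input: all values mapped to the lower bound")
      out[] <- 0
      return(out)
    }
    out[] <- pmin(pmax((values - q[1]) / (q[2] - q[1]), 0), 1)
  }
  out
}

#' Gamma adjustment of a unit-range grid
#'
#' Applies `clip(gain * values^gamma, 0, 1)`. Together with the
#' normalization this standardizes contrast before color thresholding;
#' `gamma < 1` lifts mid-tones (making dark probe dots stand apart from
#' nuclear stain), `gain > 1` saturates highlights. The supported
#' operating points are `(gamma, gain)` of (0.9, 1), (0.5, 1) and
#' (0.5, 2); (0.5, 1) is the default used throughout the pipeline.
#'
#' @param values numeric grid with all elements in `[0, 1]`.
#' @param gamma positive exponent.
#' @param gain positive multiplier.
#' @return Numeric object of the same shape, in `[0, 1]`.
#' @examples
#' gammaAdjust(0.25, gamma = 0.5, gain = 1)  # 0.5
#' gammaAdjust(0.25, gamma = 0.5, gain = 2)  # 1 after clipping
#' @export
gammaAdjust <- function(values, gamma = 0.5, gain = 1) {
  if (!is.numeric(values) || anyNA(values))
    stop("values must be numeric and non-missing")
  if (min(values) < 0 || max(values) > 1)
    stop("gammaAdjust expects values in [0, 1]; normalize first")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  if (!is.finite(gain) || gain <= 0) stop("gain must be positive")
  out <- values
  out[] <- pmin(pmax(gain * values^gamma, 0), 1)
  out
}

#' Normalize and gamma-adjust a RoiImage
#'
#' Runs [normalizeValues()] and [gammaAdjust()] on each RGB channel
#' independently (channels are never mixed, preserving the color identity
#' of the probes) and returns a [RoiImage-class] with pixels in `[0, 1]`,
#' ready for signal detection.
#'
#' @param roi a [RoiImage-class].
#' @param lower,upper,mode passed to [normalizeValues()]; the default
#'   stretches each channel to `[0, 1]`.
#' @param gamma,gain passed to [gammaAdjust()]; `gamma = NULL` skips the
#'   adjustment.
#' @return A normalized [RoiImage-class].
#' @export
normalizeRoi <- function(roi, lower = 0, upper = 1, mode = "value_range",
                         gamma = 0.5, gain = 1) {
  stopifnot(is(roi, "RoiImage"))
  px <- roi@pixels
  for (ch in 1:3) {
    v <- normalizeValues(px[, , ch], lower, upper, mode)
    if (!is.null(gamma)) v <- gammaAdjust(v, gamma, gain)
    px[, , ch] <- v
  }
  RoiImage(px, roi@resolution, roi@imageId)
}
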