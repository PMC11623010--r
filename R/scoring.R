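#' Status thresholds for amplification calling
#'
#' Three calling modes are supported. `binary_ratio` (default) calls
#' Positive when the HER2/CEP17 ratio is at or above `binary_cutoff`
#' (2.0), Negative otherwise — the reading consistent with the reference
#' comparisons this package reproduces. `three_way_ratio` adds an
#' Equivocal band: Negative below `negative_below` (1.8), Equivocal in
#' `[1.8, 2.0]`, Positive above. `asco_full` applies the ratio rule first
#' and then, for sub-cutoff ratios, the HER2 copy-number bands: at or
#' above `copy_positive` (6.0) Positive, in `[copy_equivocal_low,
#' copy_positive)` Equivocal, otherwise Negative.
#'
#' @param binary_cutoff Positive/Negative ratio cutoff (default 2.0).
#' @param negative_below lower Equivocal bound (default 1.8).
#' @param equivocal_upper upper Equivocal bound (default 2.0).
#' @param copy_positive copies-per-nucleus Positive bound (default 6.0).
#' @param copy_equivocal_low copies-per-nucleus Equivocal bound (4.0).
#' @param mode `"binary_ratio"`, `"three_way_ratio"` or `"asco_full"`.
#' @return Validated list of thresholds.
#' @export
statusThresholds <- function(binary_cutoff = 2.0, negative_below = 1.8,
                             equivocal_upper = 2.0, copy_positive = 6.0,
                             copy_equivocal_low = 4.0,
                             mode = c("binary_ratio", "three_way_ratio",
                                      "asco_full")) {
  mode <- match.arg(mode)
  if (negative_below > equivocal_upper)
    stop("negative_below must not exceed equivocal_upper")
  if (copy_equivocal_low > copy_positive)
    stop("copy_equivocal_low must not exceed copy_positive")
  list(binary_cutoff = binary_cutoff, negative_below = negative_below,
       equivocal_upper = equivocal_upper, copy_positive = copy_positive,
       copy_equivocal_low = copy_equivocal_low, mode = mode)
}

#' Rank nuclei by differentiation value
#'
#' Orders qualified nuclei by descending differentiation value
#' (`her2_count - cep17_count`) — the nuclei with the greatest excess of
#' HER2 over CEP17 signals are the best representatives for amplification
#' estimation. Ties break by higher `her2_count`, then lower `label`,
#' yielding a deterministic total order.
#'
#' @param records qualified nucleus records.
#' @return The same records, reordered.
#' @export
rankNuclei <- function(records) {
  ord <- order(-records$differentiation, -records$her2_count,
               records$label)
  records[ord, , drop = FALSE]
}

#' Select the top-ranked nuclei
#'
#' Takes the first `n` ranked nuclei (default 20). When fewer than `n`
#' are available, all of them are returned and the shortfall is signaled
#' through the `"lowConfidence"` attribute, so the caller can score
#' anyway while flagging the result.
#'
#' @param ranked records ordered by [rankNuclei()].
#' @param n selection size (default 20).
#' @return The selected records, with attribute `lowConfidence`.
#' @export
selectNuclei <- function(ranked, n = 20) {
  if (nrow(ranked) == 0L)
    stop("no quantifiable nuclei: cannot select a representative set")
  sel <- utils::head(ranked, n)
  attr(sel, "lowConfidence") <- nrow(ranked) < n
  sel
}

#' HER2/CEP17 ratio over a selection
#'
#' Sum of HER2 signal counts divided by the sum of CEP17 signal counts.
#' The raw value is returned; reports round to 2 decimals half away from
#' zero (see [roundHalfAway()]), while classification always uses the
#' unrounded value.
#'
#' @param selection selected nucleus records.
#' @return Single numeric ratio (unrounded).
#' @export
computeRatio <- function(selection) {
  if (nrow(selection) == 0L) stop("empty selection")
  totC <- sum(selection$cep17_count)
  if (totC == 0)
    stop("total CEP17 count is zero: no ratio is defined; ",
         "use the single-CEP17 fallback path (filterByCep17) upstream")
  sum(selection$her2_count) / totC
}

#' Mean HER2 copies per quantified nucleus
#'
#' @param selection selected nucleus records.
#' @return Total HER2 signals divided by the number of selected nuclei.
#' @export
copiesPerNucleus <- function(selection) {
  if (nrow(selection) == 0L) stop("empty selection")
  sum(selection$her2_count) / nrow(selection)
}

#' Classify amplification status
#'
#' @param ratio HER2/CEP17 ratio (unrounded).
#' @param copies HER2 copies per nucleus; only consulted in `asco_full`
#'   mode.
#' @param thresholds a [statusThresholds()] list.
#' @return `"Positive"`, `"Negative"` or `"Equivocal"`.
#' @examples
#' classifyStatus(2.59)  # Positive
#' classifyStatus(1.19)  # Negative
#' @export
classifyStatus <- function(ratio, copies = NA_real_,
                           thresholds = statusThresholds()) {
  stopifnot(is.finite(ratio), ratio >= 0)
  switch(thresholds$mode,
    binary_ratio = if (ratio >= thresholds$binary_cutoff) "Positive"
                   else "Negative",
    three_way_ratio =
      if (ratio < thresholds$negative_below) "Negative"
      else if (ratio <= thresholds$equivocal_upper) "Equivocal"
      else "Positive",
    asco_full = {
      if (ratio >= thresholds$binary_cutoff) "Positive"
      else if (is.finite(copies) && copies >= thresholds$copy_positive)
        "Positive"
      else if (is.finite(copies) &&
               copies >= thresholds$copy_equivocal_low) "Equivocal"
      else "Negative"
    })
}

#' Score an ROI from its qualified nucleus records
#'
#' The quantification workflow: rank by differentiation value, select the
#' first `nFirst` nuclei, compute the ratio and copies per nucleus. If the
#' copy number falls in the recount band
#' `[copy_equivocal_low, copy_positive)` and further ranked nuclei exist,
#' the next `nExtra` nuclei are added, totals are recomputed over the
#' enlarged set (at least 40 nuclei when available) and
#' `extraSetCounted` is flagged. Classification uses the configured mode
#' on the unrounded ratio.
#'
#' @param records qualified nucleus records (after [qualifyNuclei()]).
#' @param thresholds a [statusThresholds()] list.
#' @param nFirst,nExtra first and additional selection sizes (20/20).
#' @param fallbackUsed propagated from [filterByCep17()].
#' @param imageId identifier stored in the result.
#' @param detectedNuclei,nucleiWithMinCep17 provenance counts for
#'   reporting.
#' @return A [ScoreResult-class].
#' @export
scoreNuclei <- function(records, thresholds = statusThresholds(),
                        nFirst = 20, nExtra = 20, fallbackUsed = FALSE,
                        imageId = "roi",
                        detectedNuclei = NA_integer_,
                        nucleiWithMinCep17 = NA_integer_) {
  if (nrow(records) == 0L)
    stop("no qualified nuclei to score")
  ranked <- rankNuclei(records)
  sel <- selectNuclei(ranked, nFirst)
  lowConf <- attr(sel, "lowConfidence")
  copies <- copiesPerNucleus(sel)
  extra <- FALSE
  if (copies >= thresholds$copy_equivocal_low &&
      copies < thresholds$copy_positive && nrow(ranked) > nrow(sel)) {
    sel <- utils::head(ranked, min(nFirst + nExtra, nrow(ranked)))
    copies <- copiesPerNucleus(sel)
    extra <- TRUE
  }
  ratio <- computeRatio(sel)
  status <- classifyStatus(ratio, copies, thresholds)
  new("ScoreResult", imageId = imageId, nQuantified = nrow(sel),
      totalHer2 = sum(sel$her2_count), totalCep17 = sum(sel$cep17_count),
      ratio = ratio, copiesPerNucleus = copies, status = status,
      fallbackUsed = fallbackUsed, extraSetCounted = extra,
      lowConfidence = lowConf,
      detectedNuclei = as.integer(detectedNuclei),
      nucleiWithMinCep17 = as.integer(nucleiWithMinCep17))
}
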