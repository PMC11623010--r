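#' Foreground (tissue) mask by background removal
#'
#' SISH backgrounds are near-white. A pixel is background when every
#' channel exceeds the whiteness threshold; the complement is the tissue
#' foreground within which probe signals are sought.
#'
#' @param roi a normalized [RoiImage-class] (pixels in `[0, 1]`).
#' @param whitenessMin background threshold on the minimum channel value,
#'   in `[0, 1]`. Setting it to 0 classifies every pixel as background-free
#'   (full-true mask).
#' @return Logical `H x W` matrix, `TRUE` where tissue is present.
#' @export
removeBackground <- function(roi, whitenessMin = 0.9) {
  stopifnot(is(roi, "RoiImage"))
  px <- roi@pixels
  if (max(px) > 1) px <- px / 255
  minChan <- pmin(px[, , 1], px[, , 2], px[, , 3])
  minChan < whitenessMin
}

#' Detect HER2 or CEP17 probe signals
#'
#' Four-step detection on a normalized ROI: (1) background removal;
#' (2) per-channel color thresholding in HSV space — HER2 candidates are
#' dark and chromatically neutral (value <= `her2_value_max`, saturation
#' <= `her2_saturation_max`), CEP17 candidates are red (hue within
#' `cep17_hue_halfwidth_deg` of 0, saturation >= `cep17_saturation_min`,
#' value within `[cep17_value_min, cep17_value_max]`); (3) grouping of
#' candidate pixels into 8-connected components; (4) discarding components
#' outside the physical size bounds, converted to pixel areas through the
#' ROI resolution.
#'
#' When `cluster_split` is enabled, merged probe clusters are decomposed
#' by area: the per-component signal count is
#' `max(1, round(area / median singleton area))`, where the median
#' singleton area is the lower-value median of surviving components whose
#' area does not exceed twice the smallest surviving area. This mirrors
#' how pathologists count large signal clusters as multiples.
#'
#' Each spot carries a contrast in `[0, 1]`: mean darkness (`1 - value`)
#' for HER2, mean `saturation * redness` for CEP17 (redness = 1 minus the
#' angular hue distance to pure red over 180 degrees). Faint spots are
#' removed downstream by [removeFaint()].
#'
#' @param roi a normalized [RoiImage-class] (pixels in `[0, 1]`).
#' @param channel `"HER2"` or `"CEP17"`.
#' @param config list of detection parameters; see
#'   [defaultConfig()]`$signals` for the keys and defaults.
#' @return `data.frame` with one row per spot: `channel`, `row`, `col`
#'   (0-based centroid, pixel-center convention), `area_px`,
#'   `signal_count`, `contrast`.
#' @export
detectSpots <- function(roi, channel = c("HER2", "CEP17"),
                        config = defaultConfig()$signals) {
  stopifnot(is(roi, "RoiImage"))
  channel <- match.arg(channel)
  cfg <- utils::modifyList(defaultConfig()$signals, as.list(config))
  px <- roi@pixels
  if (max(px) > 1) px <- px / 255
  fg <- removeBackground(roi, cfg$whiteness_min)
  hsv <- rgbToHsv(px)
  if (channel == "HER2") {
    cand <- hsv$v <= cfg$her2_value_max & hsv$s <= cfg$her2_saturation_max
  } else {
    cand <- hueDistToRed(hsv$h) <= cfg$cep17_hue_halfwidth_deg &
      hsv$s >= cfg$cep17_saturation_min &
      hsv$v >= cfg$cep17_value_min & hsv$v <= cfg$cep17_value_max
  }
  cand <- cand & fg
  empty <- data.frame(channel = character(), row = numeric(),
                      col = numeric(), area_px = integer(),
                      signal_count = integer(), contrast = numeric())
  if (!any(cand)) return(empty)
  lab <- labelComponents8(cand)
  n <- max(lab)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  areas <- tabulate(labs, n)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  areaMin <- diameterUmToAreaPx(cfg$min_spot_diameter_um, roi@resolution)
  areaMax <- diameterUmToAreaPx(cfg$max_spot_diameter_um, roi@resolution)
  keep <- which(areas >= areaMin & areas <= areaMax)
  if (!length(keep)) return(empty)
  inKeep <- labs %in% keep
  labsK <- labs[inKeep]
  grp <- match(labsK, keep)
  cr <- rowsum(rows[inKeep], grp) / areas[keep] - 1  # 0-based centroid
  cc <- rowsum(cols[inKeep], grp) / areas[keep] - 1
  if (channel == "HER2") {
    contrastPx <- 1 - hsv$v
  } else {
    contrastPx <- hsv$s * (1 - hueDistToRed(hsv$h) / 180)
  }
  contr <- rowsum(contrastPx[idx][inKeep], grp) / areas[keep]
  counts <- rep(1L, length(keep))
  if (isTRUE(cfg$cluster_split) && length(keep) > 0) {
    minObs <- min(areas[keep])
    singles <- areas[keep][areas[keep] <= 2 * minObs]
    medSingle <- medianLow(singles)
    counts <- pmax(1L, as.integer(round(areas[keep] / medSingle)))
  }
  data.frame(channel = channel, row = as.numeric(cr), col = as.numeric(cc),
             area_px = as.integer(areas[keep]),
             signal_count = counts, contrast = as.numeric(contr))
}

#' Remove faint spots
#'
#' Drops spots whose contrast falls below the threshold — the paper-style
#' cleanup of very faint signals that are likely noise. Order is
#' preserved; the output is always a subset of the input.
#'
#' @param spots spot `data.frame` from [detectSpots()].
#' @param faintContrastMin minimum contrast to survive, in `[0, 1]`.
#' @return Filtered spot `data.frame`.
#' @export
removeFaint <- function(spots, faintContrastMin = 0.15) {
  stopifnot(is.data.frame(spots), "contrast" %in% names(spots))
  spots[spots$contrast >= faintContrastMin, , drop = FALSE]
}

#' Export and import detected spots
#'
#' `writeSpots` writes a CSV (`image_id`, `channel`, `row`, `col`,
#' `area_px`, `signal_count`, `contrast`) or, for a `.json` path, a
#' detections document consumed by the nucleus-assignment stage;
#' `readSpots` reads either format back.
#'
#' @param spots spot `data.frame`.
#' @param path output path (`.csv` or `.json`).
#' @param imageId identifier stored alongside the spots.
#' @return `writeSpots` returns `path` invisibly; `readSpots` returns a
#'   spot `data.frame`.
#' @export
writeSpots <- function(spots, path, imageId = "roi") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(cbind(image_id = imageId, spots), path,
                     row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(image_id = imageId, spots = spots), path,
                         dataframe = "columns", digits = NA,
                         auto_unbox = TRUE)
  } else stop("unsupported spot format '.", ext, "'")
  invisible(path)
}

#' @rdname writeSpots
#' @export
readSpots <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    df$image_id <- NULL
  } else if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(doc$spots)
  } else stop("unsupported spot format '.", ext, "'")
  df
}
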