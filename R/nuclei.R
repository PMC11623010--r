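#' Classical watershed segmentation backend
#'
#' The default nucleus segmenter: thresholds non-background, non-spot
#' stain (the bluish/purple nuclear hue window), fills the holes punched
#' by probe dots, computes a distance transform and separates touching
#' instances by watershed seeded at its regional maxima. Instances below
#' the minimum nucleus area (physical units, default 20 square
#' micrometres) are discarded as debris. Deterministic for a fixed input.
#'
#' The watershed `min_separation_um` is the minimum distance-transform
#' height (converted to pixels) between two seeds for them to count as
#' separate nuclei; larger values merge shallowly-separated instances.
#'
#' @param config list overriding keys of [defaultConfig()]`$nuclei`.
#' @return A [SegmentationBackend-class].
#' @seealso [segmentNuclei()], [labelBackend()]
#' @export
watershedBackend <- function(config = list()) {
  cfg <- utils::modifyList(defaultConfig()$nuclei, as.list(config))
  new("SegmentationBackend", name = "watershed", fun = function(roi, ...) {
    px <- roi@pixels
    if (max(px) > 1) px <- px / 255
    sig <- defaultConfig()$signals
    fg <- removeBackground(roi, sig$whiteness_min)
    hsv <- rgbToHsv(px)
    her2cand <- hsv$v <= sig$her2_value_max & hsv$s <= sig$her2_saturation_max
    cepcand <- hueDistToRed(hsv$h) <= sig$cep17_hue_halfwidth_deg &
      hsv$s >= sig$cep17_saturation_min &
      hsv$v >= sig$cep17_value_min & hsv$v <= sig$cep17_value_max
    body <- fg & !her2cand & !cepcand &
      hsv$h >= cfg$hue_min_deg & hsv$h <= cfg$hue_max_deg &
      hsv$s >= cfg$saturation_min
    # probe dots sit inside nuclei: union them into the mask so they do
    # not punch holes; isolated extranuclear dot clusters fall below the
    # minimum nucleus area and are dropped after labeling
    nuc <- body | (fg & (her2cand | cepcand))
    if (!any(nuc)) return(matrix(0L, nrow(nuc), ncol(nuc)))
    nuc <- EBImage::fillHull(nuc)
    dm <- EBImage::distmap(nuc)
    tolPx <- max(1, cfg$min_separation_um / roi@resolution)
    ws <- EBImage::watershed(dm, tolerance = tolPx, ext = 1)
    lab <- matrix(as.integer(ws), nrow(nuc), ncol(nuc))
    minArea <- cfg$min_area_um2 / roi@resolution^2
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L], max(lab))
      small <- which(areas > 0 & areas < minArea)
      if (length(small)) lab <- relabelDrop(lab, small)
    }
    lab
  })
}

#' Precomputed label-map backend
#'
#' Wraps an existing instance label map — e.g. exported by an external
#' star-convex deep-learning segmenter — behind the
#' [SegmentationBackend-class] contract, so the downstream qualification
#' filters and scoring run unchanged.
#'
#' @param labels integer label matrix, or a path to a 16-bit TIFF label
#'   map (see [readLabelMap()]).
#' @return A [SegmentationBackend-class].
#' @export
labelBackend <- function(labels) {
  if (is.character(labels)) labels <- readLabelMap(labels)
  stopifnot(is.matrix(labels))
  force(labels)
  new("SegmentationBackend", name = "labelmap", fun = function(roi, ...) {
    if (!all(dim(labels) == dim(roi@pixels)[1:2]))
      stop("label map dimensions do not match the image")
    labels
  })
}

#' Segment nuclei in an ROI
#'
#' Dispatches to the backend's segmentation function and validates the
#' returned label map. Backend failures are propagated with the backend
#' name attached.
#'
#' @param roi a normalized [RoiImage-class].
#' @param backend a [SegmentationBackend-class]; default the classical
#'   watershed backend.
#' @return Integer `H x W` label matrix (0 = background).
#' @export
segmentNuclei <- function(roi, backend = watershedBackend()) {
  stopifnot(is(roi, "RoiImage"), is(backend, "SegmentationBackend"))
  lab <- tryCatch(backend@fun(roi),
                  error = function(e) stop("segmentation backend '",
                                           backend@name, "' failed: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!is.matrix(lab) || !all(dim(lab) == dim(roi@pixels)[1:2]))
    stop("segmentation backend '", backend@name,
         "' returned a label map of the wrong shape")
  lab
}

#' Assign detected spots to nuclei
#'
#' Each spot contributes its `signal_count` to the nucleus whose label
#' covers the spot's rounded centroid; spots over background are ignored.
#' Every nucleus present in the label map yields one record, with zero
#' counts where nothing was assigned.
#'
#' @param labels integer label matrix from [segmentNuclei()].
#' @param spots spot `data.frame` (both channels concatenated is fine).
#' @return `data.frame` with one row per nucleus: `label`, `area_px`,
#'   `row`, `col` (0-based centroid), `her2_count`, `cep17_count`,
#'   `differentiation` (= her2 - cep17), `touches_border`,
#'   `max_overlap_fraction`, `qualified`.
#' @export
assignSpots <- function(labels, spots) {
  stopifnot(is.matrix(labels))
  n <- max(labels, 0L)
  labsIdx <- which(labels > 0L)
  labsVal <- labels[labsIdx]
  areas <- tabulate(labsVal, n)
  present <- which(areas > 0)
  rws <- ((labsIdx - 1L) %% nrow(labels))
  cls <- ((labsIdx - 1L) %/% nrow(labels))
  her2 <- integer(n); cep17 <- integer(n)
  if (nrow(spots)) {
    r <- round(spots$row) + 1L
    c <- round(spots$col) + 1L
    if (any(r < 1L | r > nrow(labels) | c < 1L | c > ncol(labels)))
      stop("spot centroid outside the label map: dimension mismatch ",
           "between the label map and the spots' source image")
    lab <- labels[cbind(r, c)]
    hit <- lab > 0L
    if (any(hit)) {
      isH <- spots$channel == "HER2"
      for (i in which(hit)) {
        if (isH[i]) her2[lab[i]] <- her2[lab[i]] + spots$signal_count[i]
        else cep17[lab[i]] <- cep17[lab[i]] + spots$signal_count[i]
      }
    }
  }
  cr <- rowsum(rws, labsVal)[, 1] / areas[present]
  cc <- rowsum(cls, labsVal)[, 1] / areas[present]
  data.frame(label = present, area_px = areas[present],
             row = as.numeric(cr), col = as.numeric(cc),
             her2_count = her2[present], cep17_count = cep17[present],
             differentiation = her2[present] - cep17[present],
             touches_border = FALSE, max_overlap_fraction = 0,
             qualified = TRUE)
}

#' Exclude border-truncated nuclei
#'
#' A nucleus whose mask includes any pixel on the image edge carries
#' incomplete information and is excluded from quantification. Excluded
#' records are marked `touches_border` and dropped from the qualified
#' stream.
#'
#' @param records nucleus records from [assignSpots()].
#' @param labels the label matrix the records derive from.
#' @return Filtered records (interior nuclei only).
#' @export
filterTruncated <- function(records, labels) {
  stopifnot(is.matrix(labels))
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- border[border > 0L]
  records$touches_border <- records$label %in% border
  records$qualified <- records$qualified & !records$touches_border
  records[!records$touches_border, , drop = FALSE]
}

#' Exclude heavily overlapping nuclei
#'
#' Polygon-based segmenters may emit overlapping instances. For each
#' nucleus the overlap fraction against every other instance is computed
#' on the rasterized regions as intersection area over the nucleus's own
#' area; any nucleus whose maximum fraction exceeds `maxOverlap` is
#' removed. Fractions are computed once on the full instance set and not
#' recomputed as nuclei are removed, so when two nuclei each exceed the
#' bound against the other, both are removed — a deterministic outcome
#' independent of instance ordering. Masks rasterized from a label map
#' cannot overlap and pass trivially (`outlines = NULL`).
#'
#' @param records nucleus records.
#' @param outlines named list of instance pixel sets (1-based linear
#'   indices into the image), one per record label; or `NULL` for
#'   label-map instances (no overlap possible).
#' @param maxOverlap maximum tolerated overlap fraction (default 0.5).
#' @return Filtered records with `max_overlap_fraction` filled in.
#' @export
filterOverlapping <- function(records, outlines = NULL, maxOverlap = 0.5) {
  if (is.null(outlines) || nrow(records) < 2L) {
    return(records)
  }
  labs <- as.character(records$label)
  if (!all(labs %in% names(outlines)))
    stop("outlines must be a named list covering every record label")
  sets <- lapply(outlines[labs], as.integer)
  n <- length(sets)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      if (inter > 0)
        frac[i] <- max(frac[i], inter / length(sets[[i]]))
    }
  }
  records$max_overlap_fraction <- frac
  keep <- frac <= maxOverlap
  records$qualified <- records$qualified & keep
  records[keep, , drop = FALSE]
}

#' Qualify nuclei by CEP17 signal count
#'
#' Quantification considers nuclei displaying at least `minCep17`
#' (default 2) CEP17 signals. In strongly amplified samples no nucleus may
#' meet that rule; when `allowFallback` is set and the strict set is
#' empty, nuclei with a single CEP17 signal are admitted instead and
#' `fallbackUsed` is flagged — mirroring the flexibility of manual
#' assessment in high-positivity cases.
#'
#' @param records nucleus records.
#' @param minCep17 minimum CEP17 count (default 2).
#' @param allowFallback allow the single-CEP17 relaxation (default TRUE).
#' @return `list(records = <filtered records>, fallbackUsed = <logical>)`.
#' @export
filterByCep17 <- function(records, minCep17 = 2, allowFallback = TRUE) {
  strict <- records[records$cep17_count >= minCep17, , drop = FALSE]
  if (nrow(strict) > 0L || !allowFallback)
    return(list(records = strict, fallbackUsed = FALSE))
  relaxed <- records[records$cep17_count >= 1, , drop = FALSE]
  list(records = relaxed, fallbackUsed = TRUE)
}

#' Run the full nucleus qualification cascade
#'
#' Fixed composition: border-truncation exclusion, then overlap exclusion,
#' then the CEP17 rule. The output is invariant to relabeling of instance
#' identifiers.
#'
#' @param records nucleus records from [assignSpots()].
#' @param labels label matrix (for border contact).
#' @param outlines optional overlapping instance pixel sets (see
#'   [filterOverlapping()]).
#' @param minCep17,allowFallback,maxOverlap rule parameters.
#' @return `list(records, fallbackUsed, stageCounts)` where `stageCounts`
#'   records the surviving count after each stage.
#' @export
qualifyNuclei <- function(records, labels, outlines = NULL, minCep17 = 2,
                          allowFallback = TRUE, maxOverlap = 0.5) {
  counts <- c(detected = nrow(records))
  records <- filterTruncated(records, labels)
  counts["interior"] <- nrow(records)
  records <- filterOverlapping(records, outlines, maxOverlap)
  counts["non_overlapping"] <- nrow(records)
  fb <- filterByCep17(records, minCep17, allowFallback)
  counts["cep17_qualified"] <- nrow(fb$records)
  list(records = fb$records, fallbackUsed = fb$fallbackUsed,
       stageCounts = counts)
}

#' Export nucleus records to CSV
#'
#' @param records nucleus records.
#' @param path CSV path.
#' @param imageId identifier column value.
#' @return `path`, invisibly.
#' @export
writeNucleusRecords <- function(records, path, imageId = "roi") {
  utils::write.csv(cbind(image_id = imageId, records), path,
                   row.names = FALSE)
  invisible(path)
}
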