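sishLog <- function(level, cfg, ...) {
  levels <- c(debug = 1, info = 2, warning = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$run$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Score one ROI end to end
#'
#' The full per-region workflow: channel-wise normalization and gamma
#' adjustment, HER2 and CEP17 spot detection with faint-signal removal,
#' nucleus segmentation, the qualification cascade
#' (truncation, overlap, CEP17 rule with fallback), then
#' differentiation-value ranking, selection and ratio scoring.
#'
#' @param roi a raw [RoiImage-class] (pixels in `[0, 255]`).
#' @param config pipeline configuration (see [defaultConfig()]).
#' @param backend optional [SegmentationBackend-class] overriding the
#'   configured one (e.g. [labelBackend()] with a precomputed map).
#' @return A [ScoreResult-class].
#' @examples
#' \donttest{
#' sc <- simulateRoi(syntheticPreset("amplified", seed = 7))
#' scoreImage(sc$image)
#' }
#' @export
scoreImage <- function(roi, config = defaultConfig(), backend = NULL) {
  stopifnot(is(roi, "RoiImage"))
  config <- validateConfig(config)
  norm <- normalizeRoi(roi, config$normalize$lower,
                       config$normalize$upper, config$normalize$mode,
                       gamma = config$gamma$gamma,
                       gain = config$gamma$gain)
  spots <- rbind(detectSpots(norm, "HER2", config$signals),
                 detectSpots(norm, "CEP17", config$signals))
  spots <- removeFaint(spots, config$signals$faint_contrast_min)
  if (is.null(backend)) backend <- watershedBackend(config$nuclei)
  labels <- segmentNuclei(norm, backend)
  if (max(labels) == 0L)
    stop("no qualified nuclei: segmentation found no nuclei")
  records <- assignSpots(labels, spots)
  q <- qualifyNuclei(records, labels,
                     minCep17 = config$nuclei$min_cep17,
                     allowFallback = config$nuclei$allow_fallback,
                     maxOverlap = config$nuclei$max_overlap)
  if (nrow(q$records) == 0L) {
    failed <- names(which(q$stageCounts == 0))[1]
    stage <- c(detected = "segmentation",
               interior = "border-truncation filter",
               non_overlapping = "overlap filter",
               cep17_qualified = "CEP17 qualification")[failed]
    stop("no qualified nuclei: all nuclei removed at the ", stage,
         " stage")
  }
  thr <- statusThresholds(config$scoring$binary_cutoff,
                          config$scoring$negative_below,
                          config$scoring$equivocal_upper,
                          config$scoring$copy_positive,
                          config$scoring$copy_equivocal_low,
                          config$scoring$mode)
  scoreNuclei(q$records, thr, config$scoring$n_first,
              config$scoring$n_extra, q$fallbackUsed, roi@imageId,
              detectedNuclei = q$stageCounts[["detected"]],
              nucleiWithMinCep17 = q$stageCounts[["cep17_qualified"]])
}

scoreResultRow <- function(x) {
  data.frame(image_id = x@imageId, detected_nuclei = x@detectedNuclei,
             nuclei_with_2_cep17 = x@nucleiWithMinCep17,
             her2_signals = as.integer(x@totalHer2),
             cep17_signals = as.integer(x@totalCep17),
             ratio = sprintf("%.2f", roundHalfAway(x@ratio, 2)),
             status = x@status, n_quantified = x@nQuantified,
             fallback_used = x@fallbackUsed,
             extra_set_counted = x@extraSetCounted,
             low_confidence = x@lowConfidence, failed = FALSE,
             reason = "")
}

failedRow <- function(id, reason) {
  data.frame(image_id = id, detected_nuclei = NA_integer_,
             nuclei_with_2_cep17 = NA_integer_,
             her2_signals = NA_integer_, cep17_signals = NA_integer_,
             ratio = NA_character_, status = NA_character_,
             n_quantified = NA_integer_, fallback_used = NA,
             extra_set_counted = NA, low_confidence = NA, failed = TRUE,
             reason = reason)
}

#' Batch-score ROI images
#'
#' Scores each image and writes one CSV row per ROI (mirroring the
#' method-comparison table schema: identifier, detected nuclei,
#' CEP17-qualified nuclei, signal totals, 2-decimal ratio, status plus
#' provenance flags) and a per-ROI JSON result. A failing ROI is logged
#' and marked `failed` in its row without aborting the batch. Every
#' artifact embeds the configuration hash and package version; the run is
#' reproducible byte for byte for identical inputs, config and seed.
#'
#' @param paths character vector of PNG/TIFF image paths.
#' @param config pipeline configuration.
#' @param outDir output directory (created if needed).
#' @param resolution micrometres per pixel of the inputs.
#' @return `data.frame` of result rows, invisibly; side effects:
#'   `scores.csv`, `<image_id>.json` per ROI and `run_manifest.json`
#'   under `outDir`.
#' @export
runScore <- function(paths, config = defaultConfig(),
                     outDir = config$run$out_dir, resolution = 0.13) {
  if (length(paths) == 0L) stop("usage: no input images given")
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  ver <- as.character(utils::packageVersion("SISHscore"))
  rows <- list()
  for (p in paths) {
    id <- tools::file_path_sans_ext(basename(p))
    row <- tryCatch({
      roi <- readRoi(p, resolution = resolution)
      res <- scoreImage(roi, config)
      doc <- list(image_id = res@imageId,
                  n_quantified = res@nQuantified,
                  total_her2 = res@totalHer2,
                  total_cep17 = res@totalCep17,
                  ratio = res@ratio,
                  ratio_2dp = roundHalfAway(res@ratio, 2),
                  copies_per_nucleus = res@copiesPerNucleus,
                  status = res@status,
                  fallback_used = res@fallbackUsed,
                  extra_set_counted = res@extraSetCounted,
                  low_confidence = res@lowConfidence,
                  detected_nuclei = res@detectedNuclei,
                  nuclei_with_2_cep17 = res@nucleiWithMinCep17,
                  config_hash = hash, package_version = ver)
      jsonlite::write_json(doc, file.path(outDir,
                                          paste0(res@imageId, ".json")),
                           auto_unbox = TRUE, digits = NA)
      scoreResultRow(res)
    }, error = function(e) {
      sishLog("warning", config, "ROI '", id, "' failed: ",
              conditionMessage(e))
      failedRow(id, conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(outDir, "scores.csv"),
                   row.names = FALSE)
  manifest <- list(package_version = ver, config_hash = hash,
                   config = config, n_images = length(paths),
                   n_failed = sum(out$failed))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  exit <- if (any(out$failed)) 1L else 0L
  attr(out, "exit_status") <- exit
  invisible(out)
}

#' Evaluate scored results against a reference table
#'
#' Joins the method results to the reference by `image_id` (repeated
#' identifiers are paired by occurrence order; rows present in only one
#' file are reported and excluded), then computes the Bland-Altman bias
#' and limits of agreement, the paired t-test and the misclassification
#' table, writing a comparison JSON and a Bland-Altman plot.
#'
#' The method ratio column is `ratio` (or `method_ratio`); the reference
#' columns are `expert_ratio` and `expert_status` — so a single file
#' carrying both column sets, like the packaged [referenceScores()]
#' table, can be evaluated against itself.
#'
#' @param resultsCsv path to the method results CSV.
#' @param referenceCsv path to the reference CSV.
#' @param outDir output directory.
#' @param cutoff misclassification ratio cutoff.
#' @param sidedness paired t-test sidedness.
#' @return The [MethodComparison-class], invisibly; side effects:
#'   `comparison.json` and `bland_altman.png` under `outDir`.
#' @export
runEvaluate <- function(resultsCsv, referenceCsv, outDir = ".",
                        cutoff = 2.0, sidedness = "two_sided") {
  res <- utils::read.csv(resultsCsv, colClasses = c(image_id = "character"))
  ref <- utils::read.csv(referenceCsv,
                         colClasses = c(image_id = "character"))
  mcol <- intersect(c("ratio", "method_ratio"), names(res))[1]
  if (is.na(mcol)) stop("results file lacks a 'ratio' column")
  if (!all(c("expert_ratio", "expert_status") %in% names(ref)))
    stop("reference file must carry 'expert_ratio' and 'expert_status'")
  if ("failed" %in% names(res)) res <- res[!res$failed, , drop = FALSE]
  res$..occ <- stats::ave(seq_len(nrow(res)), res$image_id,
                          FUN = seq_along)
  ref$..occ <- stats::ave(seq_len(nrow(ref)), ref$image_id,
                          FUN = seq_along)
  joined <- merge(res[c("image_id", "..occ", mcol)],
                  ref[c("image_id", "..occ", "expert_ratio",
                        "expert_status")],
                  by = c("image_id", "..occ"))
  dropped <- setdiff(union(res$image_id, ref$image_id), joined$image_id)
  if (length(dropped))
    message("excluded (present in only one file): ",
            paste(dropped, collapse = ", "))
  if (nrow(joined) == 0L) stop("empty join: no shared image_id values")
  joined <- joined[order(match(joined$image_id, res$image_id),
                         joined$..occ), ]
  mc <- compareMethods(as.numeric(joined[[mcol]]), joined$expert_ratio,
                       ids = joined$image_id,
                       referenceStatus = joined$expert_status,
                       cutoff = cutoff, sidedness = sidedness)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(n_pairs = mc@nPairs, bias = mc@bias, sd_diff = mc@sdDiff,
              loa_low = mc@loaLow, loa_high = mc@loaHigh,
              t_statistic = mc@tStatistic, p_value = mc@pValue,
              sidedness = mc@sidedness, misclassified = mc@misclassified,
              false_positives = mc@falsePositives,
              false_negatives = mc@falseNegatives,
              package_version = as.character(
                utils::packageVersion("SISHscore")))
  jsonlite::write_json(doc, file.path(outDir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  plotBlandAltman(as.numeric(joined[[mcol]]), joined$expert_ratio,
                  file = file.path(outDir, "bland_altman.png"))
  invisible(mc)
}

#' Emit a synthetic scene to disk
#'
#' Renders a preset (or custom spec), writing the PNG image, the truth
#' JSON and a one-row manifest CSV with the expected totals — the
#' `simulate` command of the CLI.
#'
#' @param preset preset name (see [syntheticPreset()]), ignored when
#'   `spec` is given.
#' @param outDir output directory.
#' @param seed generator seed.
#' @param spec optional explicit [syntheticSpec()].
#' @return Named list of written paths, invisibly.
#' @export
runSimulate <- function(preset = "normal", outDir = ".", seed = 1L,
                        spec = NULL) {
  if (is.null(spec)) spec <- syntheticPreset(preset, seed = seed)
  sc <- simulateRoi(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  id <- sc$image@imageId
  pngPath <- file.path(outDir, paste0(id, ".png"))
  truthPath <- file.path(outDir, paste0(id, "_truth.json"))
  csvPath <- file.path(outDir, paste0(id, "_manifest.csv"))
  writeRoi(sc$image, pngPath)
  writeTruth(sc$truth, truthPath)
  ex <- sc$truth@expected
  utils::write.csv(data.frame(
    image_id = id, n_nuclei = nrow(sc$truth@nuclei),
    expected_her2 = ex$totalHer2, expected_cep17 = ex$totalCep17,
    expected_ratio = ex$ratio, expected_status = ex$status,
    n_qualifying = ex$nQualifying, fallback = ex$fallback),
    csvPath, row.names = FALSE)
  invisible(list(image = pngPath, truth = truthPath,
                 manifest = csvPath))
}
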