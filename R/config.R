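#' Default pipeline configuration
#'
#' The complete, validated parameter set of the scoring pipeline, grouped
#' by stage. Every value can be overridden from a YAML (or JSON) file via
#' [loadConfig()]. Thresholds live on the scales the stages operate on:
#' HSV components in `[0, 1]` (hue in degrees), physical sizes in
#' micrometres, so they transfer across image resolutions.
#'
#' \describe{
#' \item{normalize}{`lower`, `upper`, `mode` for [normalizeValues()]. The
#'   default stretches each channel to `[0, 1]`; percentile mode with
#'   ranks such as 1 / 99.8 is available for robust clipping.}
#' \item{gamma}{`gamma`, `gain` for [gammaAdjust()]; supported operating
#'   points (0.9, 1), (0.5, 1), (0.5, 2); default (0.5, 1).}
#' \item{signals}{color thresholds, physical spot size bounds
#'   (0.4-2.5 um equivalent diameter), `faint_contrast_min`,
#'   `cluster_split`.}
#' \item{nuclei}{backend choice, nuclear hue window, watershed
#'   separation, 20 um2 minimum nucleus area, 0.5 overlap bound, CEP17
#'   rule and fallback.}
#' \item{scoring}{status thresholds (see [statusThresholds()]) and the
#'   20 + 20 selection sizes.}
#' \item{evaluation}{misclassification cutoff and t-test sidedness.}
#' \item{run}{seed, log level, output directory.}
#' }
#'
#' @return Nested named list.
#' @export
defaultConfig <- function() {
  list(
    normalize = list(lower = 0, upper = 1, mode = "value_range"),
    gamma = list(gamma = 0.5, gain = 1),
    signals = list(whiteness_min = 0.9, her2_value_max = 0.35,
                   her2_saturation_max = 0.45,
                   cep17_hue_halfwidth_deg = 25,
                   cep17_saturation_min = 0.3, cep17_value_min = 0.2,
                   cep17_value_max = 0.9, min_spot_diameter_um = 0.4,
                   max_spot_diameter_um = 2.5, faint_contrast_min = 0.15,
                   cluster_split = TRUE),
    nuclei = list(backend = "watershed", hue_min_deg = 160,
                  hue_max_deg = 340, saturation_min = 0.05,
                  min_separation_um = 0.5, min_area_um2 = 20,
                  max_overlap = 0.5, min_cep17 = 2,
                  allow_fallback = TRUE),
    scoring = list(binary_cutoff = 2.0, negative_below = 1.8,
                   equivocal_upper = 2.0, copy_positive = 6.0,
                   copy_equivocal_low = 4.0, mode = "binary_ratio",
                   n_first = 20, n_extra = 20),
    evaluation = list(cutoff = 2.0, sidedness = "two_sided"),
    run = list(seed = 1, log_level = "info", out_dir = "."))
}

# per-key validators: each returns TRUE or a constraint description
configSchema <- function() {
  inRange <- function(lo, hi) function(v)
    if (is.numeric(v) && length(v) == 1 && v >= lo && v <= hi) TRUE
    else sprintf("must be a number in [%g, %g]", lo, hi)
  positive <- function(v)
    if (is.numeric(v) && length(v) == 1 && v > 0) TRUE
    else "must be a positive number"
  flag <- function(v) if (is.logical(v) && length(v) == 1) TRUE
    else "must be TRUE or FALSE"
  oneOf <- function(...) { opts <- c(...); function(v)
    if (is.character(v) && v %in% opts) TRUE
    else paste("must be one of", paste(opts, collapse = ", ")) }
  number <- function(v) if (is.numeric(v) && length(v) == 1) TRUE
    else "must be a number"
  list(
    normalize = list(lower = number, upper = number,
                     mode = oneOf("value_range", "percentile")),
    gamma = list(gamma = positive, gain = positive),
    signals = list(whiteness_min = inRange(0, 1),
                   her2_value_max = inRange(0, 1),
                   her2_saturation_max = inRange(0, 1),
                   cep17_hue_halfwidth_deg = inRange(0, 180),
                   cep17_saturation_min = inRange(0, 1),
                   cep17_value_min = inRange(0, 1),
                   cep17_value_max = inRange(0, 1),
                   min_spot_diameter_um = positive,
                   max_spot_diameter_um = positive,
                   faint_contrast_min = inRange(0, 1),
                   cluster_split = flag),
    nuclei = list(backend = oneOf("watershed", "labelmap"),
                  hue_min_deg = inRange(0, 360),
                  hue_max_deg = inRange(0, 360),
                  saturation_min = inRange(0, 1),
                  min_separation_um = positive,
                  min_area_um2 = positive, max_overlap = inRange(0, 1),
                  min_cep17 = positive, allow_fallback = flag),
    scoring = list(binary_cutoff = positive, negative_below = positive,
                   equivocal_upper = positive, copy_positive = positive,
                   copy_equivocal_low = positive,
                   mode = oneOf("binary_ratio", "three_way_ratio",
                                "asco_full"),
                   n_first = positive, n_extra = positive),
    evaluation = list(cutoff = positive,
                      sidedness = oneOf("two_sided", "greater", "less")),
    run = list(seed = number, log_level = oneOf("debug", "info",
                                                "warning", "error"),
               out_dir = function(v) if (is.character(v)) TRUE
                 else "must be a path"))
}

#' Validate a pipeline configuration
#'
#' Checks every key against the schema; unknown keys and out-of-range
#' values raise an error naming the key and the violated constraint.
#' Cross-field constraints (`lower < upper`, size bounds ordered) are
#' checked as well.
#'
#' @param config nested configuration list.
#' @return The validated config, invisibly.
#' @export
validateConfig <- function(config) {
  schema <- configSchema()
  unknownBlocks <- setdiff(names(config), names(schema))
  if (length(unknownBlocks))
    stop("unknown config block '", unknownBlocks[1], "'")
  for (blk in names(config)) {
    unknown <- setdiff(names(config[[blk]]), names(schema[[blk]]))
    if (length(unknown))
      stop("unknown config key '", blk, ".", unknown[1], "'")
    for (key in names(config[[blk]])) {
      res <- schema[[blk]][[key]](config[[blk]][[key]])
      if (!isTRUE(res))
        stop("config key '", blk, ".", key, "' ", res)
    }
  }
  if (config$normalize$lower >= config$normalize$upper)
    stop("config key 'normalize.lower' must be below 'normalize.upper'")
  if (config$signals$min_spot_diameter_um >=
      config$signals$max_spot_diameter_um)
    stop("config key 'signals.min_spot_diameter_um' must be below ",
         "'signals.max_spot_diameter_um'")
  invisible(config)
}

#' Load a configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration, merges
#' it under the documented defaults and validates the result. An empty
#' file yields the full default configuration. TOML is not supported.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      toml = stop("TOML configs are not supported; use YAML or JSON"),
      stop("unrecognized config extension '.", ext, "'"))
    if (!is.null(user)) {
      if (!is.list(user)) stop("config file must contain a mapping")
      unknownBlocks <- setdiff(names(user), names(defaultConfig()))
      if (length(unknownBlocks))
        stop("unknown config block '", unknownBlocks[1], "'")
      for (blk in names(user)) {
        unknown <- setdiff(names(user[[blk]]),
                           names(defaultConfig()[[blk]]))
        if (length(unknown))
          stop("unknown config key '", blk, ".", unknown[1], "'")
      }
      cfg <- utils::modifyList(cfg, user)
    }
  }
  validateConfig(cfg)
  cfg
}

#' Hash of the effective configuration
#'
#' An 8-hex-digit fingerprint stamped into every output artifact for
#' provenance.
#'
#' @param config configuration list.
#' @return Single character hash.
#' @export
configHash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}
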