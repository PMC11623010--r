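#' Count distribution specifications for planted signals
#'
#' Per-nucleus signal counts are drawn from one of three forms:
#' `fixedCount(k)` plants exactly `k` signals in every nucleus (normal
#' scenes are approximately 2/2); `uniformCount(min, max)` draws integers
#' uniformly; `poissonCount(lambda, floor)` draws Poisson counts with a
#' lower floor, emulating amplified (HER2 far exceeding CEP17) and
#' borderline scenes.
#'
#' @param value,min,max,lambda,floor distribution parameters.
#' @return A count-spec list consumed by [syntheticSpec()].
#' @export
fixedCount <- function(value) {
  stopifnot(value >= 0, value == round(value))
  list(kind = "fixed", value = as.integer(value))
}

#' @rdname fixedCount
#' @export
uniformCount <- function(min, max) {
  stopifnot(min >= 0, max >= min)
  list(kind = "uniform", min = as.integer(min), max = as.integer(max))
}

#' @rdname fixedCount
#' @export
poissonCount <- function(lambda, floor = 0) {
  stopifnot(lambda >= 0, floor >= 0)
  list(kind = "poisson", lambda = lambda, floor = as.integer(floor))
}

sampleCounts <- function(spec, n) {
  switch(spec$kind,
    fixed = rep(spec$value, n),
    uniform = sample(spec$min:spec$max, n, replace = TRUE),
    poisson = pmax(spec$floor, stats::rpois(n, spec$lambda)),
    stop("unknown count distribution kind '", spec$kind, "'"))
}

#' Specification of a synthetic SISH scene
#'
#' Defines a brightfield SISH-like ROI with exhaustive ground truth: a
#' light eosin-toned background, bluish elliptical nuclei, black HER2 and
#' red CEP17 disks planted inside them, optional merged HER2 clusters,
#' faint dots, border-clipped nuclei and deliberately overlapping nucleus
#' pairs, then Gaussian pixel noise. Identical spec and seed give a
#' bit-identical image and truth.
#'
#' Appearance constants (colors, dot radii) are fields of the spec, not
#' hard-coded; the defaults are chosen so the package's default detection
#' configuration recovers every planted dot in a noise-free scene.
#'
#' @param imageSize integer `(H, W)` in pixels.
#' @param resolutionUmPerPx micrometres per pixel (default 0.13, the
#'   scan resolution the pipeline targets).
#' @param nNuclei number of nuclei to plant.
#' @param nucleusRadiusUm `(mean, sd)` of the nucleus radius in um.
#' @param her2PerNucleus,cep17PerNucleus count specs ([fixedCount()] and
#'   friends) for planted signals per nucleus.
#' @param clusterProbability probability that remaining HER2 signals form
#'   a merged cluster entity of multiplicity 2-4.
#' @param faintFraction fraction of singleton dots rendered at reduced
#'   contrast (flagged `faint` in the truth).
#' @param edgeClipFraction fraction of nuclei placed across the image
#'   border (flagged `truncated`).
#' @param overlapPairFraction fraction of nuclei planted as members of
#'   >50 percent overlapping pairs (flagged `overlapped`).
#' @param noiseSd Gaussian pixel noise SD on the 8-bit scale (0 = none).
#' @param seed integer RNG seed.
#' @param dotRadiusUm `(min, max)` dot radius range in um; the narrow
#'   default keeps singleton areas well inside one median-area unit so
#'   cluster decomposition never mistakes a large singleton for a pair.
#' @param colors named list of RGB triplets (0-255): `background`,
#'   `nucleus`, `her2`, `cep17`, `her2Faint`, `cep17Faint`.
#' @return Validated spec list of class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(imageSize = c(768L, 768L),
                          resolutionUmPerPx = 0.13,
                          nNuclei = 25L,
                          nucleusRadiusUm = c(3.5, 0.4),
                          her2PerNucleus = fixedCount(2),
                          cep17PerNucleus = fixedCount(2),
                          clusterProbability = 0,
                          faintFraction = 0,
                          edgeClipFraction = 0,
                          overlapPairFraction = 0,
                          noiseSd = 0,
                          seed = 1L,
                          dotRadiusUm = c(0.3, 0.37),
                          colors = list(
                            background = c(246, 240, 244),
                            nucleus = c(170, 158, 212),
                            her2 = c(28, 26, 27),
                            cep17 = c(165, 40, 50),
                            her2Faint = c(120, 116, 118),
                            cep17Faint = c(200, 140, 148))) {
  fracs <- c(clusterProbability, faintFraction, edgeClipFraction,
             overlapPairFraction)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions/probabilities must lie in [0, 1]")
  if (nNuclei < 0) stop("nNuclei must be non-negative")
  if (any(nucleusRadiusUm <= 0) || resolutionUmPerPx <= 0 ||
      any(dotRadiusUm <= 0))
    stop("radius and resolution parameters must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  spec <- list(imageSize = as.integer(imageSize),
               resolutionUmPerPx = resolutionUmPerPx,
               nNuclei = as.integer(nNuclei),
               nucleusRadiusUm = nucleusRadiusUm,
               her2PerNucleus = her2PerNucleus,
               cep17PerNucleus = cep17PerNucleus,
               clusterProbability = clusterProbability,
               faintFraction = faintFraction,
               edgeClipFraction = edgeClipFraction,
               overlapPairFraction = overlapPairFraction,
               noiseSd = noiseSd, seed = as.integer(seed),
               dotRadiusUm = dotRadiusUm, colors = colors)
  class(spec) <- "syntheticSpec"
  spec
}

#' Preset synthetic scenes
#'
#' Four named study conditions: `"normal"` (25 nuclei, 2 HER2 / 2 CEP17
#' each; expected ratio 1.0, Negative), `"amplified"` (30 nuclei, 6/2;
#' ratio 3.0, Positive), `"equivocal"` (45 nuclei, 5/3; copies per
#' nucleus 5.0, inside the recount band that triggers counting an extra
#' set of nuclei) and `"high-positivity"` (25 nuclei, 8 HER2 and exactly
#' one CEP17 each, exercising the single-CEP17 fallback).
#'
#' @param name preset name.
#' @param ... overrides passed to [syntheticSpec()] (e.g. `seed`,
#'   `noiseSd`).
#' @return A `"syntheticSpec"`.
#' @export
syntheticPreset <- function(name = c("normal", "amplified", "equivocal",
                                     "high-positivity"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    normal = list(nNuclei = 25L, her2PerNucleus = fixedCount(2),
                  cep17PerNucleus = fixedCount(2)),
    amplified = list(nNuclei = 30L, her2PerNucleus = fixedCount(6),
                     cep17PerNucleus = fixedCount(2)),
    equivocal = list(nNuclei = 45L, imageSize = c(1024L, 1024L),
                     her2PerNucleus = fixedCount(5),
                     cep17PerNucleus = fixedCount(3)),
    `high-positivity` = list(nNuclei = 25L,
                             her2PerNucleus = fixedCount(8),
                             cep17PerNucleus = fixedCount(1)))
  do.call(syntheticSpec, utils::modifyList(base, list(...)))
}

# pixel-center ellipse membership test; all coordinates 0-based
insideEllipse <- function(r, c, r0, c0, a, b, theta) {
  u <- (c - c0) * cos(theta) + (r - r0) * sin(theta)
  w <- -(c - c0) * sin(theta) + (r - r0) * cos(theta)
  (u / a)^2 + (w / b)^2 <= 1
}

# paint all pixels inside the ellipse (bounding-box scan); px is H x W x 3
paintEllipse <- function(px, r0, c0, a, b, theta, rgb) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rmax <- max(a, b)
  rr <- max(0, floor(r0 - rmax)):min(h - 1, ceiling(r0 + rmax))
  cc <- max(0, floor(c0 - rmax)):min(w - 1, ceiling(c0 + rmax))
  if (!length(rr) || !length(cc)) return(px)
  g <- expand.grid(r = rr, c = cc)
  inside <- insideEllipse(g$r, g$c, r0, c0, a, b, theta)
  if (!any(inside)) return(px)
  ri <- g$r[inside] + 1L; ci <- g$c[inside] + 1L
  for (ch in 1:3) px[cbind(ri, ci, ch)] <- rgb[ch]
  px
}

paintDisk <- function(px, r0, c0, radius, rgb) {
  paintEllipse(px, r0, c0, radius, radius, 0, rgb)
}

# offsets (row, col) of the k disks of a merged cluster, in units of the
# disk radius; compact arrangements keep the cluster within the nucleus
clusterOffsets <- function(k, radius, angle) {
  s <- 1.9 * radius  # center spacing: disks merge but barely overlap
  pts <- switch(as.character(k),
    `2` = rbind(c(0, -s / 2), c(0, s / 2)),
    `3` = {
      circ <- s / sqrt(3)
      t(sapply(0:2, function(i) circ * c(sin(2 * pi * i / 3),
                                         cos(2 * pi * i / 3))))
    },
    `4` = {
      circ <- s / sqrt(2)
      t(sapply(0:3, function(i) circ * c(sin(pi / 4 + pi * i / 2),
                                         cos(pi / 4 + pi * i / 2))))
    },
    stop("cluster multiplicity must be 2, 3 or 4"))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  pts %*% rot
}

#' Generate a synthetic SISH ROI with ground truth
#'
#' Renders the scene described by a [syntheticSpec()] and returns both
#' the image and a [SyntheticTruth-class] recording every planted
#' nucleus and dot entity plus the image-level expected totals, ratio and
#' status over qualifying nuclei (interior, non-overlapped, CEP17 >= 2,
#' with the single-CEP17 fallback when no nucleus reaches 2).
#'
#' Nucleus positions are rejection-sampled so that only the planted
#' overlap pairs overlap; when a position cannot be found after a bounded
#' number of attempts an error advises a smaller `nNuclei` or a larger
#' image. Dot entities are separated so each forms its own connected
#' component; clusters are rendered as `k` merged disks and recorded with
#' multiplicity `k`.
#'
#' @param spec a `"syntheticSpec"`.
#' @return `list(image = RoiImage, truth = SyntheticTruth)`.
#' @examples
#' sc <- simulateRoi(syntheticPreset("normal", nNuclei = 5, seed = 42))
#' sc$truth
#' @export
simulateRoi <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withr::with_seed(spec$seed, simulateRoiImpl(spec))
}

simulateRoiImpl <- function(spec) {
  h <- spec$imageSize[1]; w <- spec$imageSize[2]
  res <- spec$resolutionUmPerPx
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- spec$colors$background[ch]
  n <- spec$nNuclei

  nucDf <- data.frame(label = integer(), row = numeric(), col = numeric(),
                      semiA = numeric(), semiB = numeric(),
                      angle = numeric(), her2 = integer(),
                      cep17 = integer(), truncated = logical(),
                      overlapped = logical())
  dotDf <- data.frame(nucleus = integer(), channel = character(),
                      row = numeric(), col = numeric(),
                      radiusPx = numeric(), faint = logical(),
                      multiplicity = integer())

  if (n > 0) {
    nEdge <- round(spec$edgeClipFraction * n)
    nOv <- 2L * floor(spec$overlapPairFraction * n / 2)
    nInt <- n - nEdge - nOv
    if (nInt < 0) stop("edge and overlap fractions together exceed 1")
    kind <- c(rep("interior", nInt), rep("edge", nEdge),
              rep("pairA", nOv / 2), rep("pairB", nOv / 2))

    radUm <- pmin(pmax(stats::rnorm(n, spec$nucleusRadiusUm[1],
                                    spec$nucleusRadiusUm[2]), 2.9), 5.5)
    aPx <- radUm / res
    bPx <- aPx * stats::runif(n, 0.78, 1)
    ang <- stats::runif(n, 0, pi)

    ctr <- matrix(NA_real_, n, 2)  # (row, col), 0-based
    effR <- pmax(aPx, bPx)
    clearOk <- function(i, r0, c0, partner = NA) {
      j <- seq_len(i - 1L)
      if (!is.na(partner)) j <- setdiff(j, partner)
      if (!length(j)) return(TRUE)
      dd <- sqrt((ctr[j, 1] - r0)^2 + (ctr[j, 2] - c0)^2)
      all(dd >= effR[i] + effR[j] + 4)
    }
    maxAtt <- 400L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(maxAtt)) {
        if (kind[i] == "interior" || kind[i] == "pairA") {
          m <- effR[i] + 3
          r0 <- stats::runif(1, m, h - 1 - m)
          c0 <- stats::runif(1, m, w - 1 - m)
          if (kind[i] == "pairA") m2 <- effR[i] * 2.5 + 6 else m2 <- NA
          ok <- clearOk(i, r0, c0)
          if (ok && kind[i] == "pairA") {
            # keep extra clearance so the partner fits without a third
            # nucleus intruding
            for (j in seq_len(i - 1L)) {
              dd <- sqrt((ctr[j, 1] - r0)^2 + (ctr[j, 2] - c0)^2)
              if (dd < effR[i] * 2 + effR[j] + 8) { ok <- FALSE; break }
            }
          }
        } else if (kind[i] == "pairB") {
          partner <- i - as.integer(nOv / 2)
          dir <- stats::runif(1, 0, 2 * pi)
          dd <- 0.5 * effR[partner]
          r0 <- ctr[partner, 1] + dd * sin(dir)
          c0 <- ctr[partner, 2] + dd * cos(dir)
          ok <- r0 > effR[i] + 3 && r0 < h - 1 - effR[i] - 3 &&
            c0 > effR[i] + 3 && c0 < w - 1 - effR[i] - 3 &&
            clearOk(i, r0, c0, partner)
        } else {  # edge
          side <- sample(4L, 1L)
          off <- 0.4 * effR[i]
          if (side == 1L) { r0 <- off; c0 <- stats::runif(1, effR[i], w - 1 - effR[i]) }
          if (side == 2L) { r0 <- h - 1 - off; c0 <- stats::runif(1, effR[i], w - 1 - effR[i]) }
          if (side == 3L) { c0 <- off; r0 <- stats::runif(1, effR[i], h - 1 - effR[i]) }
          if (side == 4L) { c0 <- w - 1 - off; r0 <- stats::runif(1, effR[i], h - 1 - effR[i]) }
          ok <- clearOk(i, r0, c0)
        }
        if (ok) { ctr[i, ] <- c(r0, c0); placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible packing: could not place nucleus ", i, " after ",
             maxAtt, " attempts; reduce nNuclei or enlarge the image")
    }

    nHer2 <- sampleCounts(spec$her2PerNucleus, n)
    nCep17 <- sampleCounts(spec$cep17PerNucleus, n)

    # paint all nucleus bodies first, then all dots, so dots are never
    # painted over by an overlapping partner's body
    for (i in seq_len(n))
      px <- paintEllipse(px, ctr[i, 1], ctr[i, 2], bPx[i], aPx[i],
                         ang[i], spec$colors$nucleus)

    plantedH <- integer(n); plantedC <- integer(n)
    for (i in seq_len(n)) {
      # decompose the HER2 signal budget into singleton/cluster entities
      ents <- list()
      rem <- nHer2[i]
      while (rem > 0) {
        if (rem >= 2 && stats::runif(1) < spec$clusterProbability) {
          k <- sample(2:min(4, rem), 1L)
          ents[[length(ents) + 1L]] <- list(channel = "HER2", mult = k)
          rem <- rem - k
        } else {
          ents[[length(ents) + 1L]] <- list(channel = "HER2", mult = 1L)
          rem <- rem - 1L
        }
      }
      for (j in seq_len(nCep17[i]))
        ents[[length(ents) + 1L]] <- list(channel = "CEP17", mult = 1L)

      placedEnts <- data.frame(row = numeric(), col = numeric(),
                               br = numeric())
      for (e in ents) {
        rDotUm <- stats::runif(1, spec$dotRadiusUm[1], spec$dotRadiusUm[2])
        rDot <- rDotUm / res
        # clusters render at the median dot radius so area-ratio
        # decomposition against the median singleton area is unbiased
        if (e$mult > 1L) rDot <- mean(spec$dotRadiusUm) / res
        # bounding radius of the whole entity
        br <- if (e$mult == 1L) rDot else
          rDot * (1 + 1.9 / if (e$mult == 2L) 2 else
                  if (e$mult == 3L) sqrt(3) else sqrt(2))
        faint <- e$mult == 1L && stats::runif(1) < spec$faintFraction
        okPos <- FALSE
        for (att in seq_len(1000L)) {
          t <- stats::runif(1, 0, 2 * pi)
          rho <- sqrt(stats::runif(1))
          aIn <- max(bPx[i] - br - 1.5, 1)
          bIn <- max(aPx[i] - br - 1.5, 1)
          dr <- rho * aIn * sin(t); dc <- rho * bIn * cos(t)
          rr0 <- ctr[i, 1] + dr * cos(ang[i]) + dc * sin(ang[i])
          cc0 <- ctr[i, 2] + dc * cos(ang[i]) - dr * sin(ang[i])
          if (rr0 < br + 1 || rr0 > h - 2 - br ||
              cc0 < br + 1 || cc0 > w - 2 - br) next
          if (nrow(placedEnts)) {
            dd <- sqrt((placedEnts$row - rr0)^2 + (placedEnts$col - cc0)^2)
            if (any(dd < placedEnts$br + br + 3)) next
          }
          okPos <- TRUE
          break
        }
        if (!okPos) next  # entity skipped; truth reflects what is drawn
        placedEnts <- rbind(placedEnts,
                            data.frame(row = rr0, col = cc0, br = br))
        col <- if (e$channel == "HER2") {
          if (faint) spec$colors$her2Faint else spec$colors$her2
        } else {
          if (faint) spec$colors$cep17Faint else spec$colors$cep17
        }
        if (e$mult == 1L) {
          px <- paintDisk(px, rr0, cc0, rDot, col)
        } else {
          offs <- clusterOffsets(e$mult, rDot, stats::runif(1, 0, pi))
          for (q in seq_len(e$mult))
            px <- paintDisk(px, rr0 + offs[q, 1], cc0 + offs[q, 2],
                            rDot, col)
        }
        dotDf <- rbind(dotDf, data.frame(
          nucleus = i, channel = e$channel, row = rr0, col = cc0,
          radiusPx = rDot, faint = faint, multiplicity = e$mult))
        if (e$channel == "HER2") plantedH[i] <- plantedH[i] + e$mult
        else plantedC[i] <- plantedC[i] + e$mult
      }
    }

    truncated <- ctr[, 1] - effR < 0.5 | ctr[, 1] + effR > h - 1.5 |
      ctr[, 2] - effR < 0.5 | ctr[, 2] + effR > w - 1.5
    overlapped <- kind %in% c("pairA", "pairB")
    nucDf <- data.frame(label = seq_len(n), row = ctr[, 1],
                        col = ctr[, 2], semiA = aPx, semiB = bPx,
                        angle = ang, her2 = plantedH, cep17 = plantedC,
                        truncated = truncated, overlapped = overlapped)
  }

  if (spec$noiseSd > 0)
    px <- px + stats::rnorm(length(px), 0, spec$noiseSd)
  px <- roundHalfAway(pmin(pmax(px, 0), 255), 0)

  truth <- new("SyntheticTruth", nuclei = nucDf, dots = dotDf,
               expected = expectedFromNuclei(nucDf),
               imageSize = c(h, w), resolution = res, seed = spec$seed)
  list(image = RoiImage(px, res, sprintf("synthetic-seed%d", spec$seed)),
       truth = truth)
}

# image-level expectation over qualifying nuclei (interior,
# non-overlapped, CEP17 >= 2, falling back to >= 1 when necessary)
expectedFromNuclei <- function(nucDf) {
  if (!nrow(nucDf))
    return(list(totalHer2 = 0L, totalCep17 = 0L, ratio = NA_real_,
                status = NA_character_, nQualifying = 0L,
                fallback = FALSE))
  cand <- nucDf[!nucDf$truncated & !nucDf$overlapped, , drop = FALSE]
  q <- cand[cand$cep17 >= 2, , drop = FALSE]
  fallback <- FALSE
  if (!nrow(q)) {
    q <- cand[cand$cep17 >= 1, , drop = FALSE]
    fallback <- TRUE
  }
  if (!nrow(q) || sum(q$cep17) == 0)
    return(list(totalHer2 = as.integer(sum(q$her2)), totalCep17 = 0L,
                ratio = NA_real_, status = NA_character_,
                nQualifying = nrow(q), fallback = fallback))
  ratio <- sum(q$her2) / sum(q$cep17)
  list(totalHer2 = as.integer(sum(q$her2)),
       totalCep17 = as.integer(sum(q$cep17)), ratio = ratio,
       status = if (ratio >= 2) "Positive" else "Negative",
       nQualifying = nrow(q), fallback = fallback)
}

#' Ground-truth instance masks and records
#'
#' `truthMasks` rasterizes every planted nucleus ellipse into its pixel
#' set (1-based linear indices, possibly overlapping for planted pairs),
#' named by label — the oracle input for [filterOverlapping()].
#' `truthRecords` builds the nucleus-record table directly from planted
#' counts, bypassing detection — the oracle input for the qualification
#' filters and scoring.
#'
#' @param truth a [SyntheticTruth-class].
#' @return `truthMasks`: named list of integer vectors; `truthRecords`:
#'   nucleus-record `data.frame` as from [assignSpots()].
#' @export
truthMasks <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  h <- truth@imageSize[1]; w <- truth@imageSize[2]
  nuc <- truth@nuclei
  out <- vector("list", nrow(nuc))
  names(out) <- as.character(nuc$label)
  for (i in seq_len(nrow(nuc))) {
    rmax <- max(nuc$semiA[i], nuc$semiB[i])
    rr <- max(0, floor(nuc$row[i] - rmax)):min(h - 1, ceiling(nuc$row[i] + rmax))
    cc <- max(0, floor(nuc$col[i] - rmax)):min(w - 1, ceiling(nuc$col[i] + rmax))
    g <- expand.grid(r = rr, c = cc)
    inside <- insideEllipse(g$r, g$c, nuc$row[i], nuc$col[i],
                            nuc$semiB[i], nuc$semiA[i], nuc$angle[i])
    out[[i]] <- as.integer((g$r[inside]) + (g$c[inside]) * h + 1L)
  }
  out
}

#' @rdname truthMasks
#' @export
truthRecords <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  nuc <- truth@nuclei
  data.frame(label = nuc$label, area_px = as.integer(
               round(pi * nuc$semiA * nuc$semiB)),
             row = nuc$row, col = nuc$col, her2_count = nuc$her2,
             cep17_count = nuc$cep17,
             differentiation = nuc$her2 - nuc$cep17,
             touches_border = nuc$truncated, max_overlap_fraction = 0,
             qualified = TRUE)
}

#' Serialize ground truth to JSON
#'
#' Lossless round-trip: `readTruth(writeTruth(t, path))` reconstructs
#' `t`. Reading validates the schema and rejects violations (missing
#' fields, non-positive radii, negative counts) with an error naming the
#' offending field.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON file path.
#' @return `writeTruth` returns `path` invisibly; `readTruth` returns a
#'   [SyntheticTruth-class].
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  doc <- list(nuclei = truth@nuclei, dots = truth@dots,
              expected = truth@expected,
              imageSize = truth@imageSize, resolution = truth@resolution,
              seed = truth@seed)
  jsonlite::write_json(doc, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed truth JSON: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  for (f in c("nuclei", "dots", "expected", "imageSize", "resolution",
              "seed"))
    if (is.null(doc[[f]])) stop("truth schema violation: missing '", f, "'")
  nucCols <- c("label", "row", "col", "semiA", "semiB", "angle", "her2",
               "cep17", "truncated", "overlapped")
  dotCols <- c("nucleus", "channel", "row", "col", "radiusPx", "faint",
               "multiplicity")
  asDf <- function(x, cols, what) {
    x <- as.data.frame(x)
    if (nrow(x) == 0 && ncol(x) == 0)
      x <- as.data.frame(stats::setNames(
        lapply(cols, function(.) logical(0)), cols))
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("truth schema violation: ", what, " lacks field '",
           miss[1], "'")
    x[cols]
  }
  nuc <- asDf(doc$nuclei, nucCols, "nuclei")
  dots <- asDf(doc$dots, dotCols, "dots")
  if (nrow(nuc)) {
    nuc$label <- as.integer(nuc$label)
    nuc$her2 <- as.integer(nuc$her2)
    nuc$cep17 <- as.integer(nuc$cep17)
    if (any(nuc$semiA <= 0) || any(nuc$semiB <= 0))
      stop("truth schema violation: nuclei field 'semiA'/'semiB' ",
           "must be positive")
  } else {
    nuc <- data.frame(label = integer(), row = numeric(),
                      col = numeric(), semiA = numeric(),
                      semiB = numeric(), angle = numeric(),
                      her2 = integer(), cep17 = integer(),
                      truncated = logical(), overlapped = logical())
  }
  if (nrow(dots)) {
    dots$nucleus <- as.integer(dots$nucleus)
    dots$multiplicity <- as.integer(dots$multiplicity)
    if (any(dots$radiusPx <= 0))
      stop("truth schema violation: dots field 'radiusPx' must be ",
           "positive")
  } else {
    dots <- data.frame(nucleus = integer(), channel = character(),
                       row = numeric(), col = numeric(),
                       radiusPx = numeric(), faint = logical(),
                       multiplicity = integer())
  }
  exp <- doc$expected
  exp$totalHer2 <- as.integer(exp$totalHer2)
  exp$totalCep17 <- as.integer(exp$totalCep17)
  exp$nQualifying <- as.integer(exp$nQualifying)
  exp$ratio <- if (is.null(exp$ratio)) NA_real_ else as.numeric(exp$ratio)
  exp$status <- if (is.null(exp$status)) NA_character_ else exp$status
  new("SyntheticTruth", nuclei = nuc, dots = dots, expected = exp,
      imageSize = as.integer(doc$imageSize),
      resolution = as.numeric(doc$resolution),
      seed = as.integer(doc$seed))
}
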