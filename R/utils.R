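#' Round half away from zero
#'
#' Commercial rounding used for all reported ratios: `2.585 -> 2.59`,
#' `-2.585 -> -2.59`. R's `round()` rounds half to even, which would
#' disagree with printed clinical tables on exact-half values.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return Rounded numeric vector.
#' @examples roundHalfAway(c(2.585, 1.005, -0.125), 2)
#' @export
roundHalfAway <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# HSV decomposition of an H x W x 3 array with channels in [0, 1].
# Returns list of H x W matrices: h in degrees [0, 360), s and v in [0, 1].
rgbToHsv <- function(px) {
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
             as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Angular distance to pure red (hue 0), in degrees [0, 180].
hueDistToRed <- function(h) pmin(h %% 360, 360 - (h %% 360))

# Connected-component labeling with 8-connectivity. EBImage::bwlabel is
# 4-connected, so components that touch only diagonally are merged
# afterwards with a union-find over the diagonal adjacencies.
labelComponents8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- relab[lab[lab > 0L]]
  out
}

# Drop labels, keep the rest contiguous (1..k), preserving rank order.
relabelDrop <- function(lab, drop) {
  keep <- setdiff(sort(unique(lab[lab > 0L])), drop)
  map <- integer(max(lab, 1L))
  map[keep] <- seq_along(keep)
  out <- lab
  out[out > 0L] <- map[lab[lab > 0L]]
  out
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# output artifacts with the effective configuration.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  # 32-bit arithmetic carried in doubles to avoid integer overflow
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit value (stored in a double) with a byte
xor32 <- function(h, b) {
  lo <- h %% 256
  h - lo + bitwXor(as.integer(lo), as.integer(b))
}

# Convert a physical diameter (um) to a pixel area through the ROI
# resolution; spots and nuclei are treated as disks for this conversion.
diameterUmToAreaPx <- function(diameter_um, res_um_per_px) {
  if (is.null(res_um_per_px) || !is.finite(res_um_per_px) ||
      res_um_per_px <= 0)
    stop("physical size bounds require calibration: supply a positive ",
         "resolution (um/pixel) on the RoiImage", call. = FALSE)
  pi * (diameter_um / 2)^2 / res_um_per_px^2
}

# Lower-value median (type-1 quantile): the spec'd tie-break for the
# median singleton area used in cluster decomposition.
medianLow <- function(x) {
  stats::quantile(x, 0.5, type = 1, names = FALSE)
}
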