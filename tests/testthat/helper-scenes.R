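# Hand-built image helpers shared across tests. Pixels are 8-bit [0, 255];
# coordinates follow the package's 0-based pixel-center convention.

sceneColors <- function() {
  list(background = c(246, 240, 244), nucleus = c(170, 158, 212),
       her2 = c(28, 26, 27), cep17 = c(165, 40, 50))
}

flatImage <- function(h, w, rgb) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  px
}

# paint a disk (0-based center) onto an H x W x 3 array
paintDiskPx <- function(px, r0, c0, radius, rgb) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rr <- max(0, floor(r0 - radius)):min(h - 1, ceiling(r0 + radius))
  cc <- max(0, floor(c0 - radius)):min(w - 1, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  for (ch in 1:3)
    px[cbind(g$r[keep] + 1L, g$c[keep] + 1L, ch)] <- rgb[ch]
  px
}

# unit-range RoiImage without any contrast stretch (pixels / 255), so
# hand-chosen colors hit the detection thresholds directly
asNormRoi <- function(px, resolution = 0.13, id = "test") {
  RoiImage(px / 255, resolution = resolution, imageId = id)
}

rawRoi <- function(px, resolution = 0.13, id = "test") {
  RoiImage(px, resolution = resolution, imageId = id)
}

# a quick records table for scoring tests
recTable <- function(her2, cep17, label = seq_along(her2)) {
  n <- length(her2)
  data.frame(label = as.integer(label), area_px = rep(1500L, n),
             row = rep(0, n), col = rep(0, n),
             her2_count = her2, cep17_count = cep17,
             differentiation = her2 - cep17,
             touches_border = rep(FALSE, n),
             max_overlap_fraction = rep(0, n), qualified = rep(TRUE, n))
}
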