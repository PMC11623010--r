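#' Read a region-of-interest image
#'
#' Reads an 8-bit RGB PNG or TIFF into a [RoiImage-class]. Grayscale
#' images are replicated across the three channels and an alpha channel is
#' dropped; both conversions emit a message. The physical resolution is
#' not carried by PNG and only unreliably by TIFF, so it is supplied
#' explicitly.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param resolution micrometres per pixel (default 0.13).
#' @param imageId identifier; defaults to the file name without extension.
#' @return A [RoiImage-class] with pixels in `[0, 255]`.
#' @export
readRoi <- function(path, resolution = 0.13, imageId = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  if (is.null(imageId))
    imageId <- tools::file_path_sans_ext(basename(path))
  d <- dim(img)
  if (length(d) == 2L) {
    message("grayscale input: replicating the single channel to RGB")
    img <- array(img, dim = c(d, 3L))
  } else if (d[3] == 4L) {
    message("RGBA input: dropping the alpha channel")
    img <- img[, , 1:3, drop = FALSE]
  } else if (d[3] == 2L) {
    message("gray+alpha input: replicating gray to RGB, dropping alpha")
    img <- array(img[, , 1], dim = c(d[1], d[2], 3L))
  } else if (d[3] != 3L) {
    stop("expected 1, 2, 3 or 4 channels, got ", d[3])
  }
  RoiImage(img * 255, resolution = resolution, imageId = imageId)
}

#' Write a RoiImage to PNG or TIFF
#'
#' Pixels are converted to 8-bit at export, rounding half away from zero.
#'
#' @param roi a [RoiImage-class] with pixels in `[0, 255]` or `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
writeRoi <- function(roi, path) {
  stopifnot(is(roi, "RoiImage"))
  px <- roi@pixels
  if (max(px) > 1) px <- px / 255
  px <- roundHalfAway(px * 255, 0) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  invisible(path)
}

#' Read or write a nucleus label map
#'
#' Label maps are exchanged as single-channel 16-bit TIFF, accommodating
#' up to 65535 nucleus instances.
#'
#' @param path TIFF path.
#' @param labels integer matrix (0 = background).
#' @return `readLabelMap` returns an integer matrix; `writeLabelMap`
#'   returns `path` invisibly.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("no such label map: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' @rdname readLabelMap
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (max(labels) > 65535L)
    stop("more than 65535 instances cannot be stored in 16-bit TIFF")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
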