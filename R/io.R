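# Reading and writing section images and masks (PNG and TIFF).

#' Read an RGB section image from PNG or TIFF
#'
#' @param path image file (`.png`, `.tif`/`.tiff`); must contain an RGB
#'   (or RGBA, alpha dropped) raster.
#' @param pixelSizeUm um per pixel of the scan.
#' @param depthUm section depth, um.
#' @param slideId identifier; defaults to the file name.
#' @param stainKind `"nsc_prussian_blue"` or `"tumor_dab"`.
#' @return a [SectionImage-class] with intensities on [0, 255].
#' @export
readSectionImage <- function(path, pixelSizeUm = 1, depthUm = 0,
                             slideId = NULL,
                             stainKind = c("nsc_prussian_blue",
                                           "tumor_dab")) {
  stainKind <- match.arg(stainKind)
  if (is.null(slideId)) slideId <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  )
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L)
    stop("not an RGB image: ", path)
  sectionImage(raw[, , 1:3, drop = FALSE] * 255, pixelSizeUm = pixelSizeUm,
               depthUm = depthUm, slideId = slideId, stainKind = stainKind)
}

#' Write a section image to PNG or TIFF
#'
#' Intensities are quantized to 8 bits on writing.
#'
#' @param image a [SectionImage-class].
#' @param path output file (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
writeSectionImage <- function(image, path) {
  stopifnot(is(image, "SectionImage"))
  arr <- image@pixels / 255
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask a [BinaryMask-class].
#' @param path output PNG file.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(mask@mask * 1, target = path)
  invisible(path)
}

#' Read a 0/255 PNG back into a binary mask
#'
#' Pixels above 0.5 (on the PNG's [0, 1] scale) are positive.
#'
#' @param path PNG file.
#' @param pixelSizeUm um per pixel.
#' @param label `"nsc"` or `"tumor"`.
#' @return a [BinaryMask-class].
#' @export
readMaskPNG <- function(path, pixelSizeUm = 1, label = c("nsc", "tumor")) {
  label <- match.arg(label)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  binaryMask(raw > 0.5, pixelSizeUm = pixelSizeUm, label = label)
}
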