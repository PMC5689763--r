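# Constructors, accessors and show methods for the core S4 containers.

#' Construct a SectionImage
#'
#' @param pixels H x W x 3 numeric array of intensities in [0, 255].
#' @param pixelSizeUm micrometres per pixel.
#' @param depthUm depth of the section below the reference surface, um.
#' @param slideId slide identifier.
#' @param stainKind `"nsc_prussian_blue"` or `"tumor_dab"`.
#' @return a [SectionImage-class] object.
#' @examples
#' img <- sectionImage(array(200, dim = c(8, 8, 3)), pixelSizeUm = 1,
#'                     depthUm = 0, slideId = "s1",
#'                     stainKind = "tumor_dab")
#' pixelSizeUm(img)
#' @export
sectionImage <- function(pixels, pixelSizeUm = 1, depthUm = 0,
                         slideId = "section", stainKind = "tumor_dab") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  new("SectionImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm),
      depthUm = as.numeric(depthUm), slideId = as.character(slideId),
      stainKind = stainKind)
}

#' @rdname SectionImage-class
#' @export
setMethod("imagePixels", "SectionImage", function(object) object@pixels)

#' @rdname SectionImage-class
#' @export
setMethod("pixelSizeUm", "SectionImage", function(object) object@pixelSizeUm)

#' @rdname BinaryMask-class
#' @param object an object.
#' @export
setMethod("pixelSizeUm", "BinaryMask", function(object) object@pixelSizeUm)

#' @rdname SectionImage-class
#' @export
setMethod("depthUm", "SectionImage", function(object) object@depthUm)

#' @rdname SectionImage-class
#' @export
setMethod("slideId", "SectionImage", function(object) object@slideId)

#' @rdname SectionImage-class
#' @export
setMethod("stainKind", "SectionImage", function(object) object@stainKind)

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@pixels)
  cat("SectionImage:", object@slideId, "\n",
      " ", d[1], "x", d[2], "px at", object@pixelSizeUm, "um/px,",
      "depth", object@depthUm, "um\n",
      "  stain:", object@stainKind, "\n")
})

#' Construct stain vectors
#'
#' Builds a [StainVectors-class] basis from raw RGB absorbance vectors.
#' Columns are normalized to unit length; tiny negative components from
#' measurement round-off are clipped to zero.
#'
#' @param vectors 3 x k numeric matrix (k = 2 or 3) of RGB absorbances,
#'   one column per stain.
#' @param names stain labels, one per column.
#' @return a [StainVectors-class] object.
#' @examples
#' sv <- stainVectors(cbind(c(0.65, 0.70, 0.29), c(0.27, 0.57, 0.78)),
#'                    names = c("hematoxylin", "dab"))
#' stainMatrix(sv)
#' @export
stainVectors <- function(vectors, names = colnames(vectors)) {
  vectors <- as.matrix(vectors)
  if (is.null(names)) names <- paste0("stain", seq_len(ncol(vectors)))
  vectors[vectors < 0 & vectors > -1e-12] <- 0
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop("stain vectors must be non-zero")
  vectors <- sweep(vectors, 2, nrm, "/")
  rownames(vectors) <- c("R", "G", "B")
  new("StainVectors", vectors = vectors, names = as.character(names))
}

#' @rdname StainVectors-class
#' @param object an object.
#' @export
setMethod("stainMatrix", "StainVectors", function(object) object@vectors)

#' @rdname StainVectors-class
#' @export
setMethod("stainNames", "StainVectors", function(object) object@names)

setMethod("show", "StainVectors", function(object) {
  cat("StainVectors:", paste(object@names, collapse = ", "), "\n")
  print(round(object@vectors, 4))
})

#' @rdname ODImage-class
#' @param object an object.
#' @export
setMethod("odArray", "ODImage", function(object) object@od)

setMethod("show", "ODImage", function(object) {
  d <- dim(object@od)
  cat("ODImage from", object@source, ":", d[1], "x", d[2],
      "px, max OD", round(max(object@od), 3), "\n")
})

#' Construct a BinaryMask
#'
#' @param mask logical matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @param label `"nsc"` or `"tumor"`.
#' @return a [BinaryMask-class] object.
#' @examples
#' m <- binaryMask(matrix(c(TRUE, FALSE), 2, 2), pixelSizeUm = 1,
#'                 label = "nsc")
#' sum(maskArray(m))
#' @export
binaryMask <- function(mask, pixelSizeUm = 1, label = c("nsc", "tumor")) {
  label <- match.arg(label)
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask, pixelSizeUm = as.numeric(pixelSizeUm),
      label = label)
}

#' @rdname BinaryMask-class
#' @export
setMethod("maskArray", "BinaryMask", function(object) object@mask)

#' @rdname BinaryMask-class
#' @export
setMethod("maskLabel", "BinaryMask", function(object) object@label)

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat("BinaryMask (", object@label, "): ", d[1], " x ", d[2], " px, ",
      sum(object@mask), " positive (",
      round(100 * mean(object@mask), 2), "%)\n", sep = "")
})

#' Construct a serial-section sampling scheme
#'
#' @param sectionThicknessUm section thickness, um.
#' @param analysisSpacingUm spacing between analyzed sections, um; must be
#'   a positive multiple of the thickness.
#' @param slidesPerGroup slides per analysis group.
#' @return a [SamplingScheme-class] object.
#' @examples
#' samplingScheme()              # 10 um sections analyzed every 200 um
#' @export
samplingScheme <- function(sectionThicknessUm = 10, analysisSpacingUm = 200,
                           slidesPerGroup = 10) {
  new("SamplingScheme",
      sectionThicknessUm = as.numeric(sectionThicknessUm),
      analysisSpacingUm = as.numeric(analysisSpacingUm),
      slidesPerGroup = as.numeric(slidesPerGroup))
}

setMethod("show", "SamplingScheme", function(object) {
  cat("SamplingScheme:", object@sectionThicknessUm, "um sections,",
      "analyzed every", object@analysisSpacingUm, "um",
      "(groups of", object@slidesPerGroup, "slides)\n")
})
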