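#' @import methods
NULL

#' Single RGB histology section with physical calibration
#'
#' An RGB whole-section image together with its physical calibration and
#' position in the serial-section stack. Intensities live on the scanner
#' scale [0, 255]; they may be non-integer (e.g. synthetic renderings kept
#' unquantized so that downstream optical-density arithmetic is exact).
#'
#' @slot pixels numeric H x W x 3 array of intensities in [0, 255].
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot depthUm depth of the section below the reference surface, in um.
#' @slot slideId character identifier of the slide.
#' @slot stainKind one of `"nsc_prussian_blue"` (iron-labeled NSCs,
#'   Prussian blue with pararosaniline counterstain) or `"tumor_dab"`
#'   (DAB immunostain of tumor cells with hematoxylin counterstain).
#'
#' @seealso [sectionImage()], [rgbToOD()]
#' @exportClass SectionImage
setClass("SectionImage",
  representation(
    pixels = "array",
    pixelSizeUm = "numeric",
    depthUm = "numeric",
    slideId = "character",
    stainKind = "character"
  )
)

setValidity("SectionImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1] < 1L || d[2] < 1L)
    msg <- c(msg, "image must have at least one row and one column")
  if (anyNA(object@pixels) || !all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite")
  else if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixel intensities must lie in [0, 255]")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!object@stainKind %in% c("nsc_prussian_blue", "tumor_dab"))
    msg <- c(msg, "stainKind must be 'nsc_prussian_blue' or 'tumor_dab'")
  if (length(msg)) msg else TRUE
})

#' Optical-density color basis for a stain set
#'
#' Unit RGB optical-density vectors, one per stain, forming the mixing
#' matrix of Beer-Lambert color deconvolution. Columns are stains, rows are
#' the R, G, B absorbances. Vectors are normalized to unit Euclidean length
#' on construction.
#'
#' @slot vectors 3 x k numeric matrix (k = 2 or 3), each column a unit
#'   vector with non-negative components.
#' @slot names character vector of stain labels, one per column.
#'
#' @seealso [stainVectors()], [stainPresets()], [deconvolveStains()]
#' @exportClass StainVectors
setClass("StainVectors",
  representation(vectors = "matrix", names = "character")
)

setValidity("StainVectors", function(object) {
  v <- object@vectors
  msg <- character()
  if (nrow(v) != 3L || !ncol(v) %in% c(2L, 3L))
    msg <- c(msg, "vectors must be a 3 x 2 or 3 x 3 matrix")
  else {
    if (any(v < -1e-12)) msg <- c(msg, "stain vectors must be non-negative")
    nrm <- sqrt(colSums(v^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "stain vectors must have unit Euclidean norm")
    if (ncol(v) == 3L && abs(det(v)) < 1e-10)
      msg <- c(msg, "stain vectors must be linearly independent")
    if (ncol(v) == 2L && qr(v)$rank < 2L)
      msg <- c(msg, "stain vectors must be linearly independent")
  }
  if (length(object@names) != ncol(v))
    msg <- c(msg, "one name per stain vector is required")
  if (length(msg)) msg else TRUE
})

#' Optical-density image
#'
#' Per-channel Beer-Lambert optical density of an RGB section,
#' \eqn{OD = -\log_{10}(I / I_0)}, floored at zero.
#'
#' @slot od non-negative H x W x 3 numeric array.
#' @slot source slide identifier of the originating section.
#' @seealso [rgbToOD()], [deconvolveStains()]
#' @exportClass ODImage
setClass("ODImage", representation(od = "array", source = "character"))

setValidity("ODImage", function(object) {
  d <- dim(object@od)
  if (length(d) != 3L || d[3] != 3L)
    return("od must be an H x W x 3 array")
  if (anyNA(object@od) || !all(is.finite(object@od)))
    return("od must be finite")
  if (min(object@od) < 0)
    return("od must be non-negative")
  TRUE
})

#' Binary segmentation mask
#'
#' A per-pixel boolean mask for one stain class on one section, retaining
#' the physical pixel size so areas and distances can be expressed in um.
#'
#' @slot mask logical H x W matrix.
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot label `"nsc"` or `"tumor"`.
#' @seealso [segmentStain()], [binaryMask()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "matrix", pixelSizeUm = "numeric", label = "character")
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 2L)
    msg <- c(msg, "mask must be a logical matrix")
  if (anyNA(object@mask)) msg <- c(msg, "mask must not contain NA")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!object@label %in% c("nsc", "tumor"))
    msg <- c(msg, "label must be 'nsc' or 'tumor'")
  if (length(msg)) msg else TRUE
})

#' Serial-section sampling scheme
#'
#' The stereological sampling design: section thickness, spacing between
#' analyzed sections, and the number of slides per group from which one
#' section is analyzed. One analyzed section stands for the whole
#' inter-analysis interval, so counts extrapolate by
#' `analysisSpacingUm / sectionThicknessUm` and areas integrate by the
#' Cavalieri rule, area times spacing.
#'
#' @slot sectionThicknessUm physical section thickness in um (default 10).
#' @slot analysisSpacingUm spacing between analyzed sections in um
#'   (default 200); must be a positive multiple of the thickness.
#' @slot slidesPerGroup slides per analysis group (default 10).
#' @seealso [samplingScheme()], [cavalieriVolume()], [extrapolateCounts()]
#' @exportClass SamplingScheme
setClass("SamplingScheme",
  representation(
    sectionThicknessUm = "numeric",
    analysisSpacingUm = "numeric",
    slidesPerGroup = "numeric"
  )
)

setValidity("SamplingScheme", function(object) {
  t <- object@sectionThicknessUm
  s <- object@analysisSpacingUm
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    return("sectionThicknessUm must be a single positive number")
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    return("analysisSpacingUm must be a single positive number")
  k <- s / t
  if (abs(k - round(k)) > 1e-9)
    return("analysisSpacingUm must be a positive multiple of sectionThicknessUm")
  if (object@slidesPerGroup < 1)
    return("slidesPerGroup must be at least 1")
  TRUE
})

#' Specification of a synthetic two-stain phantom brain
#'
#' All parameters of the seeded synthetic-histology generator: field
#' geometry, serial-section sampling, tumor shape (an ellipsoid with
#' low-order angular irregularity of the margin), the NSC point pattern
#' (a mixture of uniform interior points, Thomas-process clusters and
#' edge-rim points), and the Beer-Lambert rendering model for both slide
#' types. The seed fixes every downstream draw.
#'
#' @slot imageSizePx integer length-2, rows and columns of each section.
#' @slot pixelSizeUm um per pixel.
#' @slot nSections number of analyzed depths.
#' @slot spacingUm spacing between analyzed depths, um.
#' @slot sectionThicknessUm physical section thickness, um.
#' @slot tumorCenterUm length-3 (x, y, depth) center of the tumor, um.
#' @slot tumorSemiAxesUm length-3 ellipsoid semi-axes (x, y, depth), um.
#' @slot irregularityAmplitude relative amplitude of the angular margin
#'   modulation (0 disables it, giving an exact ellipsoid).
#' @slot irregularityModes integer angular mode numbers of the modulation.
#' @slot nNscTotal number of NSCs retained at the tumor (points placed).
#' @slot administeredNsc number of NSCs administered; the retained
#'   fraction is `nNscTotal / administeredNsc`.
#' @slot clusterFraction fraction of NSCs placed in Thomas-process clusters.
#' @slot clustersMeanOffspring mean NSCs per cluster parent.
#' @slot clusterSdUm isotropic Gaussian spread of cluster offspring, um.
#' @slot edgeBias fraction of NSCs placed in a rim at the tumor margin.
#' @slot rimWidthUm in-plane width of the edge rim, um.
#' @slot cellRadiusUm rendered NSC radius, um.
#' @slot nscStains,tumorStains [StainVectors-class] for the two slide types.
#' @slot nscConcentration,tumorConcentration rendered chromagen
#'   concentration (OD-scale) on target-stain objects.
#' @slot counterstainConcentration rendered counterstain concentration over
#'   the whole tissue field.
#' @slot backgroundIntensity scanner white point (blank-slide intensity).
#' @slot noiseSd Gaussian intensity noise sd (scanner-scale units).
#' @slot seed integer random seed.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    imageSizePx = "integer",
    pixelSizeUm = "numeric",
    nSections = "integer",
    spacingUm = "numeric",
    sectionThicknessUm = "numeric",
    tumorCenterUm = "numeric",
    tumorSemiAxesUm = "numeric",
    irregularityAmplitude = "numeric",
    irregularityModes = "integer",
    nNscTotal = "integer",
    administeredNsc = "integer",
    clusterFraction = "numeric",
    clustersMeanOffspring = "numeric",
    clusterSdUm = "numeric",
    edgeBias = "numeric",
    rimWidthUm = "numeric",
    cellRadiusUm = "numeric",
    nscStains = "StainVectors",
    tumorStains = "StainVectors",
    nscConcentration = "numeric",
    tumorConcentration = "numeric",
    counterstainConcentration = "numeric",
    backgroundIntensity = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 1L))
    msg <- c(msg, "imageSizePx must be two positive integers")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (object@nSections < 1L) msg <- c(msg, "nSections must be at least 1")
  if (object@spacingUm <= 0 || object@sectionThicknessUm <= 0)
    msg <- c(msg, "spacing and thickness must be positive")
  if (length(object@tumorCenterUm) != 3L || length(object@tumorSemiAxesUm) != 3L)
    msg <- c(msg, "tumorCenterUm and tumorSemiAxesUm must have length 3")
  if (any(object@tumorSemiAxesUm <= 0))
    msg <- c(msg, "tumor semi-axes must be positive")
  if (object@irregularityAmplitude < 0)
    msg <- c(msg, "irregularityAmplitude must be non-negative")
  if (object@nNscTotal < 0L || object@administeredNsc < 0L)
    msg <- c(msg, "NSC counts must be non-negative")
  if (object@nNscTotal > object@administeredNsc)
    msg <- c(msg, "nNscTotal cannot exceed administeredNsc")
  fr <- c(object@clusterFraction, object@edgeBias)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    msg <- c(msg, "clusterFraction and edgeBias must be in [0,1] and sum to at most 1")
  if (object@clustersMeanOffspring <= 0 || object@clusterSdUm < 0)
    msg <- c(msg, "cluster parameters must be positive")
  if (object@cellRadiusUm <= 0) msg <- c(msg, "cellRadiusUm must be positive")
  if (object@backgroundIntensity <= 0 || object@backgroundIntensity > 255)
    msg <- c(msg, "backgroundIntensity must be in (0, 255]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})
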