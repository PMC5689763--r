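# Beer-Lambert optical density and Ruifrok-Johnston color deconvolution.
#
# A chromagen-stained pixel attenuates incident light according to
# I = I0 * 10^(-OD), with OD the sum over stains of concentration times the
# stain's unit RGB absorbance vector. Deconvolution inverts that 3 x 3
# linear system per pixel, yielding one concentration channel per stain.

#' Convert an RGB section to optical density
#'
#' Applies \eqn{OD = -\log_{10}(\max(I, 1) / I_0)} per channel, where
#' \eqn{I_0} is the blank-slide (background) intensity. Intensities are
#' floored at 1 before the logarithm so saturated-dark pixels map to a
#' finite density; densities are clipped below at 0 (pixels brighter than
#' the background carry no absorbance information).
#'
#' @param image a [SectionImage-class].
#' @param backgroundIntensity blank-slide intensity in (0, 255], default 255.
#' @return an [ODImage-class].
#' @examples
#' img <- sectionImage(array(255, dim = c(4, 4, 3)))
#' max(odArray(rgbToOD(img)))   # blank slide -> OD 0
#' @seealso [odToRGB()], [deconvolveStains()]
#' @export
rgbToOD <- function(image, backgroundIntensity = 255) {
  stopifnot(is(image, "SectionImage"))
  if (backgroundIntensity <= 0 || backgroundIntensity > 255)
    stop("'backgroundIntensity' must lie in (0, 255]")
  od <- -log10(pmax(image@pixels, 1) / backgroundIntensity)
  od[od < 0] <- 0
  new("ODImage", od = od, source = image@slideId)
}

#' Convert optical density back to RGB intensities
#'
#' Inverse of [rgbToOD()]: \eqn{I = I_0 \cdot 10^{-OD}}, clipped to
#' [0, 255]. Round-tripping an image through [rgbToOD()] and back
#' reproduces it within one intensity level (exactly, away from the
#' intensity floor).
#'
#' @param od an [ODImage-class] or a H x W x 3 numeric array of densities.
#' @param backgroundIntensity blank-slide intensity, default 255.
#' @param slideId,stainKind metadata for the reconstructed section.
#' @return a [SectionImage-class].
#' @export
odToRGB <- function(od, backgroundIntensity = 255, slideId = "recomposed",
                    stainKind = "tumor_dab") {
  arr <- if (is(od, "ODImage")) od@od else od
  px <- backgroundIntensity * 10^(-arr)
  px[px > 255] <- 255
  px[px < 0] <- 0
  sectionImage(px, pixelSizeUm = 1, depthUm = 0, slideId = slideId,
               stainKind = stainKind)
}

#' Published and renderer stain bases
#'
#' Returns preset [StainVectors-class] pairs. `"h_dab"` is the published
#' Ruifrok-Johnston hematoxylin/DAB basis used by the standard color
#' deconvolution plugin. `"prussian_pararosaniline"` is the basis for the
#' iron stain slides (Prussian blue chromagen, pararosaniline
#' counterstain); no published basis exists for this pair, so the default
#' is the pair of vectors used by the package's own synthetic renderer and
#' should be replaced by measured vectors for real slides.
#'
#' @param name `"h_dab"` or `"prussian_pararosaniline"`.
#' @return a [StainVectors-class] with two stains, target chromagen last.
#' @examples
#' stainPresets("h_dab")
#' @export
stainPresets <- function(name = c("h_dab", "prussian_pararosaniline")) {
  name <- match.arg(name)
  switch(name,
    h_dab = stainVectors(
      cbind(hematoxylin = c(0.650, 0.704, 0.286),
            dab = c(0.268, 0.570, 0.776))),
    prussian_pararosaniline = stainVectors(
      cbind(pararosaniline = c(0.175, 0.972, 0.155),
            prussian_blue = c(0.720, 0.650, 0.242)))
  )
}

#' Complete a two-stain basis with a residual third vector
#'
#' The deconvolution system needs three independent vectors. Given two,
#' the third is completed channel-wise as
#' \eqn{v_{3,i} = \sqrt{\max(0, 1 - v_{1,i}^2 - v_{2,i}^2)}} and
#' normalized — the convention of the standard plugin, which keeps the
#' residual axis non-negative.
#'
#' @param stains a [StainVectors-class] with 2 columns.
#' @return a [StainVectors-class] with 3 columns, the completed residual
#'   last (named `"residual"`).
#' @export
completeStainBasis <- function(stains) {
  stopifnot(is(stains, "StainVectors"))
  v <- stains@vectors
  if (ncol(v) == 3L) return(stains)
  v3 <- sqrt(pmax(0, 1 - v[, 1]^2 - v[, 2]^2))
  if (sum(v3^2) < 1e-12) {
    # both stains saturate every channel; fall back to the cross product
    v3 <- abs(c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
                v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
                v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2]))
  }
  m <- cbind(v, residual = v3 / sqrt(sum(v3^2)))
  if (abs(det(m)) < 1e-10)
    stop("degenerate stain basis: completed matrix is singular")
  stainVectors(m, names = c(stains@names, "residual"))
}

#' Unmix stains by color deconvolution
#'
#' Solves, per pixel, the Beer-Lambert mixture \eqn{OD = M c} for the
#' stain concentrations \eqn{c}, where the columns of \eqn{M} are the
#' stain vectors. If two stains are supplied the basis is completed with
#' the normalized residual vector ([completeStainBasis()]). Raw
#' concentrations are returned unclipped — negative values (noise pushed
#' outside the stain simplex) are only clipped later, at mask building.
#'
#' @param od an [ODImage-class] (or H x W x 3 array).
#' @param stains a [StainVectors-class].
#' @return H x W x k numeric array of concentration channels, in the
#'   input stain order (dimnames carry the stain names; a completed
#'   residual channel comes last).
#' @examples
#' img <- sectionImage(array(c(100, 120, 180), dim = c(2, 2, 3)))
#' ch <- deconvolveStains(rgbToOD(img), stainPresets("h_dab"))
#' dimnames(ch)[[3]]
#' @seealso [recomposeOD()], [segmentStain()]
#' @export
deconvolveStains <- function(od, stains) {
  arr <- if (is(od, "ODImage")) od@od else od
  stopifnot(is(stains, "StainVectors"))
  full <- completeStainBasis(stains)
  m <- full@vectors
  if (abs(det(m)) < 1e-10) stop("degenerate stain basis: singular matrix")
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = 3)
  conc <- flat %*% t(solve(m))
  out <- array(conc, dim = c(d[1], d[2], ncol(m)),
               dimnames = list(NULL, NULL, full@names))
  # return only the channels the caller asked for, in input order,
  # plus the residual channel when the basis was completed
  out
}

#' Recompose optical density from concentration channels
#'
#' Forward model \eqn{OD = M c}; the exact inverse of
#' [deconvolveStains()] when three independent stains are supplied.
#'
#' @param channels H x W x k concentration array.
#' @param stains the [StainVectors-class] used for deconvolution.
#' @return H x W x 3 optical-density array.
#' @export
recomposeOD <- function(channels, stains) {
  stopifnot(is(stains, "StainVectors"))
  m <- completeStainBasis(stains)@vectors
  d <- dim(channels)
  if (d[3] != ncol(m))
    stop("channel count does not match the stain basis")
  flat <- matrix(channels, nrow = d[1] * d[2], ncol = d[3])
  array(flat %*% t(m), dim = c(d[1], d[2], 3))
}

#' Otsu threshold of a concentration channel
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' channel range; used by [segmentStain()] when `threshold = "otsu"`.
#'
#' @param channel numeric matrix or array.
#' @param nbins number of histogram bins.
#' @return scalar threshold on the channel's own scale.
#' @export
otsuThreshold <- function(channel, nbins = 256) {
  x <- as.numeric(channel)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  # sb is flat across an empty histogram gap; cut at the plateau midpoint
  mean(mids[sb >= max(sb) - 1e-12])
}

#' Segment a concentration channel into a binary mask
#'
#' Thresholds the channel at `threshold` (pixels with concentration >=
#' threshold are positive) and removes 8-connected components smaller than
#' `minObjectPx` pixels. An empty result is valid.
#'
#' @param channel numeric matrix, one deconvolved concentration channel.
#' @param threshold scalar concentration cutoff (>= 0), or `"otsu"` for
#'   automatic thresholding via [otsuThreshold()].
#' @param minObjectPx minimum connected-component size in pixels, >= 0.
#' @param pixelSizeUm um per pixel, recorded in the mask.
#' @param label mask label, `"nsc"` or `"tumor"`.
#' @return a [BinaryMask-class].
#' @examples
#' ch <- matrix(0, 16, 16); ch[4:9, 4:9] <- 1
#' sum(maskArray(segmentStain(ch, threshold = 0.5, label = "nsc")))
#' @export
segmentStain <- function(channel, threshold = 0.3, minObjectPx = 0,
                         pixelSizeUm = 1, label = c("nsc", "tumor")) {
  label <- match.arg(label)
  channel <- as.matrix(channel)
  if (identical(threshold, "otsu")) threshold <- otsuThreshold(channel)
  if (!is.numeric(threshold) || threshold < 0)
    stop("'threshold' must be a non-negative number or \"otsu\"")
  if (minObjectPx < 0) stop("'minObjectPx' must be >= 0")
  mask <- channel >= threshold
  if (minObjectPx > 0 && any(mask)) {
    lab <- .label_components(mask)
    sz <- tabulate(lab[lab > 0L])
    keep <- which(sz >= minObjectPx)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  binaryMask(mask, pixelSizeUm = pixelSizeUm, label = label)
}
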