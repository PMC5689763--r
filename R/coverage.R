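# Radius-of-action tumor coverage by a diffusible therapeutic secreted
# from NSC-marked regions, via an exact Euclidean distance transform.

#' Distance to the nearest positive mask pixel
#'
#' Exact Euclidean distance, in um, from every pixel center to the nearest
#' positive pixel center of the mask (0 on positive pixels, Inf if the
#' mask is empty). Computed with an exact squared distance transform, so
#' thresholding the result agrees pixel-for-pixel with brute-force
#' nearest-neighbor enumeration.
#'
#' @param mask a [BinaryMask-class].
#' @return numeric matrix of distances in um.
#' @export
maskDistanceMap <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sqrt(.edt_sq(mask@mask)) * mask@pixelSizeUm
}

#' Percent tumor coverage within a radius of action
#'
#' A tumor pixel is covered when the Euclidean distance from its center to
#' the nearest NSC-positive pixel center is at most the radius of action
#' (distance 0 where tumor and NSC pixels coincide). Returns 100 x covered
#' / total tumor pixels for each requested radius. With an empty NSC mask
#' the coverage is 0 (sections are evaluated whether or not NSCs are
#' present); an empty tumor mask leaves coverage undefined and is an
#' error.
#'
#' Internally the squared distance transform of the NSC mask is
#' thresholded against the squared radius in pixel units; both sides are
#' exact, so the result equals brute-force per-pixel enumeration exactly.
#'
#' @param nscMask,tumorMask [BinaryMask-class] objects of identical shape
#'   and pixel size (consecutive sections, assumed co-registered).
#' @param radiusUm radius of action in um; may be a vector (the study
#'   radii are 25 and 50).
#' @param offsetPx optional integer (rowShift, colShift) rigid offset
#'   applied to the NSC mask before measurement, for stacks whose pairs
#'   need a known translation; default none.
#' @return named numeric vector of percentages in [0, 100], one per
#'   radius.
#' @examples
#' tum <- binaryMask(matrix(TRUE, 64, 64), 1, "tumor")
#' nsc <- matrix(FALSE, 64, 64); nsc[32, 32] <- TRUE
#' coverageFraction(binaryMask(nsc, 1, "nsc"), tum, radiusUm = c(25, 50))
#' @seealso [theoreticalMaxCoverage()], [coverageEfficiency()]
#' @export
coverageFraction <- function(nscMask, tumorMask, radiusUm = c(25, 50),
                             offsetPx = c(0L, 0L)) {
  stopifnot(is(nscMask, "BinaryMask"), is(tumorMask, "BinaryMask"))
  if (!identical(dim(nscMask@mask), dim(tumorMask@mask)))
    stop("NSC and tumor masks must share their shape")
  if (abs(nscMask@pixelSizeUm - tumorMask@pixelSizeUm) > 1e-9)
    stop("NSC and tumor masks must share their pixel size")
  if (any(radiusUm < 0)) stop("'radiusUm' must be non-negative")
  ntum <- sum(tumorMask@mask)
  if (ntum == 0L) stop("empty tumor mask: coverage undefined")
  nsc <- nscMask@mask
  if (any(offsetPx != 0L)) nsc <- .shiftMask(nsc, offsetPx)
  out <- stats::setNames(numeric(length(radiusUm)),
                         paste0("cov_", radiusUm, "um"))
  if (!any(nsc)) return(out)
  d2 <- .edt_sq(nsc)
  d2t <- d2[tumorMask@mask]
  rpx2 <- (radiusUm / tumorMask@pixelSizeUm)^2
  for (k in seq_along(radiusUm))
    out[k] <- 100 * sum(d2t <= rpx2[k]) / ntum
  out
}

# integer rigid shift, padding with FALSE
.shiftMask <- function(m, offsetPx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  dr <- as.integer(offsetPx[1]); dc <- as.integer(offsetPx[2])
  src_r <- seq_len(H) - dr
  src_c <- seq_len(W) - dc
  ok_r <- src_r >= 1L & src_r <= H
  ok_c <- src_c >= 1L & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Theoretical maximum coverage under homogeneous NSC placement
#'
#' Upper bound for the coverage achievable by `nNsc` cells spread through
#' the tumor so that their disks of action neither overlap each other nor
#' spill outside the tumor: `min(100, 100 * n * pi * (radius +
#' cellRadius)^2 / area)`. The disk is measured from the cell edge, hence
#' the effective radius `radiusUm + cellRadiusUm`.
#'
#' @param nNsc number of NSCs on the section (>= 0; non-integer
#'   pixel-ratio counts are accepted).
#' @param tumorAreaUm2 tumor area of the section, um^2 (> 0).
#' @param radiusUm radius of action, um.
#' @param cellRadiusUm equivalent NSC radius, um; default 4.5 (8-10 um
#'   diameter cells).
#' @return percent in [0, 100].
#' @examples
#' theoreticalMaxCoverage(10, 1e4, radiusUm = sqrt(100 / pi),
#'                        cellRadiusUm = 0)   # 10
#' @export
theoreticalMaxCoverage <- function(nNsc, tumorAreaUm2, radiusUm = 50,
                                   cellRadiusUm = 4.5) {
  if (tumorAreaUm2 <= 0) stop("zero tumor area: theoretical maximum undefined")
  if (nNsc < 0) stop("'nNsc' must be non-negative")
  pmin(100, 100 * nNsc * pi * (radiusUm + cellRadiusUm)^2 / tumorAreaUm2)
}

#' Coverage efficiency
#'
#' Observed coverage divided by the homogeneous-placement theoretical
#' maximum. Values above 1 are possible only through the 100% cap of the
#' theoretical maximum and are returned unclipped with a warning.
#'
#' @param observedPct observed percent coverage.
#' @param theoreticalPct theoretical maximum percent coverage (> 0).
#' @return efficiency ratio, usually in [0, 1].
#' @export
coverageEfficiency <- function(observedPct, theoreticalPct) {
  if (any(theoreticalPct <= 0))
    stop("zero theoretical coverage: efficiency undefined")
  eff <- observedPct / theoreticalPct
  if (any(eff > 1 + 1e-12))
    warning("efficiency above 1: theoretical maximum was capped at 100%")
  eff
}

#' Render a coverage overlay image
#'
#' Writes (or returns) an RGB overlay in the style of the study's coverage
#' figure: tumor in dark green, tumor within the radius of action in light
#' green, NSC pixels in red, background white.
#'
#' @param nscMask,tumorMask [BinaryMask-class] objects.
#' @param radiusUm radius of action, um.
#' @param file optional PNG path; if `NULL`, the H x W x 3 array in
#'   [0, 1] is returned invisibly.
#' @return the overlay array, invisibly.
#' @export
coverageOverlay <- function(nscMask, tumorMask, radiusUm = 50, file = NULL) {
  stopifnot(is(nscMask, "BinaryMask"), is(tumorMask, "BinaryMask"))
  d2 <- .edt_sq(nscMask@mask)
  rpx2 <- (radiusUm / nscMask@pixelSizeUm)^2
  covered <- tumorMask@mask & (d2 <= rpx2) & any(nscMask@mask)
  H <- nrow(d2); W <- ncol(d2)
  r <- matrix(1, H, W); g <- matrix(1, H, W); b <- matrix(1, H, W)
  dark <- tumorMask@mask & !covered
  r[dark] <- 0.00; g[dark] <- 0.35; b[dark] <- 0.10
  r[covered] <- 0.55; g[covered] <- 0.90; b[covered] <- 0.45
  r[nscMask@mask] <- 0.85; g[nscMask@mask] <- 0.10; b[nscMask@mask] <- 0.10
  arr <- array(c(r, g, b), dim = c(H, W, 3))
  if (!is.null(file)) png::writePNG(arr, target = file)
  invisible(arr)
}
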