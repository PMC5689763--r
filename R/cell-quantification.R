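# Per-section cell counts, centroids and tumor areas from binary masks.
#
# Coordinate convention used throughout: 0-based pixel indices, x = column
# * pixelSizeUm, y = row * pixelSizeUm, origin at the top-left pixel
# center.

#' Count cells by the marked-pixel ratio
#'
#' Estimates the number of cells on a section as total marked area divided
#' by the mean single-cell area: `(pixels * pixelSizeUm^2) /
#' meanCellAreaUm2`. The estimate is a real number and is deliberately not
#' rounded, so that serial-section extrapolation stays linear; round only
#' for display.
#'
#' @param mask a [BinaryMask-class] of the cell stain.
#' @param meanCellAreaUm2 mean area of one cell in um^2; the default 64
#'   corresponds to a 9 um diameter cell, mid-range for 8-10 um NSCs.
#' @return non-negative numeric cell-equivalent count.
#' @examples
#' m <- binaryMask(matrix(rep(c(TRUE, FALSE), c(640, 360)), 40, 25),
#'                 pixelSizeUm = 1, label = "nsc")
#' countCellsPixelRatio(m, meanCellAreaUm2 = 64)   # 10
#' @export
countCellsPixelRatio <- function(mask, meanCellAreaUm2 = 64) {
  stopifnot(is(mask, "BinaryMask"))
  if (!is.numeric(meanCellAreaUm2) || meanCellAreaUm2 <= 0)
    stop("'meanCellAreaUm2' must be positive")
  sum(mask@mask) * mask@pixelSizeUm^2 / meanCellAreaUm2
}

#' Detect individually resolved cells
#'
#' Finds 8-connected components of the mask with area inside
#' `[minAreaUm2, maxAreaUm2]` and reports one detection per component:
#' the unweighted pixel centroid in um and the component area. Detections
#' are ordered row-major by centroid (y, then x). An automated stand-in
#' for manual counting of individually resolved cells; touching cells are
#' not split (see package non-goals).
#'
#' @param mask a [BinaryMask-class].
#' @param minAreaUm2,maxAreaUm2 inclusive area band for a single cell,
#'   um^2, with `0 <= minAreaUm2 < maxAreaUm2`.
#' @return data.frame with columns `x_um`, `y_um`, `area_um2`.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[4:9, 4:9] <- TRUE; m[20:25, 12:17] <- TRUE
#' detectCells(binaryMask(m, 1, "nsc"), minAreaUm2 = 10, maxAreaUm2 = 100)
#' @export
detectCells <- function(mask, minAreaUm2 = 20, maxAreaUm2 = 400) {
  stopifnot(is(mask, "BinaryMask"))
  if (minAreaUm2 < 0 || minAreaUm2 >= maxAreaUm2)
    stop("need 0 <= minAreaUm2 < maxAreaUm2")
  ps <- mask@pixelSizeUm
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0))
  if (!any(mask@mask)) return(empty)
  lab <- .label_components(mask@mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab)      # 0-based row
  cols <- (idx - 1L) %/% nrow(lab)     # 0-based column
  npx <- tabulate(comp)
  area <- npx * ps^2
  keep <- which(area >= minAreaUm2 & area <= maxAreaUm2)
  if (!length(keep)) return(empty)
  cx <- (tapply(cols, comp, sum) / npx)[keep] * ps
  cy <- (tapply(rows, comp, sum) / npx)[keep] * ps
  out <- data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy),
                    area_um2 = area[keep])
  out[order(out$y_um, out$x_um), , drop = FALSE]
}

#' Tumor area of a section
#'
#' @param mask a [BinaryMask-class] with label `"tumor"`.
#' @return area in um^2 (pixel count times pixel area).
#' @examples
#' tumorArea(binaryMask(matrix(TRUE, 100, 100), 1, "tumor"))  # 1e4 um^2
#' @export
tumorArea <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  if (mask@label != "tumor")
    stop("tumorArea expects a mask labeled 'tumor'")
  sum(mask@mask) * mask@pixelSizeUm^2
}
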