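# Serial-section stereology: Cavalieri volumes, count extrapolation,
# whole-tumor aggregates and densities.

# one central place for the unit conversion
.um3ToMm3 <- function(x) x / 1e9

#' Cavalieri tumor volume from serial-section areas
#'
#' Rectangular Cavalieri estimator: each analyzed section's area is
#' extrapolated over the spacing separating analyzed sections,
#' `V = sum(area_i) * spacing`, converted to mm^3. No end-correction is
#' applied.
#'
#' @param sectionAreasUm2 per-section tumor areas in um^2, ordered by
#'   depth at the scheme's spacing. An empty list gives volume 0.
#' @param scheme a [SamplingScheme-class]; default 10 um sections analyzed
#'   every 200 um.
#' @return volume in mm^3.
#' @examples
#' cavalieriVolume(rep(2e6, 5))   # five 2 mm^2 sections, 200 um apart -> 2
#' @export
cavalieriVolume <- function(sectionAreasUm2, scheme = samplingScheme()) {
  stopifnot(is(scheme, "SamplingScheme"))
  if (!length(sectionAreasUm2)) return(0)
  if (any(sectionAreasUm2 < 0)) stop("areas must be non-negative")
  .um3ToMm3(sum(sectionAreasUm2) * scheme@analysisSpacingUm)
}

#' Extrapolate per-section cell counts to a whole-tumor total
#'
#' One analyzed section stands for its whole inter-analysis interval, so
#' the total is `sum(count_i) * (spacing / thickness)` — a factor of 20
#' under the default 200 um spacing of 10 um sections.
#'
#' @param sectionCounts per-section counts (non-negative, may be
#'   non-integer pixel-ratio estimates).
#' @param scheme a [SamplingScheme-class].
#' @return extrapolated total count.
#' @examples
#' extrapolateCounts(c(10, 20))   # 600
#' @export
extrapolateCounts <- function(sectionCounts, scheme = samplingScheme()) {
  stopifnot(is(scheme, "SamplingScheme"))
  if (!length(sectionCounts)) return(0)
  if (any(sectionCounts < 0)) stop("counts must be non-negative")
  sum(sectionCounts) * scheme@analysisSpacingUm / scheme@sectionThicknessUm
}

#' Whole-tumor coverage from per-section coverages
#'
#' Area-weighted mean of the per-section percent coverages — the fraction
#' of total tumor volume reached by the therapeutic under the Cavalieri
#' sampling.
#'
#' @param coveragePct per-section coverage: a numeric vector, or a matrix
#'   with one row per section and one column per radius.
#' @param tumorAreasUm2 per-section tumor areas (same order); total must
#'   be positive.
#' @return percent per radius (named as the columns of `coveragePct`).
#' @examples
#' wholeTumorCoverage(c(100, 0), c(1, 1))   # 50
#' @export
wholeTumorCoverage <- function(coveragePct, tumorAreasUm2) {
  m <- if (is.matrix(coveragePct)) coveragePct else
    matrix(coveragePct, ncol = 1,
           dimnames = list(NULL, "coverage"))
  if (nrow(m) != length(tumorAreasUm2))
    stop("coverage and area lists must match by section")
  if (sum(tumorAreasUm2) <= 0) stop("zero total tumor area: undefined")
  out <- apply(m, 2, stats::weighted.mean, w = tumorAreasUm2)
  if (!is.matrix(coveragePct)) unname(out) else out
}

#' NSC density per tumor volume
#'
#' @param totalCount whole-tumor NSC count.
#' @param tumorVolumeMm3 tumor volume in mm^3 (> 0).
#' @return NSCs per mm^3. Values outside the plausible 1e3-1e6 band for
#'   this assay are reported with an informational message, not an error.
#' @examples
#' nscDensity(600, 0.02)   # 30000
#' @export
nscDensity <- function(totalCount, tumorVolumeMm3) {
  if (tumorVolumeMm3 <= 0) stop("zero tumor volume: density undefined")
  dens <- totalCount / tumorVolumeMm3
  if (dens > 0 && (dens < 1e3 || dens > 1e6))
    message("NSC density ", signif(dens, 3),
            " /mm^3 is outside the usual 1e3-1e6 band")
  dens
}
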