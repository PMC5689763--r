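# End-to-end orchestration: image pair -> per-section quantification ->
# per-brain aggregates -> cohort table and summary statistics.

#' Quantify one aligned two-stain section pair
#'
#' Runs the full per-section pipeline: optical density, color
#' deconvolution with each slide's stain basis (the last stain in a basis
#' is the target chromagen), thresholding into NSC and tumor masks,
#' pixel-ratio NSC counting, resolved-cell detection, tumor area, percent
#' coverage per radius of action, and the clustering index of the
#' detected NSCs.
#'
#' The two stains live on consecutive sections and are assumed
#' co-registered; `offsetPx` applies a known rigid translation to the NSC
#' mask if the pair needs one.
#'
#' @param nscImage,tumorImage the paired [SectionImage-class]s; they must
#'   agree in size and pixel calibration.
#' @param nscStains,tumorStains [StainVectors-class] bases (defaults:
#'   [stainPresets()]).
#' @param backgroundIntensity blank-slide intensity for [rgbToOD()].
#' @param nscThreshold,tumorThreshold concentration cutoffs for
#'   [segmentStain()] (or `"otsu"`).
#' @param minObjectPx small-object removal threshold, px.
#' @param radiiUm radii of action, um.
#' @param clusteringRadiusUm clustering radius for the CI, um.
#' @param meanCellAreaUm2 mean single-cell area for pixel-ratio counting.
#' @param minAreaUm2,maxAreaUm2 area band for resolved-cell detection.
#' @param offsetPx rigid (row, col) shift of the NSC mask, px.
#' @param keepMasks if `TRUE`, attach the binary masks to the result.
#' @return list with `summary` (one-row data.frame: `slide_id`,
#'   `depth_um`, `nsc_count`, `nsc_detected`, `tumor_area_um2`, one
#'   `cov_<r>um` column per radius, `clustering_index`, `n_clusters`),
#'   `centroids` (data.frame), and optionally `masks`.
#' @export
analyzeSectionPair <- function(nscImage, tumorImage,
                               nscStains = stainPresets("prussian_pararosaniline"),
                               tumorStains = stainPresets("h_dab"),
                               backgroundIntensity = 255,
                               nscThreshold = 0.3, tumorThreshold = 0.3,
                               minObjectPx = 0, radiiUm = c(25, 50),
                               clusteringRadiusUm = 50,
                               meanCellAreaUm2 = 64,
                               minAreaUm2 = 20, maxAreaUm2 = 400,
                               offsetPx = c(0L, 0L), keepMasks = FALSE) {
  stopifnot(is(nscImage, "SectionImage"), is(tumorImage, "SectionImage"))
  if (!identical(dim(nscImage@pixels), dim(tumorImage@pixels)))
    stop("paired sections must agree in size")
  if (abs(nscImage@pixelSizeUm - tumorImage@pixelSizeUm) > 1e-9)
    stop("paired sections must agree in pixel calibration")
  ps <- nscImage@pixelSizeUm

  nscCh <- deconvolveStains(rgbToOD(nscImage, backgroundIntensity), nscStains)
  tumCh <- deconvolveStains(rgbToOD(tumorImage, backgroundIntensity),
                            tumorStains)
  iN <- ncol(stainMatrix(nscStains))   # target chromagen channel
  iT <- ncol(stainMatrix(tumorStains))
  nscMask <- segmentStain(nscCh[, , iN], nscThreshold, minObjectPx, ps, "nsc")
  tumMask <- segmentStain(tumCh[, , iT], tumorThreshold, minObjectPx, ps,
                          "tumor")

  area <- tumorArea(tumMask)
  cov <- if (area > 0)
    coverageFraction(nscMask, tumMask, radiiUm, offsetPx)
  else stats::setNames(rep(NA_real_, length(radiiUm)),
                       paste0("cov_", radiiUm, "um"))

  cells <- detectCells(nscMask, minAreaUm2, maxAreaUm2)
  if (nrow(cells) >= 1) {
    cl <- clusterPoints(cells, clusteringRadiusUm)
    ci <- cl$ci; k <- cl$nClusters
  } else {
    ci <- NA_real_; k <- NA_integer_
  }

  summary <- data.frame(
    slide_id = nscImage@slideId,
    depth_um = nscImage@depthUm,
    nsc_count = countCellsPixelRatio(nscMask, meanCellAreaUm2),
    nsc_detected = nrow(cells),
    tumor_area_um2 = area,
    stringsAsFactors = FALSE
  )
  summary <- cbind(summary, as.data.frame(as.list(cov)))
  summary$clustering_index <- ci
  summary$n_clusters <- k
  out <- list(summary = summary, centroids = cells)
  if (keepMasks) out$masks <- list(nsc = nscMask, tumor = tumMask)
  out
}

#' Aggregate per-section measurements into per-brain quantities
#'
#' Applies the serial-section sampling scheme: Cavalieri tumor volume,
#' extrapolated whole-tumor NSC total, percent of the administered dose
#' found at the tumor, NSC density, and area-weighted whole-tumor
#' coverage per radius.
#'
#' @param sections data.frame of per-section rows as produced by
#'   [analyzeSectionPair()] (stacked `summary` rows, ordered by depth).
#' @param scheme a [SamplingScheme-class].
#' @param administeredCount NSCs administered to this animal (NA if
#'   unknown).
#' @param route administration route, `"ic"` or `"iv"` (optional label).
#' @param brainId identifier.
#' @return one-row data.frame of brain-level quantities.
#' @export
analyzeBrain <- function(sections, scheme = samplingScheme(),
                         administeredCount = NA_real_,
                         route = NA_character_, brainId = "brain") {
  stopifnot(is.data.frame(sections))
  if (!is.na(route) && !route %in% c("ic", "iv"))
    stop("route must be 'ic' or 'iv'")
  vol <- cavalieriVolume(sections$tumor_area_um2, scheme)
  total <- extrapolateCounts(sections$nsc_count, scheme)
  covCols <- grep("^cov_", names(sections), value = TRUE)
  withTumor <- sections$tumor_area_um2 > 0
  whole <- if (any(withTumor)) {
    m <- as.matrix(sections[withTumor, covCols, drop = FALSE])
    wholeTumorCoverage(m, sections$tumor_area_um2[withTumor])
  } else stats::setNames(rep(NA_real_, length(covCols)), covCols)
  ciVals <- sections$clustering_index
  out <- data.frame(
    brain_id = brainId,
    route = route,
    administered_nsc = administeredCount,
    tumor_volume_mm3 = vol,
    total_nsc_count = total,
    pct_at_tumor = if (is.na(administeredCount)) NA_real_
                   else 100 * total / administeredCount,
    nsc_density_per_mm3 = if (vol > 0) nscDensity(total, vol) else NA_real_,
    mean_clustering_index = if (any(is.finite(ciVals)))
      mean(ciVals[is.finite(ciVals)]) else NA_real_,
    n_sections = nrow(sections),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(as.list(whole)))
}

#' Run the full pipeline over a rendered phantom
#'
#' Convenience wrapper: applies [analyzeSectionPair()] to every rendered
#' section pair of a [generatePhantom()] result (using the phantom's own
#' stain bases and background) and aggregates with [analyzeBrain()].
#'
#' @param phantom result of [generatePhantom()] with `render = TRUE`.
#' @param spec the [PhantomSpec-class] that generated it.
#' @param radiiUm radii of action, um.
#' @param route route label recorded in the brain row.
#' @param brainId identifier.
#' @param ... further arguments passed to [analyzeSectionPair()].
#' @return list with `sections` (stacked per-section rows), `brain`
#'   (one-row data.frame) and `centroids` (per-section list).
#' @export
analyzePhantom <- function(phantom, spec, radiiUm = c(25, 50),
                           route = "ic", brainId = "phantom", ...) {
  if (is.null(phantom$sections[[1]]$nsc))
    stop("phantom was generated with render = FALSE")
  res <- lapply(phantom$sections, function(s)
    analyzeSectionPair(s$nsc, s$tumor,
                       nscStains = spec@nscStains,
                       tumorStains = spec@tumorStains,
                       backgroundIntensity = spec@backgroundIntensity,
                       radiiUm = radiiUm, ...))
  sections <- do.call(rbind, lapply(res, `[[`, "summary"))
  scheme <- samplingScheme(spec@sectionThicknessUm, spec@spacingUm)
  brain <- analyzeBrain(sections, scheme,
                        administeredCount = spec@administeredNsc,
                        route = route, brainId = brainId)
  list(sections = sections, brain = brain,
       centroids = lapply(res, `[[`, "centroids"))
}

#' Run a phantom cohort and write its reports
#'
#' Generates and analyzes one phantom per spec, assembles the cohort
#' table, computes the study's summary statistics (dose-response
#' regressions and rank correlations), and optionally writes per-section
#' CSVs, per-brain JSONs, a cohort CSV and the statistics table. Rerunning
#' with the same specs reproduces the outputs byte for byte.
#'
#' @param specs list of [PhantomSpec-class] objects (one brain each; set
#'   each spec's `administeredNsc`/`nNscTotal` and `seed`).
#' @param routes route label per brain (recycled).
#' @param radiiUm radii of action, um.
#' @param outDir optional output directory; created if needed.
#' @param ... passed to [analyzeSectionPair()].
#' @return list with `cohort` (one row per brain), `sections` (all
#'   per-section rows), and `stats` (the summary-statistics table).
#' @export
runPhantomCohort <- function(specs, routes = "ic", radiiUm = c(25, 50),
                             outDir = NULL, ...) {
  if (is(specs, "PhantomSpec")) specs <- list(specs)
  n <- length(specs)
  if (n == 0L) {
    empty <- data.frame()
    return(list(cohort = empty, sections = empty, stats = empty))
  }
  routes <- rep_len(routes, n)
  allSections <- list(); cohort <- list()
  for (i in seq_len(n)) {
    id <- sprintf("brain%02d", i)
    ph <- generatePhantom(specs[[i]], radiiUm = radiiUm)
    an <- analyzePhantom(ph, specs[[i]], radiiUm = radiiUm,
                         route = routes[i], brainId = id, ...)
    an$sections$brain_id <- id
    allSections[[i]] <- an$sections
    cohort[[i]] <- an$brain
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(an$sections,
                       file.path(outDir, paste0("sections_", id, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(as.list(an$brain),
                           file.path(outDir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  cohort <- do.call(rbind, cohort)
  sections <- do.call(rbind, allSections)
  stats <- cohortStats(cohort, radiiUm = radiiUm)
  if (!is.null(outDir)) {
    utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(outDir, "stats.csv"),
                     row.names = FALSE)
  }
  list(cohort = cohort, sections = sections, stats = stats)
}

#' Cohort summary statistics table
#'
#' The figure-level analyses of the study, computed on a cohort table:
#' OLS r^2 against the administered dose (a predetermined variable) for
#' the NSC total, the percent at tumor and the whole-tumor coverage; and
#' Spearman correlations between not-predetermined pairs (coverage vs NSC
#' total, coverage vs volume, density vs volume). Raw p-values, no
#' multiple-testing correction.
#'
#' @param cohort cohort data.frame from [runPhantomCohort()] /
#'   [analyzeBrain()].
#' @param radiiUm radii whose coverage column is analyzed (the largest is
#'   used, matching the study's 50 um focus).
#' @return data.frame with one row per analysis: `analysis`, `method`,
#'   `statistic`, `p_value`, `n`.
#' @export
cohortStats <- function(cohort, radiiUm = c(25, 50)) {
  covCol <- paste0("cov_", max(radiiUm), "um")
  rows <- list()
  addRow <- function(label, res) {
    res$analysis <- label
    rows[[length(rows) + 1L]] <<- res[, c("analysis", "method", "statistic",
                                          "p_value", "n")]
  }
  tryRow <- function(label, f) tryCatch(addRow(label, f()),
                                        error = function(e) invisible(NULL))
  tryRow("total_nsc_vs_dose", function()
    linearRegressionR2(cohort$administered_nsc, cohort$total_nsc_count))
  tryRow("pct_at_tumor_vs_dose", function()
    linearRegressionR2(cohort$administered_nsc, cohort$pct_at_tumor))
  tryRow("coverage_vs_dose", function()
    linearRegressionR2(cohort$administered_nsc, cohort[[covCol]]))
  tryRow("coverage_vs_total_nsc", function()
    spearmanR(cohort$total_nsc_count, cohort[[covCol]]))
  tryRow("coverage_vs_volume", function()
    spearmanR(cohort$tumor_volume_mm3, cohort[[covCol]]))
  tryRow("density_vs_volume", function()
    spearmanR(cohort$tumor_volume_mm3, cohort$nsc_density_per_mm3))
  if (!length(rows))
    return(data.frame(analysis = character(0), method = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      n = integer(0)))
  do.call(rbind, rows)
}

#' Run the pipeline from a configuration
#'
#' Thin configuration-driven front end. The config (a list, or a path to
#' a YAML/JSON file) selects one of two modes:
#'
#' * `mode: "phantom"` — fields `n_brains`, `administered` (dose per
#'   brain), `retention` (retained fraction), `seed`, optional `radii_um`,
#'   `out_dir`, and any `phantom` sub-list of [phantomSpec()] overrides.
#'   Brain i uses seed `seed + i`.
#' * `mode: "images"` — field `pairs`: a list of records with `nsc` and
#'   `tumor` image paths, `depth_um` and optional `slide_id`; plus
#'   `pixel_size_um`, optional `radii_um`, `administered`, `route`,
#'   `out_dir`, and scheme overrides `section_thickness_um` /
#'   `analysis_spacing_um`. A pair missing one member, or images with
#'   mismatched calibration, is an error.
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return as [runPhantomCohort()] (phantom mode) or a list with
#'   `sections` and `brain` (image mode).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  mode <- config$mode %||% "phantom"
  radii <- config$radii_um %||% c(25, 50)
  if (mode == "phantom") {
    nb <- config$n_brains %||% length(config$administered)
    if (!nb) stop("phantom mode needs 'n_brains' or 'administered'")
    doses <- rep_len(config$administered %||% 20000, nb)
    retention <- config$retention %||% 0.5
    seed0 <- config$seed %||% 1L
    overrides <- config$phantom %||% list()
    specs <- lapply(seq_len(nb), function(i) {
      args <- overrides
      args$administeredNsc <- as.integer(doses[i])
      args$nNscTotal <- as.integer(round(doses[i] * retention))
      args$seed <- as.integer(seed0 + i)
      do.call(phantomSpec, args)
    })
    runPhantomCohort(specs, routes = config$route %||% "ic",
                     radiiUm = radii, outDir = config$out_dir)
  } else if (mode == "images") {
    pairs <- config$pairs
    if (is.null(pairs) || !length(pairs)) stop("image mode needs 'pairs'")
    ps <- config$pixel_size_um %||% 1
    res <- lapply(seq_along(pairs), function(i) {
      p <- pairs[[i]]
      if (is.null(p$nsc) || is.null(p$tumor))
        stop("pair ", i, " is missing its nsc or tumor member")
      id <- p$slide_id %||% sprintf("pair%02d", i)
      nscImg <- readSectionImage(p$nsc, pixelSizeUm = ps,
                                 depthUm = p$depth_um %||% 0,
                                 slideId = id,
                                 stainKind = "nsc_prussian_blue")
      tumImg <- readSectionImage(p$tumor, pixelSizeUm = ps,
                                 depthUm = p$depth_um %||% 0,
                                 slideId = id, stainKind = "tumor_dab")
      analyzeSectionPair(nscImg, tumImg, radiiUm = radii)$summary
    })
    sections <- do.call(rbind, res)
    scheme <- samplingScheme(config$section_thickness_um %||% 10,
                             config$analysis_spacing_um %||% 200)
    brain <- analyzeBrain(sections, scheme,
                          administeredCount = config$administered %||% NA,
                          route = config$route %||% NA_character_,
                          brainId = config$brain_id %||% "brain")
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sections, file.path(config$out_dir, "sections.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(brain),
                           file.path(config$out_dir, "brain.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(sections = sections, brain = brain)
  } else stop("unknown mode: ", mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
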