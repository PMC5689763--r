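# Seeded synthetic-histology phantoms with exact ground truth.
#
# A phantom brain is a 3-D tumor blob (ellipsoid with a low-order angular
# modulation of its margin), an NSC point pattern mixing uniform interior
# points, Thomas-process clusters and edge-rim points, and a Beer-Lambert
# two-stain rendering of each sampled depth: one Prussian blue /
# pararosaniline slide for the NSCs and one DAB / hematoxylin slide for
# the tumor, aligned, with Gaussian scanner noise. Every quantity the
# pipeline later estimates is also computed exactly from the generating
# objects, so recovery can be tested without real data.

#' Construct a phantom specification
#'
#' Returns a [PhantomSpec-class] with the package's default study
#' conditions: 512 x 512 px sections at 1 um/px, 12 analyzed depths 200 um
#' apart (10 um sections), an irregular ellipsoidal tumor of semi-axes
#' 200 x 160 x 900 um, and 10 000 retained NSCs out of 20 000
#' administered, placed as 40% Thomas-process clusters (mean 8 offspring,
#' 25 um spread), 20% edge-rim points within 40 um of the margin, and 40%
#' uniform interior points.
#'
#' @param ... named values overriding any [PhantomSpec-class] slot.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nSections = 4L, imageSizePx = c(128L, 128L),
#'                     tumorSemiAxesUm = c(50, 40, 300),
#'                     tumorCenterUm = c(63.5, 63.5, 300),
#'                     nNscTotal = 200L, administeredNsc = 400L)
#' @export
phantomSpec <- function(...) {
  defaults <- list(
    imageSizePx = c(512L, 512L),
    pixelSizeUm = 1,
    nSections = 12L,
    spacingUm = 200,
    sectionThicknessUm = 10,
    tumorCenterUm = c(255.5, 255.5, 1100),
    tumorSemiAxesUm = c(200, 160, 900),
    irregularityAmplitude = 0.08,
    irregularityModes = 2:5,
    nNscTotal = 10000L,
    administeredNsc = 20000L,
    clusterFraction = 0.4,
    clustersMeanOffspring = 8,
    clusterSdUm = 25,
    edgeBias = 0.2,
    rimWidthUm = 40,
    cellRadiusUm = 4.5,
    nscStains = stainPresets("prussian_pararosaniline"),
    tumorStains = stainPresets("h_dab"),
    nscConcentration = 1,
    tumorConcentration = 1,
    counterstainConcentration = 0.25,
    backgroundIntensity = 255,
    noiseSd = 2,
    seed = 1L
  )
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown phantom parameters: ",
                        paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  ints <- c("imageSizePx", "nSections", "nNscTotal", "administeredNsc",
            "irregularityModes", "seed")
  for (f in ints) defaults[[f]] <- as.integer(defaults[[f]])
  do.call(new, c(list(Class = "PhantomSpec"), defaults))
}

# --- tumor geometry -------------------------------------------------------

#' Draw the tumor margin geometry of a phantom
#'
#' Draws the angular margin modulation from the current RNG stream: a sum
#' of the spec's Fourier modes with Gaussian coefficients, rescaled to
#' unit sup-norm so that `irregularityAmplitude` is the exact maximal
#' relative radius modulation. Amplitude 0 gives an exact ellipsoid. The
#' analytic tumor volume follows by quadrature over the angle.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with the center, semi-axes, modes, coefficients and the
#'   analytic volume in mm^3 (`volumeMm3`); pass it to
#'   [tumorSectionMask()] and [placeNSCs()].
#' @export
tumorGeometry <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  modes <- spec@irregularityModes
  nm <- length(modes)
  if (spec@irregularityAmplitude > 0 && nm > 0) {
    ca <- stats::rnorm(nm); cb <- stats::rnorm(nm)
    thg <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    g <- .fourierEval(thg, modes, ca, cb)
    supg <- max(abs(g))
    if (supg > 0) { ca <- ca / supg; cb <- cb / supg }
    r3 <- mean((1 + spec@irregularityAmplitude *
                  .fourierEval(thg, modes, ca, cb))^3)
  } else {
    ca <- numeric(0); cb <- numeric(0); modes <- integer(0)
    r3 <- 1
  }
  ax <- spec@tumorSemiAxesUm
  list(center = spec@tumorCenterUm, semiAxes = ax,
       amplitude = spec@irregularityAmplitude,
       modes = modes, coefA = ca, coefB = cb,
       volumeMm3 = (4 / 3) * pi * prod(ax) * r3 / 1e9)
}

.fourierEval <- function(theta, modes, ca, cb) {
  g <- numeric(length(theta))
  for (i in seq_along(modes))
    g <- g + ca[i] * cos(modes[i] * theta) + cb[i] * sin(modes[i] * theta)
  g
}

# boundary radius multiplier R(theta) = 1 + amp * g(theta)
.marginR <- function(geom, theta) {
  if (!length(geom$modes)) return(rep(1, length(theta)))
  1 + geom$amplitude * .fourierEval(theta, geom$modes, geom$coefA, geom$coefB)
}

# normalized coordinates and inside test for points (um)
.insideTumor <- function(x, y, z, geom) {
  u <- (x - geom$center[1]) / geom$semiAxes[1]
  v <- (y - geom$center[2]) / geom$semiAxes[2]
  w <- (z - geom$center[3]) / geom$semiAxes[3]
  th <- atan2(v, u)
  sqrt(u^2 + v^2 + w^2) <= .marginR(geom, th)
}

#' Rasterize the tumor cross-section at one depth
#'
#' @param geom geometry from [tumorGeometry()].
#' @param depthUm section depth in um.
#' @param spec the [PhantomSpec-class] (field size and pixel size).
#' @return a tumor [BinaryMask-class] (empty when the section misses the
#'   tumor).
#' @export
tumorSectionMask <- function(geom, depthUm, spec) {
  H <- spec@imageSizePx[1]; W <- spec@imageSizePx[2]
  ps <- spec@pixelSizeUm
  x <- (seq_len(W) - 1) * ps   # pixel-center x per column
  y <- (seq_len(H) - 1) * ps
  u <- (x - geom$center[1]) / geom$semiAxes[1]
  v <- (y - geom$center[2]) / geom$semiAxes[2]
  w0 <- (depthUm - geom$center[3]) / geom$semiAxes[3]
  um <- matrix(u, H, W, byrow = TRUE)
  vm <- matrix(v, H, W)
  th <- atan2(vm, um)
  inside <- um^2 + vm^2 + w0^2 <= .marginR(geom, th)^2
  binaryMask(matrix(inside, H, W), pixelSizeUm = ps, label = "tumor")
}

# --- NSC placement --------------------------------------------------------

# batch rejection sampler of uniform points inside the tumor body
.uniformInTumor <- function(n, geom) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  lim <- 1 + geom$amplitude
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- max(64L, 3L * (n - nrow(out)))
    x <- geom$center[1] + (stats::runif(m, -1, 1) * lim) * geom$semiAxes[1]
    y <- geom$center[2] + (stats::runif(m, -1, 1) * lim) * geom$semiAxes[2]
    z <- geom$center[3] + (stats::runif(m, -1, 1) * lim) * geom$semiAxes[3]
    ok <- .insideTumor(x, y, z, geom)
    out <- rbind(out, cbind(x, y, z)[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# in-plane radial distance (um) from a point to the tumor margin at its own
# depth; large when the point sits on the vertical axis (direction undefined)
.edgeDistance <- function(pts, geom) {
  u <- (pts[, 1] - geom$center[1]) / geom$semiAxes[1]
  v <- (pts[, 2] - geom$center[2]) / geom$semiAxes[2]
  w <- (pts[, 3] - geom$center[3]) / geom$semiAxes[3]
  th <- atan2(v, u)
  sb2 <- .marginR(geom, th)^2 - w^2
  sb <- sqrt(pmax(0, sb2))
  sp <- sqrt(u^2 + v^2)
  physPerS <- sqrt((geom$semiAxes[1] * u)^2 + (geom$semiAxes[2] * v)^2)
  d <- ifelse(sp > 1e-12, (sb - sp) * physPerS / sp, Inf)
  pmax(0, d)
}

#' Place the NSC point pattern of a phantom
#'
#' Places exactly `nNscTotal` points inside the tumor as a mixture of
#' three components, in the spec's proportions: uniform interior points;
#' Thomas-process clusters (parents uniform in the tumor, offspring
#' isotropic Gaussian with sd `clusterSdUm`, re-drawn until inside); and
#' edge-rim points, uniform points conditioned to lie within `rimWidthUm`
#' of the tumor margin in their own section plane. Draws from the current
#' RNG stream.
#'
#' @param spec a [PhantomSpec-class].
#' @param geom geometry from [tumorGeometry()]; drawn from `spec` if
#'   missing.
#' @return data.frame with `x_um`, `y_um`, `z_um` and `component`
#'   (`"uniform"`, `"cluster"`, `"edge"`).
#' @export
placeNSCs <- function(spec, geom = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  if (is.null(geom)) geom <- tumorGeometry(spec)
  n <- spec@nNscTotal
  if (n == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), component = character(0)))
  nC <- round(spec@clusterFraction * n)
  nE <- round(spec@edgeBias * n)
  nU <- n - nC - nE
  if (nU < 0) stop("impossible proportions: clusterFraction + edgeBias > 1")
  pts <- list()
  if (nU > 0)
    pts$uniform <- .uniformInTumor(nU, geom)
  if (nC > 0) {
    nPar <- max(1L, round(nC / spec@clustersMeanOffspring))
    parents <- .uniformInTumor(nPar, geom)
    assign <- sample.int(nPar, nC, replace = TRUE)
    off <- parents[assign, , drop = FALSE] +
      matrix(stats::rnorm(3 * nC, sd = spec@clusterSdUm), nC, 3)
    for (it in 1:100) {
      bad <- which(!.insideTumor(off[, 1], off[, 2], off[, 3], geom))
      if (!length(bad)) break
      off[bad, ] <- parents[assign[bad], , drop = FALSE] +
        matrix(stats::rnorm(3 * length(bad), sd = spec@clusterSdUm),
               length(bad), 3)
    }
    if (length(bad <- which(!.insideTumor(off[, 1], off[, 2], off[, 3],
                                          geom))))
      off[bad, ] <- parents[assign[bad], , drop = FALSE]
    pts$cluster <- off
  }
  if (nE > 0) {
    rim <- matrix(numeric(0), 0, 3)
    while (nrow(rim) < nE) {
      cand <- .uniformInTumor(max(64L, 2L * (nE - nrow(rim))), geom)
      ok <- .edgeDistance(cand, geom) <= spec@rimWidthUm
      rim <- rbind(rim, cand[ok, , drop = FALSE])
    }
    pts$edge <- rim[seq_len(nE), , drop = FALSE]
  }
  comp <- rep(names(pts), vapply(pts, nrow, 1L))
  m <- do.call(rbind, pts)
  data.frame(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3], component = comp)
}

# --- rendering ------------------------------------------------------------

# rasterize cells as disks of cellRadiusUm around their in-plane centroids
.cellMask <- function(cells, spec) {
  H <- spec@imageSizePx[1]; W <- spec@imageSizePx[2]
  ps <- spec@pixelSizeUm
  if (!nrow(cells)) return(matrix(FALSE, H, W))
  .disk_union(cells$y_um / ps, cells$x_um / ps, H, W,
              spec@cellRadiusUm / ps)
}

.renderOne <- function(targetConc, counterConc, stains, spec, depthUm,
                       slideId, stainKind, noise = spec@noiseSd) {
  m <- stainMatrix(stains)        # column 1 counterstain, column 2 target
  H <- nrow(targetConc); W <- ncol(targetConc)
  od <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    od[, , ch] <- counterConc * m[ch, 1] + targetConc * m[ch, 2]
  px <- spec@backgroundIntensity * 10^(-od)
  if (noise > 0)
    px <- px + stats::rnorm(length(px), sd = noise)
  px[px < 0] <- 0; px[px > 255] <- 255
  sectionImage(px, pixelSizeUm = spec@pixelSizeUm, depthUm = depthUm,
               slideId = slideId, stainKind = stainKind)
}

#' Render one aligned two-stain section pair
#'
#' Forward Beer-Lambert model of the deconvolution algorithm: per pixel,
#' OD is concentration times stain vector summed over stains (target
#' chromagen on objects, counterstain over the whole field), intensities
#' are `background * 10^-OD` plus Gaussian noise, clipped to [0, 255] and
#' left unquantized.
#'
#' @param tumorMask tumor [BinaryMask-class] for the depth.
#' @param nscCells data.frame of NSC centroids lying in this section's
#'   slab (columns `x_um`, `y_um`).
#' @param spec a [PhantomSpec-class].
#' @param depthUm section depth, um.
#' @param slideId identifier stem for the pair.
#' @return list with `nsc` and `tumor` [SectionImage-class] objects.
#' @export
renderSection <- function(tumorMask, nscCells, spec, depthUm = 0,
                          slideId = "phantom") {
  stopifnot(is(tumorMask, "BinaryMask"))
  nscM <- .cellMask(nscCells, spec)
  list(
    nsc = .renderOne(spec@nscConcentration * nscM,
                     spec@counterstainConcentration, spec@nscStains, spec,
                     depthUm, paste0(slideId, "_nsc"), "nsc_prussian_blue"),
    tumor = .renderOne(spec@tumorConcentration * maskArray(tumorMask),
                       spec@counterstainConcentration, spec@tumorStains,
                       spec, depthUm, paste0(slideId, "_tumor"), "tumor_dab")
  )
}

# --- full phantom ---------------------------------------------------------

#' Generate a seeded phantom brain with complete ground truth
#'
#' Deterministic given `spec@seed`: draws the tumor geometry, places the
#' NSC pattern, and for each analyzed depth rasterizes the true masks,
#' renders the aligned two-stain image pair and computes the true
#' per-section coverage per radius by the independent disk-union oracle.
#'
#' @param spec a [PhantomSpec-class].
#' @param radiiUm radii of action for the truth coverage, um.
#' @param render if `FALSE`, skip image rendering (masks and truth only).
#' @return list with `sections` (per depth: `depthUm`, `nsc`/`tumor`
#'   [SectionImage-class]s when rendered) and `truth`, a list holding the
#'   per-section true masks, NSC centroids with section assignment,
#'   per-section and whole-tumor coverage per radius, per-section areas
#'   and slab cell counts, analytic and voxelized tumor volume (mm^3),
#'   administered count and retained fraction, and the drawn geometry.
#' @examples
#' spec <- phantomSpec(imageSizePx = c(96L, 96L), nSections = 3L,
#'                     spacingUm = 100, tumorCenterUm = c(47.5, 47.5, 100),
#'                     tumorSemiAxesUm = c(35, 30, 120), nNscTotal = 60L,
#'                     administeredNsc = 120L, seed = 7L)
#' ph <- generatePhantom(spec, radiiUm = 25)
#' ph$truth$perSectionCoverage
#' @export
generatePhantom <- function(spec, radiiUm = c(25, 50), render = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  geom <- tumorGeometry(spec)
  ps <- spec@pixelSizeUm
  fieldUm <- (spec@imageSizePx - 1L) * ps
  lim <- 1 + geom$amplitude
  reachX <- geom$semiAxes[1] * lim
  reachY <- geom$semiAxes[2] * lim
  if (geom$center[1] - reachX < 0 || geom$center[1] + reachX > fieldUm[2] ||
      geom$center[2] - reachY < 0 || geom$center[2] + reachY > fieldUm[1])
    stop("tumor larger than field: widen imageSizePx or shrink the tumor")

  cells <- placeNSCs(spec, geom)
  depths <- (seq_len(spec@nSections) - 1L) * spec@spacingUm
  half <- spec@sectionThicknessUm / 2
  section <- rep(NA_integer_, nrow(cells))
  for (k in seq_along(depths)) {
    inSlab <- cells$z_um > depths[k] - half & cells$z_um <= depths[k] + half
    section[inSlab] <- k
  }
  cells$section <- section

  nr <- length(radiiUm)
  cov <- matrix(0, spec@nSections, nr,
                dimnames = list(NULL, paste0("cov_", radiiUm, "um")))
  areas <- numeric(spec@nSections)
  nPerSection <- integer(spec@nSections)
  masks <- vector("list", spec@nSections)
  sections <- vector("list", spec@nSections)
  for (k in seq_along(depths)) {
    tum <- tumorSectionMask(geom, depths[k], spec)
    slab <- cells[!is.na(cells$section) & cells$section == k, , drop = FALSE]
    nscM <- .cellMask(slab, spec)
    masks[[k]] <- list(
      nsc = binaryMask(nscM, ps, "nsc"),
      tumor = tum
    )
    areas[k] <- tumorArea(tum)
    nPerSection[k] <- nrow(slab)
    ntum <- sum(maskArray(tum))
    if (ntum > 0 && any(nscM)) {
      idx <- which(nscM, arr.ind = TRUE)
      for (j in seq_len(nr)) {
        covered <- .disk_union(as.numeric(idx[, 1] - 1L),
                               as.numeric(idx[, 2] - 1L),
                               nrow(nscM), ncol(nscM), radiiUm[j] / ps)
        cov[k, j] <- 100 * sum(covered & maskArray(tum)) / ntum
      }
    }
    sections[[k]] <- c(
      list(depthUm = depths[k]),
      if (render) renderSection(tum, slab, spec, depths[k],
                                sprintf("phantom_s%02d", k))
    )
  }

  withTumor <- areas > 0
  whole <- if (any(withTumor))
    wholeTumorCoverage(cov[withTumor, , drop = FALSE], areas[withTumor])
  else stats::setNames(rep(NA_real_, nr), colnames(cov))

  truth <- list(
    geometry = geom,
    sectionDepthsUm = depths,
    sectionMasks = masks,
    nscCentroids = cells,
    nscPerSection = nPerSection,
    tumorAreasUm2 = areas,
    perSectionCoverage = cov,
    wholeTumorCoverage = whole,
    volumeAnalyticMm3 = geom$volumeMm3,
    volumeVoxelizedMm3 = .voxelizedVolume(geom, spec),
    totalPlaced = nrow(cells),
    administeredCount = spec@administeredNsc,
    retainedFraction = if (spec@administeredNsc > 0)
      spec@nNscTotal / spec@administeredNsc else NA_real_
  )
  list(sections = sections, truth = truth)
}

#' Coverage along a dose ladder at fixed geometry
#'
#' Evaluates whole-tumor coverage for increasing NSC doses while holding
#' the tumor geometry and the point-pattern realization fixed: the full
#' pattern is drawn once, randomly permuted, and each dose keeps a nested
#' prefix of it (coupled sampling). Because the retained sets are nested,
#' the coverage mask can only grow with dose, isolating the dose effect
#' from sampling noise.
#'
#' @param spec a [PhantomSpec-class]; `nNscTotal` is the top dose.
#' @param doseFractions increasing fractions of `nNscTotal` to evaluate.
#' @param radiusUm radius of action, um.
#' @return data.frame with `fraction`, `n_nsc` and `coverage_pct`
#'   (area-weighted whole-tumor coverage from the true masks).
#' @export
doseLadderCoverage <- function(spec, doseFractions = c(0.125, 0.25, 0.5, 1),
                               radiusUm = 50) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  geom <- tumorGeometry(spec)
  cells <- placeNSCs(spec, geom)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  depths <- (seq_len(spec@nSections) - 1L) * spec@spacingUm
  half <- spec@sectionThicknessUm / 2
  tumorMasks <- lapply(depths, tumorSectionMask, geom = geom, spec = spec)
  areas <- vapply(tumorMasks, tumorArea, numeric(1))
  wt <- areas > 0
  out <- lapply(sort(doseFractions), function(f) {
    n <- round(f * nrow(cells))
    sub <- cells[seq_len(n), , drop = FALSE]
    cov <- vapply(seq_along(depths), function(k) {
      if (!wt[k]) return(NA_real_)
      slab <- sub[sub$z_um > depths[k] - half & sub$z_um <= depths[k] + half,
                  , drop = FALSE]
      nscM <- binaryMask(.cellMask(slab, spec), spec@pixelSizeUm, "nsc")
      unname(coverageFraction(nscM, tumorMasks[[k]], radiusUm))
    }, numeric(1))
    data.frame(fraction = f, n_nsc = n,
               coverage_pct = stats::weighted.mean(cov[wt], areas[wt]))
  })
  do.call(rbind, out)
}

# fine-depth voxelization of the tumor (planes every ~spacing/10)
.voxelizedVolume <- function(geom, spec) {
  dz <- max(spec@sectionThicknessUm, spec@spacingUm / 10)
  zr <- geom$center[3] + c(-1, 1) * geom$semiAxes[3] * (1 + geom$amplitude)
  z <- seq(zr[1] + dz / 2, zr[2], by = dz)
  a <- vapply(z, function(zi)
    tumorArea(tumorSectionMask(geom, zi, spec)), numeric(1))
  .um3ToMm3(sum(a) * dz)
}
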