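# The synthetic-histology generator: determinism, point-pattern
# properties, rendering round trips and truth self-consistency.

test_that("the same seed reproduces the phantom byte for byte", {
  spec <- smallSpec(nNscTotal = 100L, administeredNsc = 200L)
  a <- generatePhantom(spec, radiiUm = 25)
  b <- generatePhantom(spec, radiiUm = 25)
  expect_identical(lapply(a$sections, function(s) imagePixels(s$nsc)),
                   lapply(b$sections, function(s) imagePixels(s$nsc)))
  expect_identical(a$truth$nscCentroids, b$truth$nscCentroids)
  expect_identical(a$truth$perSectionCoverage, b$truth$perSectionCoverage)
  # a different seed gives a different realization
  c <- generatePhantom(smallSpec(nNscTotal = 100L, administeredNsc = 200L,
                                 seed = 12L), radiiUm = 25)
  expect_false(identical(a$truth$nscCentroids, c$truth$nscCentroids))
})

test_that("a phantom with no NSCs renders counterstain only", {
  spec <- smallSpec(nNscTotal = 0L, administeredNsc = 0L, noiseSd = 0)
  ph <- generatePhantom(spec, radiiUm = c(25, 50))
  expect_true(all(ph$truth$perSectionCoverage == 0))
  px <- imagePixels(ph$sections[[2]]$nsc)
  # uniform counterstain background: every pixel identical per channel
  for (ch in 1:3) expect_equal(max(px[, , ch]) - min(px[, , ch]), 0)
})

test_that("placement returns exactly n points, all inside the tumor", {
  spec <- smallSpec(nNscTotal = 500L, administeredNsc = 1000L)
  set.seed(3)
  geom <- tumorGeometry(spec)
  pts <- placeNSCs(spec, geom)
  expect_equal(nrow(pts), 500)
  expect_true(all(nscoverage:::.insideTumor(pts$x_um, pts$y_um, pts$z_um,
                                            geom)))
  expect_equal(as.numeric(table(pts$component)[c("uniform", "cluster",
                                                 "edge")]),
               c(200, 200, 100))
})

test_that("impossible mixture proportions are rejected", {
  expect_error(phantomSpec(clusterFraction = 0.8, edgeBias = 0.4),
               "sum to at most 1")
  expect_error(generatePhantom(smallSpec(tumorSemiAxesUm = c(200, 38, 160))),
               "larger than field")
})

test_that("pure uniform placement is consistent with spatial randomness", {
  spec <- smallSpec(clusterFraction = 0, edgeBias = 0, nNscTotal = 400L,
                    administeredNsc = 800L, irregularityAmplitude = 0)
  set.seed(41)
  geom <- tumorGeometry(spec)
  pts <- placeNSCs(spec, geom)
  nn <- function(m) {
    d <- as.matrix(stats::dist(m)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  obs <- nn(cbind(pts$x_um, pts$y_um, pts$z_um))
  # Monte-Carlo envelope from direct rejection-sampled CSR in the same
  # ellipsoid (independent of the generator's sampler)
  sims <- vapply(1:20, function(i) {
    got <- matrix(numeric(0), 0, 3)
    while (nrow(got) < 400) {
      cand <- cbind(runif(2000, -1, 1), runif(2000, -1, 1),
                    runif(2000, -1, 1))
      keep <- rowSums(cand^2) <= 1
      got <- rbind(got, cand[keep, , drop = FALSE])
    }
    got <- got[1:400, ]
    got <- sweep(got, 2, spec@tumorSemiAxesUm, "*")
    nn(sweep(got, 2, spec@tumorCenterUm, "+"))
  }, numeric(1))
  expect_gte(obs, min(sims) * 0.9)
  expect_lte(obs, max(sims) * 1.1)
  # Clark-Evans style index against the CSR expectation is near 1
  expect_equal(obs / mean(sims), 1, tolerance = 0.15)
})

test_that("tight clusters drive the per-section CI toward its maximum", {
  spec <- smallSpec(clusterFraction = 1, edgeBias = 0, clusterSdUm = 4,
                    clustersMeanOffspring = 10, nNscTotal = 300L,
                    administeredNsc = 600L, seed = 19L)
  ph <- generatePhantom(spec, radiiUm = 25, render = FALSE)
  k <- which.max(ph$truth$nscPerSection)
  cells <- subset(ph$truth$nscCentroids, !is.na(section) & section == k)
  res <- clusterPoints(data.frame(x_um = cells$x_um, y_um = cells$y_um), 50)
  n <- nrow(cells)
  expect_gte(n, 10)
  expect_gte(res$ci, 0.75 * (1 - 1 / n))
})

test_that("truth coverage agrees between disk-union and distance transform", {
  spec <- smallSpec(nNscTotal = 150L, administeredNsc = 300L)
  ph <- generatePhantom(spec, radiiUm = c(25, 50), render = FALSE)
  for (k in seq_along(ph$truth$sectionMasks)) {
    m <- ph$truth$sectionMasks[[k]]
    if (tumorArea(m$tumor) == 0) next
    expect_equal(unname(coverageFraction(m$nsc, m$tumor, c(25, 50))),
                 unname(ph$truth$perSectionCoverage[k, ]))
  }
})

test_that("noise-free rendering deconvolves to the exact concentrations", {
  spec <- smallSpec(noiseSd = 0, nNscTotal = 120L, administeredNsc = 240L)
  ph <- generatePhantom(spec, radiiUm = 25)
  s <- ph$sections[[2]]
  truthMasks <- ph$truth$sectionMasks[[2]]
  ch <- deconvolveStains(rgbToOD(s$nsc, spec@backgroundIntensity),
                         spec@nscStains)
  # channel 2 is the Prussian blue target; exact cell concentration
  target <- spec@nscConcentration * maskArray(truthMasks$nsc)
  expect_lt(max(abs(ch[, , 2] - target)), 1e-9)
  expect_lt(max(abs(ch[, , 1] - spec@counterstainConcentration)), 1e-9)
  # segmentation reproduces the ground-truth masks pixel for pixel
  got <- maskArray(segmentStain(ch[, , 2], 0.3, pixelSizeUm = 1,
                                label = "nsc"))
  expect_identical(got, maskArray(truthMasks$nsc))
  chT <- deconvolveStains(rgbToOD(s$tumor, spec@backgroundIntensity),
                          spec@tumorStains)
  gotT <- maskArray(segmentStain(chT[, , 2], 0.3, pixelSizeUm = 1,
                                 label = "tumor"))
  expect_identical(gotT, maskArray(truthMasks$tumor))
})

test_that("noisy rendering recovers concentrations within the propagated bound", {
  noiseSd <- 2
  spec <- smallSpec(noiseSd = noiseSd, nNscTotal = 120L,
                    administeredNsc = 240L, seed = 8L)
  ph <- generatePhantom(spec, radiiUm = 25)
  s <- ph$sections[[2]]
  truthMasks <- ph$truth$sectionMasks[[2]]
  ch <- deconvolveStains(rgbToOD(s$nsc, spec@backgroundIntensity),
                         spec@nscStains)
  target <- spec@nscConcentration * maskArray(truthMasks$nsc)
  # intensity noise propagates through d(OD)/dI = 1/(I ln 10) and the
  # unmixing inverse; bound each pixel by 3 sigma of that linearization
  m <- stainMatrix(completeStainBasis(spec@nscStains))
  minv <- solve(m)
  px <- pmax(imagePixels(s$nsc), 1)
  odSd <- noiseSd / (px * log(10))
  chSd <- sqrt(odSd[, , 1]^2 * minv[2, 1]^2 +
               odSd[, , 2]^2 * minv[2, 2]^2 +
               odSd[, , 3]^2 * minv[2, 3]^2)
  frac <- mean(abs(ch[, , 2] - target) <= 3 * chSd + 1e-6)
  expect_gte(frac, 0.99)
})

test_that("voxelized and analytic tumor volumes agree", {
  spec <- smallSpec()
  ph <- generatePhantom(spec, radiiUm = 25, render = FALSE)
  expect_equal(ph$truth$volumeVoxelizedMm3, ph$truth$volumeAnalyticMm3,
               tolerance = 0.05)
  expect_equal(ph$truth$retainedFraction, 0.5)
})

test_that("coverage grows with dose under coupled sampling", {
  spec <- smallSpec(nNscTotal = 400L, administeredNsc = 800L)
  lad <- doseLadderCoverage(spec, c(0.125, 0.25, 0.5, 1), radiusUm = 50)
  expect_true(all(diff(lad$coverage_pct) >= 0))
  expect_gt(lad$coverage_pct[4], lad$coverage_pct[1])
})
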