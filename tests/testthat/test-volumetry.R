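# Cavalieri volumes, count extrapolation, aggregates and densities.

test_that("the sampling scheme validates its invariant", {
  s <- samplingScheme()
  expect_equal(s@analysisSpacingUm / s@sectionThicknessUm, 20)
  expect_error(samplingScheme(10, 150.5), "multiple")
  expect_error(samplingScheme(-1, 200), "positive")
})

test_that("Cavalieri volume integrates area times spacing", {
  expect_equal(cavalieriVolume(rep(2e6, 5)), 2)      # 5 x 2 mm^2 prisms
  expect_equal(cavalieriVolume(rep(0, 7)), 0)
  expect_equal(cavalieriVolume(numeric(0)), 0)
  expect_error(cavalieriVolume(c(1, -1)), "non-negative")

  # linear in areas and in spacing
  a <- c(1e5, 3e5, 2e5)
  expect_equal(cavalieriVolume(2 * a), 2 * cavalieriVolume(a))
  expect_equal(cavalieriVolume(a, samplingScheme(10, 400)),
               2 * cavalieriVolume(a, samplingScheme(10, 200)))
})

test_that("an ellipsoid sampled every 200 um recovers its analytic volume", {
  # semi-axes 1.5, 1.0, 0.8 mm; cross-section pi*a*b*(1 - z^2/c^2)
  a <- 1500; b <- 1000; cc <- 800
  z <- seq(-cc, cc, by = 200)
  areas <- pi * a * b * pmax(0, 1 - (z / cc)^2)
  vol <- cavalieriVolume(areas)
  truth <- 4 / 3 * pi * a * b * cc / 1e9
  expect_equal(vol, truth, tolerance = 0.05)

  # refining the grid brings the estimate closer than the 200 um error
  z100 <- seq(-cc, cc, by = 100)
  areas100 <- pi * a * b * pmax(0, 1 - (z100 / cc)^2)
  vol100 <- cavalieriVolume(areas100, samplingScheme(10, 100))
  expect_lt(abs(vol100 - truth), abs(vol - truth) + 1e-12)
})

test_that("counts extrapolate by spacing over thickness and sum", {
  expect_equal(extrapolateCounts(c(10, 20)), 600)
  expect_equal(extrapolateCounts(numeric(0)), 0)
  expect_equal(extrapolateCounts(5, samplingScheme(10, 100)), 50)
  expect_error(extrapolateCounts(-1), "non-negative")
})

test_that("seeded phantom cells are recovered by slab extrapolation", {
  # average over three seeds to damp slab-sampling noise
  errs <- vapply(1:3, function(sd) {
    spec <- smallSpec(nNscTotal = 2000L, administeredNsc = 4000L,
                      seed = sd)
    ph <- generatePhantom(spec, radiiUm = 25, render = FALSE)
    scheme <- samplingScheme(spec@sectionThicknessUm, spec@spacingUm)
    est <- extrapolateCounts(ph$truth$nscPerSection, scheme)
    (est - ph$truth$totalPlaced) / ph$truth$totalPlaced
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.15)
})

test_that("whole-tumor coverage is the area-weighted mean", {
  expect_equal(wholeTumorCoverage(c(30, 30, 30), c(1, 5, 2)), 30)
  expect_equal(wholeTumorCoverage(c(100, 0), c(1, 1)), 50)
  m <- cbind(cov_25um = c(10, 30), cov_50um = c(20, 60))
  expect_equal(unname(wholeTumorCoverage(m, c(3, 1))),
               c(15, 30))
  expect_error(wholeTumorCoverage(c(10, 20), c(0, 0)), "zero total")
  expect_error(wholeTumorCoverage(c(10, 20), c(1, 1, 1)), "match")
})

test_that("density divides count by volume with a plausibility note", {
  expect_equal(nscDensity(600, 0.02), 30000)
  expect_equal(nscDensity(0, 1), 0)
  expect_error(nscDensity(10, 0), "undefined")
  expect_message(nscDensity(5, 1), "outside")
})
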