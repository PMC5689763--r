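# Optical density and Ruifrok-Johnston deconvolution.

test_that("optical density follows the Beer-Lambert form with floor and clip", {
  blank <- sectionImage(array(255, dim = c(4, 4, 3)))
  expect_equal(odArray(rgbToOD(blank)), array(0, dim = c(4, 4, 3)))

  # one channel at a tenth of the background is one decade of absorbance
  px <- array(255, dim = c(2, 2, 3))
  px[, , 2] <- 25.5
  od <- odArray(rgbToOD(sectionImage(px), backgroundIntensity = 255))
  expect_equal(od[, , 2], matrix(1, 2, 2))
  expect_equal(od[, , 1], matrix(0, 2, 2))

  # intensities above background clip to zero density
  dim3 <- c(1, 1, 3)
  bright <- sectionImage(array(250, dim = dim3))
  expect_equal(odArray(rgbToOD(bright, backgroundIntensity = 200)),
               array(0, dim = dim3))

  # zero pixels hit the intensity floor, not infinity
  dark <- sectionImage(array(0, dim = dim3))
  expect_true(all(is.finite(odArray(rgbToOD(dark)))))
  expect_error(rgbToOD(blank, backgroundIntensity = 0), "background")
})

test_that("od/rgb round trip reproduces intensities within one level", {
  set.seed(101)
  px <- array(runif(12 * 12 * 3, min = 5, max = 255), dim = c(12, 12, 3))
  img <- sectionImage(px)
  back <- odToRGB(rgbToOD(img), backgroundIntensity = 255)
  expect_lt(max(abs(imagePixels(back) - px)), 1)
})

test_that("deconvolution inverts the stain mixture", {
  sv <- stainPresets("h_dab")
  m <- stainMatrix(completeStainBasis(sv))

  # a pixel that is exactly 0.7 x stain 1
  od <- array(0.7 * m[, 1], dim = c(1, 1, 3))
  ch <- deconvolveStains(od, sv)
  expect_equal(as.numeric(ch), c(0.7, 0, 0), tolerance = 1e-12)

  # identity basis passes densities through unchanged
  eye <- stainVectors(diag(3), names = c("r", "g", "b"))
  odr <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  expect_equal(unname(deconvolveStains(odr, eye)), odr, tolerance = 1e-12)

  # noise-free synthetic mixture is recovered exactly
  set.seed(7)
  cTrue <- array(runif(6 * 6 * 3, 0, 2), dim = c(6, 6, 3))
  odMix <- recomposeOD(cTrue, sv)
  expect_equal(unname(deconvolveStains(odMix, sv)), cTrue,
               tolerance = 1e-9)
  # and recomposition inverts deconvolution to numerical precision
  expect_equal(recomposeOD(deconvolveStains(odMix, sv), sv), odMix,
               tolerance = 1e-12)
})

test_that("degenerate stain bases are rejected", {
  expect_error(
    stainVectors(cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))),
    "independent")
  # two identical columns cannot be completed into a basis
  expect_error(
    deconvolveStains(array(0.1, dim = c(2, 2, 3)),
                     stainVectors(cbind(c(1, 0, 0), c(1, 0, 0)))),
    "independent|singular|degenerate")
})

test_that("segmentation thresholds and size-filters as specified", {
  expect_true(all(maskArray(segmentStain(matrix(1, 8, 8), threshold = 0.5))))
  expect_false(any(maskArray(segmentStain(matrix(0.2, 8, 8), threshold = 0.5))))

  # 5 px object dies, 500 px object survives a 20 px filter
  ch <- matrix(0, 64, 64)
  ch[2, 2:6] <- 1                     # 5 px
  ch[20:44, 20:39] <- 1               # 500 px
  m <- maskArray(segmentStain(ch, threshold = 0.5, minObjectPx = 20))
  expect_equal(sum(m), 500)
  expect_false(m[2, 2])

  # raising the threshold never adds pixels
  set.seed(21)
  ch <- matrix(runif(40 * 40), 40, 40)
  ths <- seq(0.1, 0.9, by = 0.2)
  masks <- lapply(ths, function(t) maskArray(segmentStain(ch, t)))
  for (i in seq_len(length(ths) - 1))
    expect_true(all(masks[[i]] | !masks[[i + 1]]))
})

test_that("otsu mode separates a bimodal channel", {
  set.seed(5)
  lo <- rnorm(500, 0.05, 0.02); hi <- rnorm(500, 1, 0.05)
  ch <- matrix(c(lo, hi), 25, 40)
  th <- otsuThreshold(ch)
  # the cut separates the two populations
  expect_gt(th, max(lo))
  expect_lt(th, min(hi))
  m <- maskArray(segmentStain(ch, threshold = "otsu"))
  expect_equal(sum(m), 500)
})
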