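# Radius-of-action coverage and its brute-force equivalence.

test_that("coverage handles the degenerate mask cases", {
  tum <- binaryMask(matrix(TRUE, 32, 32), 1, "tumor")
  none <- binaryMask(matrix(FALSE, 32, 32), 1, "nsc")
  expect_equal(unname(coverageFraction(none, tum, c(25, 50))), c(0, 0))
  expect_error(coverageFraction(none,
                                binaryMask(matrix(FALSE, 32, 32), 1, "tumor")),
               "empty tumor")

  # tumor enclosed by an NSC ring is fully covered
  nsc <- matrix(FALSE, 64, 64)
  nsc[20, 20:44] <- TRUE; nsc[44, 20:44] <- TRUE
  nsc[20:44, 20] <- TRUE; nsc[20:44, 44] <- TRUE
  tumor <- matrix(FALSE, 64, 64); tumor[28:36, 28:36] <- TRUE
  expect_equal(unname(coverageFraction(binaryMask(nsc, 1, "nsc"),
                                       binaryMask(tumor, 1, "tumor"), 25)),
               100)
})

test_that("a centered point source covers the exact lattice disk", {
  # enumerate the disk by exhaustive distance computation
  H <- 201; W <- 201
  nsc <- matrix(FALSE, H, W); nsc[101, 101] <- TRUE
  tum <- matrix(TRUE, H, W)
  expectPx <- sum(outer((1:H - 101)^2, (1:W - 101)^2, "+") <= 50^2)
  got <- coverageFraction(binaryMask(nsc, 1, "nsc"),
                          binaryMask(tum, 1, "tumor"), 50)
  expect_equal(unname(got), 100 * expectPx / (H * W))
})

test_that("distance-transform coverage equals brute force on random masks", {
  set.seed(99)
  for (i in 1:8) {
    H <- sample(40:128, 1); W <- sample(40:128, 1)
    nsc <- matrix(runif(H * W) < 0.004, H, W)
    tum <- matrix(FALSE, H, W)
    # random blob-ish tumor: union of a few rectangles
    for (b in 1:3) {
      r0 <- sort(sample(H, 2)); c0 <- sort(sample(W, 2))
      tum[r0[1]:r0[2], c0[1]:c0[2]] <- TRUE
    }
    if (!any(tum)) tum[1:10, 1:10] <- TRUE
    r <- sample(c(10, 25, 50), 1)
    got <- unname(coverageFraction(binaryMask(nsc, 1, "nsc"),
                                   binaryMask(tum, 1, "tumor"), r))
    expect_identical(got, bruteCoverage(nsc, tum, r))
  }
})

test_that("coverage is monotone in radius and in NSC inclusion", {
  set.seed(55)
  H <- 96; W <- 96
  tum <- matrix(runif(H * W) < 0.5, H, W)
  tum[40:60, 40:60] <- TRUE
  nscA <- matrix(runif(H * W) < 0.002, H, W)
  nscB <- nscA | (matrix(runif(H * W) < 0.002, H, W))
  tumM <- binaryMask(tum, 1, "tumor")
  radii <- c(0, 5, 10, 20, 40, 80)
  covA <- coverageFraction(binaryMask(nscA, 1, "nsc"), tumM, radii)
  expect_true(all(diff(covA) >= 0))
  covB <- coverageFraction(binaryMask(nscB, 1, "nsc"), tumM, radii)
  expect_true(all(covB >= covA))

  # radius zero reduces to the overlap fraction
  expect_equal(unname(covA[1]), 100 * sum(nscA & tum) / sum(tum))
})

test_that("a known rigid offset can be applied to the NSC mask", {
  nsc <- matrix(FALSE, 32, 32); nsc[10, 10] <- TRUE
  tum <- matrix(FALSE, 32, 32); tum[15, 13] <- TRUE
  nscM <- binaryMask(nsc, 1, "nsc"); tumM <- binaryMask(tum, 1, "tumor")
  expect_equal(unname(coverageFraction(nscM, tumM, 2)), 0)
  # shifting the NSC mask by (+5, +3) puts the source on the tumor pixel
  expect_equal(unname(coverageFraction(nscM, tumM, 2,
                                       offsetPx = c(5L, 3L))), 100)
})

test_that("theoretical maximum and efficiency behave as defined", {
  expect_equal(theoreticalMaxCoverage(0, 1e4), 0)
  expect_equal(theoreticalMaxCoverage(1e6, 1e4), 100)   # capped
  rEff <- sqrt(100 / pi)
  expect_equal(theoreticalMaxCoverage(10, 1e4, radiusUm = rEff,
                                      cellRadiusUm = 0), 10)
  expect_error(theoreticalMaxCoverage(10, 0), "undefined")

  expect_equal(coverageEfficiency(30, 30), 1)
  expect_equal(coverageEfficiency(0, 40), 0)
  expect_error(coverageEfficiency(10, 0), "undefined")
  expect_warning(coverageEfficiency(50, 40), "capped")
})

test_that("widely spaced interior sources reach unit efficiency", {
  H <- 360; W <- 360
  xy <- expand.grid(x = c(80, 200, 320) - 21, y = c(80, 200, 320) - 21)
  nsc <- matrix(FALSE, H, W)
  nsc[cbind(xy$y + 1, xy$x + 1)] <- TRUE   # isolated single-pixel cells
  tum <- binaryMask(matrix(TRUE, H, W), 1, "tumor")
  obs <- unname(coverageFraction(binaryMask(nsc, 1, "nsc"), tum, 50))
  theo <- theoreticalMaxCoverage(nrow(xy), H * W, radiusUm = 50,
                                 cellRadiusUm = 0)
  expect_equal(coverageEfficiency(obs, theo), 1, tolerance = 0.02)
})

test_that("the distance map itself is exact and in physical units", {
  m <- matrix(FALSE, 20, 20); m[5, 5] <- TRUE
  dm <- maskDistanceMap(binaryMask(m, 2, "nsc"))
  expect_equal(dm[5, 5], 0)
  expect_equal(dm[5, 9], 8)         # 4 px at 2 um/px
  expect_equal(dm[8, 9], 10)        # 3-4-5 triangle
})

test_that("the coverage overlay encodes the three classes", {
  nsc <- matrix(FALSE, 40, 40); nsc[20, 20] <- TRUE
  tum <- matrix(FALSE, 40, 40); tum[10:30, 10:30] <- TRUE
  ov <- coverageOverlay(binaryMask(nsc, 1, "nsc"),
                        binaryMask(tum, 1, "tumor"), radiusUm = 6)
  expect_equal(dim(ov), c(40, 40, 3))
  expect_equal(ov[20, 20, ], c(0.85, 0.10, 0.10))       # NSC red
  expect_equal(ov[20, 24, ], c(0.55, 0.90, 0.45))       # covered tumor
  expect_equal(ov[10, 30, ], c(0.00, 0.35, 0.10))       # distant tumor
  expect_equal(ov[1, 1, ], c(1, 1, 1))                  # background
})
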