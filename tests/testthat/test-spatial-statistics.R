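# Pairwise distances, single-linkage clusters and the clustering index.

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  d <- pairwiseDistances(data.frame(x_um = c(0, 3), y_um = c(0, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c("1" = 0, "2" = 0), ignore_attr = TRUE)

  set.seed(13)
  xy <- matrix(runif(100, 0, 500), 50, 2)
  d <- pairwiseDistances(xy)
  # exhaustive double loop oracle
  ref <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    ref[i, j] <- sqrt((xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2)
  expect_equal(unname(d), ref, tolerance = 1e-12)
  expect_identical(unname(d), unname(t(d)))
})

test_that("single-linkage clusters follow the threshold graph", {
  two <- function(gap) data.frame(x_um = c(0, gap), y_um = 0)
  expect_equal(clusterPoints(two(49), 50)$nClusters, 1)
  expect_equal(clusterPoints(two(51), 50)$nClusters, 2)
  expect_equal(clusterPoints(two(50), 50)$nClusters, 1)   # tie joins

  # transitive chain: spacings 40, 40, ends 80 apart
  chain <- data.frame(x_um = c(0, 40, 80), y_um = 0)
  expect_equal(clusterPoints(chain, 50)$nClusters, 1)

  expect_equal(clusterPoints(data.frame(x_um = 1, y_um = 1), 50)$nClusters, 1)
  expect_error(clusterPoints(data.frame(x_um = numeric(0),
                                        y_um = numeric(0)), 50),
               "no cells")
})

test_that("labels are permutation invariant up to relabeling", {
  set.seed(23)
  pts <- data.frame(x_um = runif(60, 0, 400), y_um = runif(60, 0, 400))
  res <- clusterPoints(pts, 50)
  perm <- sample.int(60)
  resP <- clusterPoints(pts[perm, ], 50)
  expect_equal(resP$nClusters, res$nClusters)
  # same partition: co-membership matrices agree after permutation
  co <- outer(res$labels, res$labels, "==")
  coP <- outer(resP$labels, resP$labels, "==")
  expect_identical(coP, co[perm, perm])
})

test_that("the clustering index follows its formula and bounds", {
  expect_equal(clusteringIndex(10, 10), 0)    # complete dispersion
  expect_equal(clusteringIndex(1, 10), 0.9)   # one cluster of ten
  expect_equal(clusteringIndex(1, 1), 0)      # a single cell
  expect_error(clusteringIndex(0, 0), ">= 1")
  expect_error(clusteringIndex(11, 10), "nClusters")

  set.seed(29)
  for (i in 1:5) {
    n <- sample(2:40, 1)
    pts <- data.frame(x_um = runif(n, 0, 300), y_um = runif(n, 0, 300))
    res <- clusterPoints(pts, 50)
    expect_gte(res$ci, 0)
    expect_lte(res$ci, 1 - 1 / n)
    expect_equal(res$ci, clusteringIndex(res, n))
  }
})

test_that("CI is non-increasing as the clustering radius shrinks", {
  set.seed(37)
  pts <- data.frame(x_um = runif(80, 0, 500), y_um = runif(80, 0, 500))
  radii <- c(200, 100, 50, 25, 10, 0)
  cis <- vapply(radii, function(r) clusterPoints(pts, r)$ci, numeric(1))
  expect_true(all(diff(cis) <= 0))
  expect_equal(cis[length(radii)], 0)   # radius 0: all singletons
})

test_that("ciSummary returns the box-plot percentiles", {
  ci <- seq(0, 1, by = 0.1)
  s <- ciSummary(ci)
  expect_equal(unname(s["median"]), 0.5)
  expect_equal(unname(s["p25"]), 0.25)
  expect_equal(unname(s["p90"]), 0.9)
  expect_equal(unname(s["n"]), 11)
})
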