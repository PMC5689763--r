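# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check: coverage by
# exhaustive per-pixel nearest-neighbor enumeration, ranks by explicit
# mid-rank assignment, regression and t statistics by their closed forms.

# exhaustive nearest-NSC squared-distance map (pixel units)
bruteDistSq <- function(nscMat) {
  H <- nrow(nscMat); W <- ncol(nscMat)
  idx <- which(nscMat, arr.ind = TRUE)
  d2 <- matrix(Inf, H, W)
  if (!nrow(idx)) return(d2)
  rows <- row(d2); cols <- col(d2)
  for (k in seq_len(nrow(idx)))
    d2 <- pmin(d2, (rows - idx[k, 1])^2 + (cols - idx[k, 2])^2)
  d2
}

# brute-force percent coverage for one radius (um), pixel size 1 um
bruteCoverage <- function(nscMat, tumorMat, radiusUm) {
  if (!any(nscMat)) return(0)
  d2 <- bruteDistSq(nscMat)
  100 * sum(d2[tumorMat] <= radiusUm^2) / sum(tumorMat)
}

# rasterize disks of radius r (um at 1 um/px) around (x, y) centers,
# independent of the package's stamping kernel
rasterDisks <- function(x, y, H, W, r) {
  m <- matrix(FALSE, H, W)
  px <- col(m) - 1; py <- row(m) - 1
  for (k in seq_along(x))
    m <- m | ((px - x[k])^2 + (py - y[k])^2 <= r^2)
  m
}

# mid-ranks with average ties, by explicit assignment
midRanks <- function(x) {
  sorted <- sort(x)
  vapply(x, function(xi) {
    lower <- sum(sorted < xi)
    ties <- sum(sorted == xi)
    lower + (ties + 1) / 2
  }, numeric(1))
}

# a small fast phantom spec; override as needed
smallSpec <- function(...) {
  args <- list(
    imageSizePx = c(128L, 128L),
    nSections = 4L,
    spacingUm = 100,
    tumorCenterUm = c(63.5, 63.5, 150),
    tumorSemiAxesUm = c(45, 38, 160),
    nNscTotal = 300L,
    administeredNsc = 600L,
    seed = 11L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(phantomSpec, args)
}
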