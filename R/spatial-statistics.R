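# NSC spatial statistics: pairwise distances, fixed-radius single-linkage
# clusters, and the clustering index CI = 1 - clusters/NSCs.

#' Pairwise Euclidean distances between cell centroids
#'
#' @param centroids data.frame with columns `x_um`, `y_um` (as returned by
#'   [detectCells()]), or a two-column matrix of coordinates in um.
#' @return symmetric N x N matrix of distances in um, zero diagonal.
#' @examples
#' pairwiseDistances(data.frame(x_um = c(0, 3), y_um = c(0, 4)))  # 5
#' @export
pairwiseDistances <- function(centroids) {
  xy <- .centroidMatrix(centroids)
  if (nrow(xy) < 1L) stop("at least one centroid is required")
  as.matrix(stats::dist(xy))
}

.centroidMatrix <- function(centroids) {
  if (is.data.frame(centroids)) {
    stopifnot(all(c("x_um", "y_um") %in% names(centroids)))
    cbind(centroids$x_um, centroids$y_um)
  } else {
    m <- as.matrix(centroids)
    stopifnot(ncol(m) == 2L)
    m
  }
}

#' Cluster cells at a fixed clustering radius
#'
#' Two cells belong to the same cluster when they are linked by a chain of
#' pairwise distances each at most `clusteringRadiusUm` (single linkage:
#' connected components of the threshold graph). A tie at exactly the
#' radius counts as connected. Labels are connected-component ids and are
#' invariant to input ordering up to relabeling.
#'
#' @param centroids as in [pairwiseDistances()]; N >= 1.
#' @param clusteringRadiusUm clustering radius in um, default 50 (the
#'   study's choice).
#' @return list with `labels` (integer per cell), `nClusters`, `ci` (the
#'   clustering index), and `clusteringRadiusUm`.
#' @examples
#' pts <- data.frame(x_um = c(0, 40, 80, 500), y_um = 0)
#' clusterPoints(pts, 50)$nClusters   # 2: a 3-chain and a singleton
#' @export
clusterPoints <- function(centroids, clusteringRadiusUm = 50) {
  if (clusteringRadiusUm < 0) stop("'clusteringRadiusUm' must be >= 0")
  xy <- .centroidMatrix(centroids)
  n <- nrow(xy)
  if (n == 0L) stop("no cells: clusters undefined")
  if (n == 1L) {
    labels <- 1L
  } else {
    adj <- as.matrix(stats::dist(xy)) <= clusteringRadiusUm
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    labels <- as.integer(igraph::components(g)$membership)
  }
  k <- length(unique(labels))
  list(labels = labels, nClusters = k, ci = 1 - k / n,
       clusteringRadiusUm = clusteringRadiusUm)
}

#' Clustering index
#'
#' `CI = 1 - nClusters / nCells` at a fixed clustering radius. CI = 0 is
#' complete dispersion (every cell its own cluster); the maximum
#' `1 - 1/N` is attained when all N cells form a single cluster.
#'
#' @param nClusters number of clusters (or the list from
#'   [clusterPoints()], whose `nClusters` is used).
#' @param nCells total number of cells, >= 1.
#' @return CI in [0, 1 - 1/N].
#' @examples
#' clusteringIndex(1, 10)   # 0.9
#' @export
clusteringIndex <- function(nClusters, nCells) {
  if (is.list(nClusters)) nClusters <- nClusters$nClusters
  if (nCells < 1) stop("'nCells' must be >= 1")
  if (nClusters < 1 || nClusters > nCells)
    stop("'nClusters' must lie in [1, nCells]")
  1 - nClusters / nCells
}

#' Box-plot summary of per-section clustering indices
#'
#' The study's per-brain CI display: median, quartiles and the 10th/90th
#' percentiles of the per-section CIs.
#'
#' @param ci numeric vector of per-section clustering indices.
#' @return named numeric vector `p10`, `p25`, `median`, `p75`, `p90`, `n`.
#' @export
ciSummary <- function(ci) {
  q <- stats::quantile(ci, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  c(p10 = q[1], p25 = q[2], median = q[3], p75 = q[4], p90 = q[5],
    n = length(ci))
}
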