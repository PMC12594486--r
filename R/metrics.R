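# Global network measures: mean strength, global efficiency, modularity.
#
# Graph plumbing (shortest paths, Louvain community search) is delegated to
# igraph; the metric definitions and the weight-to-distance convention live
# here.

.graphOf <- function(m) {
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Mean node strength
#'
#' Mean over nodes of the sum of incident edge weights.
#'
#' @param x a [Connectome-class] or symmetric numeric matrix.
#' @return nonnegative scalar.
#' @examples
#' meanStrength(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))  # 2
#' @export
meanStrength <- function(x) {
  m <- strengthMatrix(x)
  if (nrow(m) == 0L) stop("connectome has no nodes")
  mean(rowSums(m))
}

#' Weighted global efficiency
#'
#' Average over ordered node pairs of the inverse shortest-path length, with
#' edge length `1 / weight` (the usual connectomics convention: stronger
#' connections are shorter). Disconnected pairs contribute 0. Note the
#' measure scales linearly with a global weight factor.
#'
#' @param x a [Connectome-class] or symmetric numeric matrix.
#' @return nonnegative scalar (1 for a complete unit-weight graph).
#' @export
globalEfficiency <- function(x) {
  m <- strengthMatrix(x)
  n <- nrow(m)
  if (n < 2L) return(0)
  if (all(m == 0)) return(0)
  g <- .graphOf(m)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted modularity of the best Louvain partition
#'
#' Runs a seeded multi-restart Louvain community search and returns the
#' Newman-Girvan weighted modularity Q of the best partition found. Q is
#' invariant to a global rescaling of the weights.
#'
#' @param x a [Connectome-class] or symmetric numeric matrix with positive
#'   total weight.
#' @param seed optional integer seed (the search is stochastic).
#' @param resolution Louvain resolution parameter (default 1).
#' @param restarts number of restarts; the best Q is kept (default 10).
#' @return scalar Q in `[-0.5, 1]`.
#' @examples
#' tri2 <- matrix(0, 6, 6)
#' tri2[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
#' tri2 <- tri2 + t(tri2)
#' modularityQ(tri2, seed = 1)  # 0.5
#' @export
modularityQ <- function(x, seed = NULL, resolution = 1, restarts = 10) {
  m <- strengthMatrix(x)
  if (sum(m) <= 0) stop("total edge weight must be positive")
  g <- .graphOf(m)
  withSeed(seed, {
    best <- -Inf
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      q <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight)
      if (q > best) best <- q
    }
    best
  })
}

#' The three global network measures used in group comparisons
#'
#' @param x a [Connectome-class] or symmetric numeric matrix.
#' @param seed optional integer seed for the modularity search.
#' @return named numeric vector `meanStrength`, `globalEfficiency`,
#'   `modularity`.
#' @export
networkMetrics <- function(x, seed = NULL) {
  c(meanStrength = meanStrength(x),
    globalEfficiency = globalEfficiency(x),
    modularity = modularityQ(x, seed = seed))
}
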