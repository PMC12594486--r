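# Independent oracles used to cross-check the package implementations.
# These deliberately use brute-force formulations and share no code with the
# package internals.

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight;
# returns the average inverse distance over ordered pairs.
fwEfficiency <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[m > 0] <- 1 / m[m > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Global NNLS optimum by enumerating every active set: for each subset of
# columns solve the unconstrained least-squares problem and keep the feasible
# (componentwise nonnegative) solution with the smallest objective.
exhaustiveNnls <- function(A, y) {
  n <- ncol(A)
  best <- rep(0, n)
  bestObj <- sum(y^2)
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    s <- tryCatch(qr.solve(A[, idx, drop = FALSE], y),
                  error = function(e) NULL)
    if (is.null(s) || any(!is.finite(s)) || any(s < 0)) next
    obj <- sum((A[, idx, drop = FALSE] %*% s - y)^2)
    if (obj < bestObj - 1e-12) {
      bestObj <- obj
      best <- rep(0, n)
      best[idx] <- s
    }
  }
  best
}

# All set partitions of n elements as membership vectors (restricted growth
# strings).
allPartitions <- function(n) {
  out <- list()
  recur <- function(prefix, maxLabel) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxLabel + 1L))
      recur(c(prefix, lab), max(maxLabel, lab))
  }
  recur(integer(0), 0L)
  out
}

# Newman-Girvan weighted modularity of a given membership vector.
modularityOf <- function(m, membership) {
  tw <- sum(m) / 2
  deg <- rowSums(m)
  q <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(nrow(m)))
      if (membership[i] == membership[j])
        q <- q + m[i, j] / (2 * tw) - deg[i] * deg[j] / (2 * tw)^2
  q
}

# Dense point-sampling estimate of per-voxel intersection lengths: each
# polyline segment is split into `samples` equal pieces assigned to the voxel
# of their midpoint.
sampledTraversal <- function(points, gridDim, samples = 1e4) {
  keys <- integer(0)
  lens <- numeric(0)
  for (j in seq_len(nrow(points) - 1L)) {
    p0 <- points[j, ]; p1 <- points[j + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    mids <- (seq_len(samples) - 0.5) / samples
    M <- outer(mids, p1 - p0) + matrix(p0, samples, 3, byrow = TRUE)
    v <- floor(M)
    keys <- c(keys, v[, 1] + gridDim[1] * (v[, 2] + gridDim[2] * v[, 3]) + 1)
    lens <- c(lens, rep(len / samples, samples))
  }
  agg <- rowsum(lens, keys)
  data.frame(voxel = as.integer(rownames(agg)), length = agg[, 1],
             row.names = NULL)
}

# A random polyline staying strictly inside the grid.
randomPolyline <- function(nPoints, gridDim, margin = 0.25) {
  sapply(gridDim, function(d) runif(nPoints, margin, d - margin))
}

# Random lesioned multi-bundle phantom paired with a damaged signal; the
# lesion avoids covering all exclusive voxels of any bundle so the noiseless
# system stays identifiable.
randomLesionedPhantom <- function(seed, damage, nNodes = 6, nBundles = 8,
                                  lesionFraction = 0.08) {
  phantom <- makeBundlePhantom(nNodes = nNodes, nBundles = nBundles,
                               seed = seed)
  mask <- generateLesionMask(phantom@wmMask, lesionFraction, seed = seed + 1L)
  signal <- applyDamage(phantomSignal(phantom), mask, damage)
  list(phantom = phantom, mask = mask, signal = signal)
}
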