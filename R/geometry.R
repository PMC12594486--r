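# Exact streamline-voxel intersection geometry.
#
# Convention: continuous voxel coordinates u are world coordinates mapped
# through the inverse affine; voxel index k (0-based) owns the half-open
# interval [k, k+1) on each axis. The default affine is diag(voxelSize) with
# zero translation, i.e. the grid corner sits at the world origin. Each
# polyline segment is clipped against the integer planes it crosses; every
# sub-segment is assigned to the voxel containing its midpoint, which is
# interior to the sub-segment and therefore implements the half-open rule
# with a deterministic tie-break (boundary points belong to the higher-index
# voxel).

worldToVoxelCoords <- function(points, voxelSize = 1, affine = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (is.null(affine)) return(points / voxelSize)
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  inv <- tryCatch(solve(affine), error = function(e)
    stop("'affine' is not invertible"))
  u <- inv %*% rbind(t(points), 1)
  t(u[1:3, , drop = FALSE])
}

# Clip one polyline into (voxel, length, tStart) sub-segments.
# Returns a list with vectors voxel (1-based linear), len (world mm), tStart
# (arc-length parameter in [0,1) at which the sub-segment begins).
.clipPolyline <- function(points, gridDim, voxelSize = 1, affine = NULL) {
  gridDim <- checkGridDim(gridDim)
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 2L) stop("a streamline needs at least 2 points")
  if (!all(is.finite(points))) stop("streamline coordinates must be finite")
  U <- worldToVoxelCoords(points, voxelSize, affine)

  segVec <- diff(points)
  segLen <- sqrt(rowSums(segVec^2))
  keep <- segLen > 0                       # repeated points: skipped silently
  total <- sum(segLen)
  if (total == 0) stop("streamline has zero total length")
  cum <- cumsum(c(0, segLen))

  vox <- integer(0); len <- numeric(0); tStart <- numeric(0)
  for (j in which(keep)) {
    u0 <- U[j, ]; u1 <- U[j + 1L, ]
    tb <- c(0, 1)
    for (ax in 1:3) {
      a <- u0[ax]; b <- u1[ax]
      if (a == b) next
      lo <- floor(min(a, b)) + 1L
      hi <- ceiling(max(a, b)) - 1L
      if (hi >= lo) {
        tc <- (seq.int(lo, hi) - a) / (b - a)
        tb <- c(tb, tc[tc > 0 & tc < 1])
      }
    }
    tb <- sort(unique(tb))
    dt <- diff(tb)
    nz <- dt > 0
    if (!any(nz)) next
    mids <- tb[-length(tb)][nz] + dt[nz] / 2
    M <- sweep(outer(mids, u1 - u0), 2, u0, "+")  # midpoint voxel coords
    ijk <- floor(M)
    bad <- which(ijk[, 1] < 0 | ijk[, 2] < 0 | ijk[, 3] < 0 |
                 ijk[, 1] >= gridDim[1] | ijk[, 2] >= gridDim[2] |
                 ijk[, 3] >= gridDim[3])
    if (length(bad)) {
      w <- points[j, ] + mids[bad[1]] * segVec[j, ]
      stop(sprintf(
        "streamline exits the grid near world point (%.4g, %.4g, %.4g)",
        w[1], w[2], w[3]))
    }
    vox <- c(vox, voxelIndex(ijk, gridDim))
    len <- c(len, dt[nz] * segLen[j])
    tStart <- c(tStart, (cum[j] + tb[-length(tb)][nz] * segLen[j]) / total)
  }
  list(voxel = vox, len = len, tStart = tStart, totalLength = total)
}

#' Exact streamline-voxel intersection lengths
#'
#' Clips a polyline against the voxel grid and returns, per traversed voxel,
#' the total intersection length `l(i, v)` in mm. Lengths over all voxels sum
#' to the polyline arc length exactly (up to floating point).
#'
#' @param points `n x 3` numeric matrix of world coordinates (mm), `n >= 2`.
#' @param gridDim integer triple of grid dimensions.
#' @param voxelSize isotropic voxel edge length (mm); ignored when `affine`
#'   is given.
#' @param affine optional 4x4 matrix mapping continuous voxel coordinates
#'   (corner convention: voxel `k` owns `[k, k+1)`) to world mm.
#' @return data.frame with columns `voxel` (1-based linear index) and
#'   `length` (mm), one row per traversed voxel, in first-entry order.
#' @examples
#' traverseStreamline(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)), c(3, 1, 1))
#' @export
traverseStreamline <- function(points, gridDim, voxelSize = 1, affine = NULL) {
  cl <- .clipPolyline(points, gridDim, voxelSize, affine)
  agg <- rowsum(cl$len, group = cl$voxel, reorder = FALSE)
  data.frame(voxel = as.integer(rownames(agg)), length = as.numeric(agg))
}

#' Voxels visited by a streamline, in traversal order
#'
#' Returns the ordered voxel sequence with the arc-length parameter
#' `t in [0, 1]` at which each voxel is first entered. A voxel re-entered
#' later (e.g. by a loop) appears again; consecutive sub-segments inside the
#' same voxel are merged.
#'
#' @inheritParams traverseStreamline
#' @return data.frame with columns `voxel` and `t` (entry parameter).
#' @examples
#' visitedVoxels(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)), c(3, 1, 1))
#' @export
visitedVoxels <- function(points, gridDim, voxelSize = 1, affine = NULL) {
  cl <- .clipPolyline(points, gridDim, voxelSize, affine)
  if (!length(cl$voxel))
    return(data.frame(voxel = integer(0), t = numeric(0)))
  run <- c(TRUE, cl$voxel[-1L] != cl$voxel[-length(cl$voxel)])
  data.frame(voxel = cl$voxel[run], t = cl$tStart[run])
}

#' Build the segment table of a tractogram
#'
#' Applies [traverseStreamline()] to every streamline and stacks the results
#' into a [SegmentTable-class], the geometric substrate of the forward
#' operator.
#'
#' @param tractogram a [Tractogram-class] (or a [Phantom-class], whose bundle
#'   streamlines and grid are then used).
#' @inheritParams traverseStreamline
#' @return a [SegmentTable-class].
#' @examples
#' ph <- makeCrossingPhantom()
#' segmentTable(ph$phantom)
#' @export
segmentTable <- function(tractogram, gridDim = NULL, voxelSize = 1,
                         affine = NULL) {
  if (is(tractogram, "Phantom")) {
    if (is.null(gridDim)) gridDim <- tractogram@gridDim
    voxelSize <- tractogram@voxelSize
    tractogram <- tractogram(tractogram)
  }
  if (is.null(gridDim)) stop("'gridDim' is required for a plain Tractogram")
  gridDim <- checkGridDim(gridDim)
  sl <- streamlines(tractogram)
  parts <- lapply(seq_along(sl), function(i) {
    tr <- traverseStreamline(sl[[i]], gridDim, voxelSize, affine)
    cbind(i = rep.int(i, nrow(tr)), v = tr$voxel, l = tr$length)
  })
  tab <- if (length(parts)) do.call(rbind, parts) else
    matrix(numeric(0), ncol = 3L)
  new("SegmentTable",
      streamline = as.integer(tab[, 1]),
      voxel = as.integer(tab[, 2]),
      length = as.numeric(tab[, 3]),
      gridDim = gridDim,
      nStreamlines = length(sl))
}
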