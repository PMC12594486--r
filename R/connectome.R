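# Node assignment and connectome construction.

#' Assign streamline endpoints to parcellation nodes
#'
#' Each endpoint is mapped to the label of its containing voxel (points lying
#' exactly on the outer grid boundary belong to the boundary voxel).
#' Streamlines with an endpoint outside the grid, in the background
#' (label 0), or with both endpoints in the same node (self-loops) are marked
#' unassigned.
#'
#' @param tractogram a [Tractogram-class].
#' @param parcellation integer 3D label array (0 = background).
#' @param voxelSize isotropic voxel edge length; ignored when `affine` given.
#' @param affine optional 4x4 voxel-to-world matrix (corner convention).
#' @return data.frame with columns `nodeA`, `nodeB` (smaller label first,
#'   `NA` when unassigned) and logical `assigned`.
#' @export
assignNodes <- function(tractogram, parcellation, voxelSize = 1,
                        affine = NULL) {
  stopifnot(is(tractogram, "Tractogram"))
  gridDim <- as.integer(dim(parcellation))
  if (length(gridDim) != 3L) stop("parcellation must be a 3D array")
  endVoxelLabel <- function(p) {
    u <- as.numeric(worldToVoxelCoords(matrix(p, ncol = 3L), voxelSize,
                                       affine))
    if (any(u < 0) || any(u > gridDim)) return(NA_integer_)
    f <- pmin(floor(u), gridDim - 1L)   # boundary points -> boundary voxel
    as.integer(parcellation[f[1] + 1L, f[2] + 1L, f[3] + 1L])
  }
  sl <- streamlines(tractogram)
  out <- t(vapply(sl, function(s) {
    a <- endVoxelLabel(s[1L, ])
    b <- endVoxelLabel(s[nrow(s), ])
    if (is.na(a) || is.na(b) || a == 0L || b == 0L || a == b)
      c(NA_integer_, NA_integer_)
    else
      c(min(a, b), max(a, b))
  }, integer(2)))
  if (!length(sl)) out <- matrix(integer(0), ncol = 2L)
  data.frame(nodeA = out[, 1], nodeB = out[, 2],
             assigned = !is.na(out[, 1]))
}

#' Build a connectome from streamline weights and node assignments
#'
#' Edge `(a, b)` sums the weights of all streamlines assigned to that node
#' pair; unassigned streamlines are excluded. Passing weakest-link adjusted
#' weights yields the multi-compartment variant.
#'
#' @param weights numeric vector aligned with `assignments` rows.
#' @param assignments data.frame from [assignNodes()].
#' @param nNodes number of parcellation nodes.
#' @param variant `"standard"` or `"multicompartment"`.
#' @return a [Connectome-class].
#' @examples
#' asn <- data.frame(nodeA = c(1L, 1L), nodeB = c(2L, 2L),
#'                   assigned = c(TRUE, TRUE))
#' strengthMatrix(buildConnectome(c(0.1, 0.2), asn, 2))[1, 2]  # 0.3
#' @export
buildConnectome <- function(weights, assignments, nNodes,
                            variant = c("standard", "multicompartment")) {
  variant <- match.arg(variant)
  if (length(weights) != nrow(assignments))
    stop("need one weight per assignment row")
  if (any(weights < 0)) stop("weights must be nonnegative")
  keep <- which(assignments$assigned)
  a <- assignments$nodeA[keep]
  b <- assignments$nodeB[keep]
  if (length(keep) && (max(a, b) > nNodes || min(a, b) < 1L))
    stop("node index outside 1..nNodes")
  m <- matrix(0, nNodes, nNodes)
  for (j in seq_along(keep)) {
    m[a[j], b[j]] <- m[a[j], b[j]] + weights[keep[j]]
    m[b[j], a[j]] <- m[a[j], b[j]]
  }
  new("Connectome", matrix = m, variant = variant)
}

#' Threshold a connectome to a target edge density
#'
#' Keeps the strongest edges until the edge count over the number of possible
#' edges `n (n - 1) / 2` is at most `targetDensity`. All edges tied with the
#' cutoff weight are kept (the result may overshoot the target density), so
#' the operation is deterministic.
#'
#' @param connectome a [Connectome-class].
#' @param targetDensity value in `(0, 1]`.
#' @return a thresholded [Connectome-class] of the same variant.
#' @export
thresholdDensity <- function(connectome, targetDensity) {
  stopifnot(is(connectome, "Connectome"))
  if (targetDensity <= 0 || targetDensity > 1)
    stop("'targetDensity' must lie in (0, 1]")
  m <- connectome@matrix
  n <- nrow(m)
  possible <- n * (n - 1) / 2
  ut <- upper.tri(m)
  w <- m[ut]
  nEdges <- sum(w > 0)
  k <- floor(targetDensity * possible)
  if (nEdges <= k) return(connectome)
  if (k == 0L) {
    m[] <- 0
  } else {
    cutoff <- sort(w[w > 0], decreasing = TRUE)[k]
    m[m < cutoff] <- 0
  }
  new("Connectome", matrix = m, variant = connectome@variant)
}
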