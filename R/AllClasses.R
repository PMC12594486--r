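#' @importClassesFrom Matrix dgCMatrix
NULL

# ---------------------------------------------------------------------------
# Tractogram
# ---------------------------------------------------------------------------

#' Tractogram: a set of streamlines in world millimetres
#'
#' A `Tractogram` holds an ordered list of streamlines, each an `n x 3` numeric
#' matrix of world-space points (mm), and optionally one nonnegative weight per
#' streamline (the effective intra-axonal cross-sectional area `c_i`).
#'
#' @slot streamlines list of numeric matrices, each with >= 2 rows and 3 columns.
#' @slot weights numeric vector, either empty or one value per streamline.
#' @export
setClass("Tractogram",
         slots = c(streamlines = "list", weights = "numeric"))

setValidity("Tractogram", function(object) {
  for (s in object@streamlines) {
    if (!is.matrix(s) || !is.numeric(s) || ncol(s) != 3L)
      return("each streamline must be a numeric matrix with 3 columns")
    if (nrow(s) < 2L)
      return("each streamline needs at least 2 points")
    if (!all(is.finite(s)))
      return("streamline coordinates must be finite")
  }
  nw <- length(object@weights)
  if (nw != 0L && nw != length(object@streamlines))
    return("weights must be empty or one per streamline")
  if (nw > 0L && any(object@weights < 0))
    return("weights must be nonnegative")
  TRUE
})

#' Construct a Tractogram
#'
#' @param streamlines list of `n x 3` numeric matrices (world mm).
#' @param weights optional nonnegative weight per streamline.
#' @return A [Tractogram-class] object.
#' @examples
#' tg <- Tractogram(list(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5))))
#' nStreamlines(tg)
#' @export
Tractogram <- function(streamlines, weights = numeric(0)) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  new("Tractogram", streamlines = streamlines, weights = as.numeric(weights))
}

#' @describeIn Tractogram Number of streamlines.
#' @param x a `Tractogram`.
#' @export
nStreamlines <- function(x) length(x@streamlines)

#' @describeIn Tractogram List of streamline point matrices.
#' @export
streamlines <- function(x) x@streamlines

setMethod("show", "Tractogram", function(object) {
  n <- length(object@streamlines)
  np <- if (n) sum(vapply(object@streamlines, nrow, integer(1))) else 0L
  cat("Tractogram with", n, "streamline(s),", np, "points",
      if (length(object@weights)) "(weighted)" else "(unweighted)", "\n")
})

# ---------------------------------------------------------------------------
# SegmentTable
# ---------------------------------------------------------------------------

#' SegmentTable: streamline-voxel intersection lengths
#'
#' Rows are triples (streamline index, 1-based linear voxel index, intersection
#' length in mm). This is the geometric substrate of the forward operator: the
#' entry `l(i, v)` of the operator is the summed length of streamline `i`
#' inside voxel `v`.
#'
#' @slot streamline integer streamline indices (1-based).
#' @slot voxel integer linear voxel indices (1-based, column-major).
#' @slot length positive segment lengths (mm).
#' @slot gridDim integer triple, the voxel grid dimensions.
#' @slot nStreamlines number of streamlines the table was built from.
#' @export
setClass("SegmentTable",
         slots = c(streamline = "integer", voxel = "integer",
                   length = "numeric", gridDim = "integer",
                   nStreamlines = "integer"))

setValidity("SegmentTable", function(object) {
  n <- length(object@streamline)
  if (length(object@voxel) != n || length(object@length) != n)
    return("streamline, voxel and length must have equal length")
  if (n && any(object@length <= 0))
    return("segment lengths must be > 0")
  if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
    return("gridDim must be three positive integers")
  nv <- prod(object@gridDim)
  if (n && (any(object@voxel < 1L) || any(object@voxel > nv)))
    return("voxel indices outside the grid")
  if (n && any(object@streamline > object@nStreamlines))
    return("streamline index exceeds nStreamlines")
  TRUE
})

setMethod("show", "SegmentTable", function(object) {
  cat("SegmentTable:", length(object@voxel), "segments,",
      object@nStreamlines, "streamlines on grid",
      paste(object@gridDim, collapse = "x"), "\n")
})

# ---------------------------------------------------------------------------
# LesionOperator
# ---------------------------------------------------------------------------

#' LesionOperator: sparse forward operator with optional lesion compartment
#'
#' The operator couples the streamline block `A` (`n_voxels x n_streamlines`,
#' entry `l(i, v)` = length of streamline `i` inside voxel `v`, all
#' nonnegative) with the lesion block `L` (`n_voxels x n_lesion_voxels`, one
#' column per pathological voxel holding a single `-1` at that voxel's row).
#' Solving the augmented system lets a nonnegative coefficient per lesion
#' voxel absorb the absolute local signal loss instead of forcing the
#' streamline weights to compensate.
#'
#' @slot A sparse streamline block (`dgCMatrix`).
#' @slot L sparse lesion block (`dgCMatrix`), zero columns when no lesions.
#' @slot lesionVoxels 1-based linear voxel indices of the lesion columns, in
#'   ascending order; column `k` of `L` corresponds to `lesionVoxels[k]`.
#' @slot gridDim integer triple.
#' @export
setClass("LesionOperator",
         slots = c(A = "dgCMatrix", L = "dgCMatrix",
                   lesionVoxels = "integer", gridDim = "integer"))

setValidity("LesionOperator", function(object) {
  nv <- prod(object@gridDim)
  if (nrow(object@A) != nv) return("nrow(A) must equal prod(gridDim)")
  if (nrow(object@L) != nv) return("nrow(L) must equal prod(gridDim)")
  if (length(object@A@x) && any(object@A@x < 0))
    return("A must be elementwise nonnegative")
  if (ncol(object@L) != length(object@lesionVoxels))
    return("one lesion voxel per L column required")
  if (is.unsorted(object@lesionVoxels, strictly = TRUE) &&
      length(object@lesionVoxels) > 1L)
    return("lesionVoxels must be strictly ascending")
  if (ncol(object@L)) {
    dl <- diff(object@L@p)
    if (any(dl != 1L)) return("each L column must have exactly one nonzero")
    if (any(object@L@x != -1)) return("L entries must equal -1")
    rows <- object@L@i + 1L
    if (!identical(rows, object@lesionVoxels))
      return("L nonzero rows must match lesionVoxels")
  }
  TRUE
})

setMethod("show", "LesionOperator", function(object) {
  cat("LesionOperator on grid", paste(object@gridDim, collapse = "x"), "\n",
      " streamline columns:", ncol(object@A), "\n",
      " lesion columns:    ", ncol(object@L), "\n")
})

# ---------------------------------------------------------------------------
# LesionFit
# ---------------------------------------------------------------------------

#' LesionFit: solution of the (augmented) non-negative least-squares problem
#'
#' @slot x nonnegative streamline coefficients `c_i`.
#' @slot xL nonnegative per-lesion-voxel absolute signal losses (empty for a
#'   standard fit).
#' @slot residual per-voxel residual `y - [A|L] [x|xL]` over the whole grid.
#' @slot objective squared l2 misfit, `sum(residual^2)`.
#' @slot lesionVoxels linear indices matching `xL`.
#' @slot gridDim integer triple.
#' @export
setClass("LesionFit",
         slots = c(x = "numeric", xL = "numeric", residual = "numeric",
                   objective = "numeric", lesionVoxels = "integer",
                   gridDim = "integer"))

setValidity("LesionFit", function(object) {
  if (any(object@x < 0)) return("x must be nonnegative")
  if (any(object@xL < 0)) return("xL must be nonnegative")
  if (length(object@xL) != length(object@lesionVoxels))
    return("xL and lesionVoxels must align")
  if (length(object@residual) != prod(object@gridDim))
    return("residual must cover the full grid")
  if (abs(object@objective - sum(object@residual^2)) >
      1e-8 * max(1, object@objective))
    return("objective must equal sum of squared residuals")
  TRUE
})

setMethod("show", "LesionFit", function(object) {
  cat("LesionFit:", length(object@x), "streamline coefficients,",
      length(object@xL), "lesion coefficients\n",
      " objective:", format(object@objective, digits = 6), "\n")
})

#' Fitted streamline weights of a LesionFit
#' @param fit a [LesionFit-class].
#' @return numeric vector of nonnegative streamline coefficients.
#' @export
streamlineWeights <- function(fit) fit@x

#' Fitted per-lesion-voxel signal losses of a LesionFit
#' @param fit a [LesionFit-class].
#' @return numeric vector aligned with `fit@lesionVoxels`.
#' @export
lesionLosses <- function(fit) fit@xL

# ---------------------------------------------------------------------------
# ReductionMap
# ---------------------------------------------------------------------------

#' ReductionMap: per-voxel relative signal reduction R(v)
#'
#' `R(v)` is the fraction of intra-axonal signal surviving pathology in voxel
#' `v`: 1 outside lesions and wherever no damage was fitted, 0 under complete
#' axonal damage. Values are clamped into `[0, 1]`.
#'
#' @slot R 3D numeric array of values in `[0, 1]`.
#' @slot lesionVoxels linear indices of the voxels that carried a lesion column.
#' @export
setClass("ReductionMap",
         slots = c(R = "array", lesionVoxels = "integer"))

setValidity("ReductionMap", function(object) {
  if (length(dim(object@R)) != 3L) return("R must be a 3D array")
  if (any(object@R < 0) || any(object@R > 1)) return("R must lie in [0, 1]")
  out <- object@R
  out[object@lesionVoxels] <- 1
  if (any(out != 1)) return("R must equal 1 outside lesion voxels")
  TRUE
})

setMethod("show", "ReductionMap", function(object) {
  les <- object@lesionVoxels
  cat("ReductionMap on grid", paste(dim(object@R), collapse = "x"), "with",
      length(les), "lesion voxel(s)\n")
  if (length(les))
    cat("  R range inside lesions: [",
        format(min(object@R[les]), digits = 4), ", ",
        format(max(object@R[les]), digits = 4), "]\n", sep = "")
})

# ---------------------------------------------------------------------------
# Connectome
# ---------------------------------------------------------------------------

#' Connectome: symmetric weighted adjacency matrix over parcellation nodes
#'
#' Edge `(a, b)` stores the connection strength `C_b`, the sum of (possibly
#' lesion-adjusted) streamline weights over streamlines whose endpoints map to
#' nodes `a` and `b`. The `variant` records whether weights were the raw
#' coefficients (`"standard"`) or the weakest-link adjusted ones
#' (`"multicompartment"`).
#'
#' @slot matrix symmetric nonnegative numeric matrix with zero diagonal.
#' @slot variant `"standard"` or `"multicompartment"`.
#' @export
setClass("Connectome",
         slots = c(matrix = "matrix", variant = "character"))

setValidity("Connectome", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12, check.attributes = FALSE)))
    return("matrix must be symmetric")
  if (any(m < 0)) return("edge weights must be nonnegative")
  if (nrow(m) && any(diag(m) != 0)) return("diagonal must be zero")
  if (!object@variant %in% c("standard", "multicompartment"))
    return("variant must be 'standard' or 'multicompartment'")
  TRUE
})

setMethod("show", "Connectome", function(object) {
  m <- object@matrix
  ne <- sum(m[upper.tri(m)] > 0)
  cat("Connectome (", object@variant, "): ", nrow(m), " nodes, ", ne,
      " edges, total strength ", format(sum(m) / 2, digits = 6), "\n", sep = "")
})

#' Strength matrix of a Connectome
#' @param x a [Connectome-class].
#' @return the symmetric numeric adjacency matrix.
#' @export
strengthMatrix <- function(x) {
  if (is(x, "Connectome")) x@matrix else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Variant of a Connectome
#' @param x a [Connectome-class].
#' @return `"standard"` or `"multicompartment"`.
#' @export
connectomeVariant <- function(x) x@variant

#' Number of nodes of a Connectome
#' @param x a [Connectome-class].
#' @export
nNodes <- function(x) nrow(strengthMatrix(x))

# ---------------------------------------------------------------------------
# Phantom
# ---------------------------------------------------------------------------

#' Phantom: synthetic bundle configuration on a voxel grid
#'
#' A phantom emulates the inputs of the pipeline without any imaging data:
#' straight bundles with known true weights, a white-matter mask (the traversed
#' voxels), and an integer parcellation labelling the endpoint voxels. Voxels
#' are isotropic; voxel `(i, j, k)` (0-based) owns the world box
#' `[i, i+1) x [j, j+1) x [k, k+1)` times the voxel size.
#'
#' @slot gridDim integer triple.
#' @slot voxelSize isotropic voxel edge length (mm).
#' @slot wmMask logical 3D array of white-matter voxels.
#' @slot parcellation integer 3D array; 0 = background, labels `1..n` are nodes.
#' @slot bundles list; each element has `streamline` (`n x 3` matrix, world mm)
#'   and `trueWeight` (nonnegative).
#' @export
setClass("Phantom",
         slots = c(gridDim = "integer", voxelSize = "numeric",
                   wmMask = "array", parcellation = "array",
                   bundles = "list"))

setValidity("Phantom", function(object) {
  if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
    return("gridDim must be three positive integers")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    return("voxelSize must be a positive scalar")
  if (!identical(as.integer(dim(object@wmMask)), object@gridDim))
    return("wmMask must match gridDim")
  if (!identical(as.integer(dim(object@parcellation)), object@gridDim))
    return("parcellation must match gridDim")
  p <- object@parcellation
  if (any(p < 0) || any(p != round(p)))
    return("parcellation labels must be nonnegative integers")
  for (b in object@bundles) {
    if (is.null(b$streamline) || is.null(b$trueWeight))
      return("each bundle needs 'streamline' and 'trueWeight'")
    if (b$trueWeight < 0) return("trueWeight must be nonnegative")
    u <- b$streamline / object@voxelSize
    if (any(u < 0) || any(u > rep(object@gridDim, each = nrow(u))))
      return("bundle streamlines must lie inside the grid")
  }
  TRUE
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom: grid", paste(object@gridDim, collapse = "x"),
      sprintf("(%.3g mm voxels),", object@voxelSize),
      length(object@bundles), "bundle(s),",
      sum(object@wmMask), "WM voxel(s),",
      max(object@parcellation), "node(s)\n")
})

#' True bundle weights of a Phantom
#' @param phantom a [Phantom-class].
#' @return numeric vector, one weight per bundle.
#' @export
trueWeights <- function(phantom)
  vapply(phantom@bundles, function(b) b$trueWeight, numeric(1))

#' Tractogram of a Phantom
#'
#' One streamline per bundle, weighted by the true weights.
#' @param phantom a [Phantom-class].
#' @return a [Tractogram-class].
#' @export
tractogram <- function(phantom)
  Tractogram(lapply(phantom@bundles, `[[`, "streamline"),
             weights = trueWeights(phantom))

#' Grid dimensions of a Phantom
#' @param phantom a [Phantom-class].
#' @export
gridDim <- function(phantom) phantom@gridDim

#' Voxel size of a Phantom
#' @param phantom a [Phantom-class].
#' @export
voxelSize <- function(phantom) phantom@voxelSize
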