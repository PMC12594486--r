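# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's stream afterwards. `seed = NULL` means "use the ambient RNG".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as.integer(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# 0-based (i,j,k) voxel triplets -> 1-based linear index, column-major like R
# arrays: v = i + j*nx + k*nx*ny + 1.
voxelIndex <- function(ijk, gridDim) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  as.integer(ijk[, 1L] + gridDim[1L] * (ijk[, 2L] + gridDim[2L] * ijk[, 3L]) + 1L)
}

# Inverse of voxelIndex: 1-based linear index -> 0-based (i,j,k) matrix.
voxelTriplet <- function(v, gridDim) {
  v0 <- as.integer(v) - 1L
  i <- v0 %% gridDim[1L]
  j <- (v0 %/% gridDim[1L]) %% gridDim[2L]
  k <- v0 %/% (gridDim[1L] * gridDim[2L])
  cbind(i, j, k)
}

checkGridDim <- function(gridDim) {
  gridDim <- as.integer(gridDim)
  if (length(gridDim) != 3L || any(is.na(gridDim)) || any(gridDim < 1L))
    stop("'gridDim' must be three positive integers")
  gridDim
}

# Empty n x 0 sparse matrix used for the lesion block of a standard operator.
emptySparse <- function(nrow, ncol = 0L) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(nrow, ncol))
}

# Coerce to dgCMatrix without triggering Matrix's deprecated direct coercions.
asDgc <- function(m) {
  if (is(m, "dgCMatrix")) return(m)
  m <- Matrix::Matrix(m, sparse = TRUE)
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

asLogicalMask <- function(mask, gridDim = NULL) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!is.null(gridDim) && !identical(as.integer(dim(mask)), as.integer(gridDim)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match expected grid ", paste(gridDim, collapse = "x"))
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  mask
}
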