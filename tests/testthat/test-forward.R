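test_that("the crossing-phantom operator has unit entries and column sums 5/3/3", {
  segs <- segmentTable(makeCrossingPhantom()$phantom)
  A <- buildOperator(segs)
  expect_equal(dim(A), c(15L, 3L))
  expect_equal(length(A@x), 11L)
  expect_equal(A@x, rep(1, 11), tolerance = 1e-12)
  expect_equal(as.numeric(Matrix::colSums(A)), c(5, 3, 3), tolerance = 1e-12)
})

test_that("operator assembly handles simple and empty tables", {
  st <- new("SegmentTable", streamline = rep(1L, 3), voxel = 1:3,
            length = rep(1, 3), gridDim = c(3L, 1L, 1L), nStreamlines = 1L)
  expect_equal(as.numeric(buildOperator(st)), c(1, 1, 1))

  empty <- new("SegmentTable", streamline = integer(0), voxel = integer(0),
               length = numeric(0), gridDim = c(2L, 2L, 1L),
               nStreamlines = 2L)
  A0 <- buildOperator(empty)
  expect_equal(dim(A0), c(4L, 2L))
  expect_equal(length(A0@x), 0L)

  # repeated (streamline, voxel) rows are summed
  st2 <- new("SegmentTable", streamline = c(1L, 1L), voxel = c(2L, 2L),
             length = c(0.3, 0.4), gridDim = c(3L, 1L, 1L),
             nStreamlines = 1L)
  expect_equal(buildOperator(st2)[2, 1], 0.7)
})

test_that("lesion augmentation appends one -1 column per pathological voxel", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  A <- buildOperator(segmentTable(ph$phantom))
  op <- augmentWithLesions(A, ph$lesionMask)
  expect_equal(ncol(op@L), 1L)
  expect_equal(op@L[op@lesionVoxels, 1], -1)
  expect_equal(sum(op@L != 0), 1L)

  # empty mask: zero lesion columns, streamline block untouched
  op0 <- augmentWithLesions(A, array(FALSE, dim(ph$lesionMask)))
  expect_equal(ncol(op0@L), 0L)
  expect_identical(op0@A, op@A)

  # multi-voxel mask: columns in ascending voxel order, single -1 each
  mask3 <- array(FALSE, dim(ph$lesionMask))
  mask3[c(1, 7, 12)] <- TRUE
  op3 <- augmentWithLesions(A, mask3)
  expect_equal(op3@lesionVoxels, c(1L, 7L, 12L))
  expect_equal(as.numeric(Matrix::colSums(op3@L != 0)), rep(1, 3))
  expect_true(all(op3@L@x == -1))
})

test_that("the standard fit reproduces the biased crossing-phantom estimates", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  fit <- fitWeights(lesionOperator(segs), ph$signal)

  # independent oracle: the 3x3 normal equations of this phantom
  #   5 x1 + x2 + x3 = 3*0.16 + 2*0.30
  #     x1 + 3 x2    = 0.30 + 0.14 + 0.07
  #     x1 + 3 x3    = 0.30 + 2*0.14
  G <- rbind(c(5, 1, 1), c(1, 3, 0), c(1, 0, 3))
  b <- c(3 * 0.16 + 2 * 0.30, 0.30 + 0.14 + 0.07, 0.30 + 2 * 0.14)
  oracle <- solve(G, b)
  expect_equal(streamlineWeights(fit), oracle, tolerance = 1e-10)
  expect_equal(round(streamlineWeights(fit), 3), c(0.165, 0.115, 0.138))
})

test_that("the augmented fit recovers true weights and the absolute loss", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  op <- lesionOperator(segs, ph$lesionMask)
  fit <- fitWeights(op, ph$signal)
  expect_equal(streamlineWeights(fit), c(0.16, 0.14, 0.14),
               tolerance = 1e-10)
  expect_equal(lesionLosses(fit), 0.07, tolerance = 1e-10)
  expect_lt(fit@objective, 1e-20)

  # healthy phantom, standard fit: exact zero-residual recovery
  phH <- makeCrossingPhantom(lesion = FALSE)
  fitH <- fitWeights(lesionOperator(segs), phH$signal)
  expect_equal(streamlineWeights(fitH), c(0.16, 0.14, 0.14),
               tolerance = 1e-12)
  expect_lt(fitH@objective, 1e-24)

  expect_error(fitWeights(op, ph$signal[1:5]), "does not match")
})

test_that("residual maps flag the lesion under the standard fit only", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  lesionVoxel <- which(ph$lesionMask)

  rmseStd <- residualRmseMap(fitWeights(lesionOperator(segs), ph$signal))
  expect_gt(rmseStd[lesionVoxel], 1e-3)

  rmseAug <- residualRmseMap(
    fitWeights(lesionOperator(segs, ph$lesionMask), ph$signal))
  expect_lt(max(rmseAug), 1e-10)

  # healthy data: all-zero residual either way
  phH <- makeCrossingPhantom(lesion = FALSE)
  expect_lt(max(residualRmseMap(fitWeights(lesionOperator(segs),
                                           phH$signal))), 1e-12)
})

test_that("adding lesion columns never worsens the objective", {
  for (seed in 1:5) {
    rl <- randomLesionedPhantom(seed * 100, damage = 0.5)
    segs <- segmentTable(rl$phantom)
    objStd <- fitWeights(lesionOperator(segs), rl$signal)@objective
    objAug <- fitWeights(lesionOperator(segs, rl$mask), rl$signal)@objective
    expect_lte(objAug, objStd + 1e-12)
  }
})

test_that("at the augmented optimum lesion residuals vanish with xL = excess", {
  rl <- randomLesionedPhantom(300, damage = 0.75)
  segs <- segmentTable(rl$phantom)
  op <- lesionOperator(segs, rl$mask)
  fit <- fitWeights(op, rl$signal)
  predicted <- as.numeric(op@A %*% fit@x)
  les <- op@lesionVoxels
  y <- as.numeric(rl$signal)
  covered <- predicted[les] >= y[les] - 1e-12
  expect_true(all(abs(fit@residual[les][covered]) < 1e-8))
  expect_equal(fit@xL[covered], (predicted[les] - y[les])[covered],
               tolerance = 1e-8)
})

test_that("the NNLS solver agrees with an established reference", {
  skip_if_not_installed("pracma")
  set.seed(99)
  for (k in 1:25) {
    m <- sample(4:10, 1)
    n <- sample(2:6, 1)
    A <- matrix(rnorm(m * n), m, n)
    y <- rnorm(m)
    expect_equal(nnlsSolve(A, y), as.numeric(pracma::lsqnonneg(A, y)$x),
                 tolerance = 1e-8)
  }
  # sparse input path
  As <- Matrix::Matrix(pmax(matrix(rnorm(40), 8, 5), 0), sparse = TRUE)
  y <- rnorm(8)
  expect_equal(nnlsSolve(As, y),
               as.numeric(pracma::lsqnonneg(as.matrix(As), y)$x),
               tolerance = 1e-8)
  expect_error(nnlsSolve(matrix(1, 2, 2), 1:3), "dimension mismatch")
})
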