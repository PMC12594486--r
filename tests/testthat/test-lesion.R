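test_that("the reduction map encodes the surviving signal fraction", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  op <- lesionOperator(segs, ph$lesionMask)
  fit <- fitWeights(op, ph$signal)
  rmap <- reductionMap(fit, op)
  les <- which(ph$lesionMask)
  # predicted 0.14, fitted loss 0.07 -> R = 0.5
  expect_equal(rmap@R[les], 0.5, tolerance = 1e-10)
  expect_true(all(rmap@R[-les] == 1))
})

test_that("reduction map limits: no damage gives 1, full damage gives 0", {
  ph <- makeCrossingPhantom(lesion = FALSE)
  segs <- segmentTable(ph$phantom)
  mask <- array(FALSE, dim(ph$signal)); mask[2, 3, 1] <- TRUE
  op <- lesionOperator(segs, mask)

  # healthy signal through the augmented operator: xL = 0, R = 1
  fit0 <- fitWeights(op, ph$signal)
  expect_equal(lesionLosses(fit0), 0, tolerance = 1e-12)
  expect_true(all(reductionMap(fit0, op)@R == 1))

  # complete axonal damage: R = 0 in the lesion voxel
  dead <- applyDamage(ph$signal, mask, 1)
  fit1 <- fitWeights(op, dead)
  expect_equal(reductionMap(fit1, op)@R[2, 3, 1], 0, tolerance = 1e-10)
})

test_that("a lesioned voxel with no streamline coverage warns and keeps R = 1", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  mask <- ph$lesionMask
  mask[5, 3, 1] <- TRUE                     # untraversed corner voxel
  op <- lesionOperator(segs, mask)
  fit <- fitWeights(op, ph$signal)
  expect_warning(rmap <- reductionMap(fit, op), "no streamline coverage")
  expect_equal(rmap@R[5, 3, 1], 1)
  expect_equal(rmap@R[2, 3, 1], 0.5, tolerance = 1e-10)

  # mismatched fit/operator pairs are rejected
  opOther <- lesionOperator(segs, ph$lesionMask)
  fitOther <- fitWeights(opOther, ph$signal)
  expect_error(reductionMap(fitOther, op), "not produced")
})

test_that("weakest-link adjustment takes the path minimum of R", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  segs <- segmentTable(ph$phantom)
  op <- lesionOperator(segs, ph$lesionMask)
  fit <- fitWeights(op, ph$signal)
  rmap <- reductionMap(fit, op)
  cHat <- adjustWeights(streamlineWeights(fit), segs, rmap)
  # Bundle 2 passes R = (1, 1, 0.5) -> 0.14 * 0.5 = 0.07; others untouched
  expect_equal(cHat, c(0.16, 0.07, 0.14), tolerance = 1e-10)

  # paths outside all lesions and zero weights are fixed points
  expect_equal(adjustWeights(c(0, 0.5, 0), segs, rmap),
               c(0, 0.25, 0), tolerance = 1e-10)
  expect_error(adjustWeights(c(0.1, 0.2), segs, rmap), "one weight per")
})

test_that("empty lesion mask leaves weights and connectomes identical", {
  ph <- makeBundlePhantom(nNodes = 6, nBundles = 8, seed = 13)
  segs <- segmentTable(ph)
  y <- phantomSignal(ph)
  asn <- assignNodes(tractogram(ph), ph@parcellation)

  fitStd <- fitWeights(lesionOperator(segs), y)
  connStd <- buildConnectome(streamlineWeights(fitStd), asn, 6, "standard")

  opAug <- lesionOperator(segs, array(FALSE, gridDim(ph)))
  fitAug <- fitWeights(opAug, y)
  rmap <- reductionMap(fitAug, opAug)
  cHat <- adjustWeights(streamlineWeights(fitAug), segs, rmap)
  connMc <- buildConnectome(cHat, asn, 6, "multicompartment")

  expect_identical(strengthMatrix(connStd), strengthMatrix(connMc))
})

test_that("adjusted weights decrease monotonically with the damage level", {
  rlBase <- randomLesionedPhantom(500, damage = 0)
  segs <- segmentTable(rlBase$phantom)
  op <- lesionOperator(segs, rlBase$mask)
  healthy <- phantomSignal(rlBase$phantom)
  prev <- NULL
  for (d in c(0, 0.25, 0.5, 0.75, 1)) {
    y <- applyDamage(healthy, rlBase$mask, d)
    fit <- fitWeights(op, y)
    cHat <- adjustWeights(streamlineWeights(fit), segs,
                          reductionMap(fit, op))
    expect_true(all(cHat <= streamlineWeights(fit) + 1e-12))
    if (!is.null(prev)) expect_true(all(cHat <= prev + 1e-9))
    prev <- cHat
  }
})

test_that("single-bundle lesions recover R = 1 - d and cHat = c (1 - d)", {
  ph <- makeBundlePhantom(nNodes = 4, nBundles = 2, gridDim = c(8L, 8L, 8L),
                          seed = 31)
  segs <- segmentTable(ph)
  counts <- table(segs@voxel)
  # lesion one voxel traversed by exactly one bundle (not a node voxel)
  exclusive <- as.integer(names(counts)[counts == 1L])
  nodeVox <- which(ph@parcellation > 0)
  target <- setdiff(exclusive, nodeVox)[1]
  mask <- array(FALSE, gridDim(ph)); mask[target] <- TRUE
  bundle <- segs@streamline[segs@voxel == target]

  for (d in c(0.25, 0.6, 1)) {
    y <- applyDamage(phantomSignal(ph), mask, d)
    op <- lesionOperator(segs, mask)
    fit <- fitWeights(op, y)
    rmap <- reductionMap(fit, op)
    expect_equal(rmap@R[target], 1 - d, tolerance = 1e-6)
    cHat <- adjustWeights(streamlineWeights(fit), segs, rmap)
    expect_equal(cHat[bundle], trueWeights(ph)[bundle] * (1 - d),
                 tolerance = 1e-6)
  }
})
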