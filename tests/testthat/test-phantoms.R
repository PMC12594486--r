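test_that("the crossing phantom reproduces the canonical voxel signals", {
  ph <- makeCrossingPhantom(lesion = FALSE)
  segs <- segmentTable(ph$phantom)
  expect_equal(length(unique(segs@voxel)), 9L)

  # shared crossing voxels carry the summed signal 0.30 = 0.16 + 0.14
  expect_equal(ph$signal[2, 1, 1], 0.30, tolerance = 1e-12)
  expect_equal(ph$signal[4, 1, 1], 0.30, tolerance = 1e-12)
  # exclusive voxels carry the owning bundle's weight
  expect_equal(ph$signal[1, 1, 1], 0.16, tolerance = 1e-12)
  expect_equal(ph$signal[2, 2, 1], 0.14, tolerance = 1e-12)
  expect_equal(ph$signal[2, 3, 1], 0.14, tolerance = 1e-12)

  # noiseless forward construction: || A w - y || = 0 exactly
  A <- buildOperator(segs)
  expect_equal(as.numeric(A %*% ph$trueWeights), as.numeric(ph$signal),
               tolerance = 1e-14)
})

test_that("the lesioned crossing phantom halves the lesion voxel signal", {
  ph <- makeCrossingPhantom(lesion = TRUE)
  expect_equal(sum(ph$lesionMask), 1L)
  expect_equal(ph$signal[2, 3, 1], 0.07, tolerance = 1e-12)
  healthy <- makeCrossingPhantom(lesion = FALSE)
  expect_equal(ph$signal[!ph$lesionMask], healthy$signal[!ph$lesionMask])
})

test_that("lesion masks respect coverage, subset and determinism contracts", {
  wm <- array(TRUE, c(20L, 20L, 20L))
  expect_equal(sum(generateLesionMask(wm, 0, seed = 1)), 0L)

  mask <- generateLesionMask(wm, 0.05, seed = 3)
  expect_gte(sum(mask), 0.05 * 8000)
  expect_identical(mask, generateLesionMask(wm, 0.05, seed = 3))

  # masks stay inside irregular WM
  wm2 <- array(FALSE, c(12L, 12L, 12L))
  wm2[3:9, 3:9, 5:7] <- TRUE
  m2 <- generateLesionMask(wm2, 0.1, seed = 9)
  expect_true(all(wm2[m2]))
  expect_gte(sum(m2), 0.1 * sum(wm2))

  expect_error(generateLesionMask(array(FALSE, c(4L, 4L, 4L)), 0.05),
               "empty")
  expect_error(generateLesionMask(wm, 1.5), "targetFraction")
})

test_that("damage scales masked voxels only and is monotone in the fraction", {
  s <- array(0.14, c(2L, 2L, 1L))
  m <- array(c(TRUE, FALSE, FALSE, FALSE), c(2L, 2L, 1L))
  expect_identical(applyDamage(s, m, 0), s)
  expect_equal(applyDamage(s, m, 0.5)[1, 1, 1], 0.07)
  expect_equal(applyDamage(s, m, 1)[1, 1, 1], 0)
  expect_equal(applyDamage(s, m, 0.5)[2, 1, 1], 0.14)

  set.seed(5)
  sig <- array(runif(27), c(3L, 3L, 3L))
  msk <- array(runif(27) < 0.4, c(3L, 3L, 3L))
  prev <- applyDamage(sig, msk, 0)
  for (f in c(0.25, 0.5, 0.75, 1)) {
    cur <- applyDamage(sig, msk, f)
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
  expect_error(applyDamage(sig, array(TRUE, c(2L, 2L, 2L)), 0.5),
               "does not match")
  expect_error(applyDamage(sig, msk, 1.2), "fraction")
})

test_that("random bundle phantoms are identifiable and well-formed", {
  ph <- makeBundlePhantom(nNodes = 6, nBundles = 8, seed = 21)
  expect_s4_class(ph, "Phantom")
  expect_equal(length(ph@bundles), 8L)
  expect_equal(max(ph@parcellation), 6L)
  segs <- segmentTable(ph)
  # every bundle owns at least one exclusive voxel
  perBundle <- split(segs@voxel, segs@streamline)
  counts <- table(segs@voxel)
  for (v in perBundle)
    expect_true(any(counts[as.character(v)] == 1L))
  # WM mask is exactly the traversed voxels
  expect_setequal(which(ph@wmMask), unique(segs@voxel))
})

test_that("cohort synthesis is seeded and degenerates correctly", {
  ph <- makeBundlePhantom(nNodes = 6, nBundles = 8, seed = 21)
  co <- synthesizeCohort(ph, 4, weightCv = 0, damageLevels = 0,
                         lesionFraction = 0, seed = 1)
  base <- phantomSignal(ph)
  for (s in co$subjects) {
    expect_equal(s$weights, trueWeights(ph))
    expect_equal(s$healthySignal, base)
    expect_equal(sum(s$lesionMask), 0L)
  }

  co1 <- synthesizeCohort(ph, 5, weightCv = 0.1, damageLevels = c(0, 0.25),
                          lesionFraction = 0.05, seed = 8)
  co2 <- synthesizeCohort(ph, 5, weightCv = 0.1, damageLevels = c(0, 0.25),
                          lesionFraction = 0.05, seed = 8)
  expect_identical(co1$subjects, co2$subjects)
  wmN <- sum(ph@wmMask)
  for (s in co1$subjects) {
    expect_gte(sum(s$lesionMask), 0.05 * wmN)
    expect_true(all(ph@wmMask[s$lesionMask]))
    # damaged signal never exceeds the healthy one
    expect_true(all(s$signals[["0.25"]] <= s$healthySignal + 1e-15))
  }
  expect_error(synthesizeCohort(ph, 1), "nSubjects")
})
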