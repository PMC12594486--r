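test_that("axis-aligned clipping splits a line into the expected lengths", {
  tr <- traverseStreamline(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)),
                           c(3L, 1L, 1L))
  expect_equal(tr$voxel, 1:3)
  expect_equal(tr$length, c(0.5, 1.0, 0.5))

  vv <- visitedVoxels(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)),
                      c(3L, 1L, 1L))
  expect_equal(vv$voxel, 1:3)
  expect_equal(vv$t, c(0, 0.25, 0.75))
})

test_that("a unit-cube body diagonal yields a single voxel of length sqrt(3)", {
  tr <- traverseStreamline(rbind(c(0, 0, 0), c(1, 1, 1)), c(1L, 1L, 1L))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$length, sqrt(3), tolerance = 1e-12)
})

test_that("per-voxel lengths conserve arc length and match a sampling oracle", {
  set.seed(42)
  grid <- c(10L, 10L, 10L)
  for (rep in 1:5) {
    pts <- randomPolyline(6, grid)
    arc <- sum(sqrt(rowSums(diff(pts)^2)))
    tr <- traverseStreamline(pts, grid)
    expect_equal(sum(tr$length), arc, tolerance = 1e-9)
    oracle <- sampledTraversal(pts, grid, samples = 1e4)
    merged <- merge(tr, oracle, by = "voxel", all = TRUE)
    merged[is.na(merged)] <- 0
    expect_lt(max(abs(merged$length.x - merged$length.y)), 5e-3 * arc)
  }
})

test_that("halving the voxel size preserves total length and nests voxels", {
  set.seed(7)
  pts <- randomPolyline(5, c(8L, 8L, 8L))
  coarse <- traverseStreamline(pts, c(8L, 8L, 8L), voxelSize = 1)
  fine <- traverseStreamline(pts, c(16L, 16L, 16L), voxelSize = 0.5)
  expect_equal(sum(coarse$length), sum(fine$length), tolerance = 1e-9)
  # every fine voxel's parent (integer-halved indices) is a coarse voxel
  f <- fine$voxel - 1L
  fi <- cbind(f %% 16L, (f %/% 16L) %% 16L, f %/% 256L)
  parents <- fi %/% 2L
  parentLin <- parents[, 1] + 8L * (parents[, 2] + 8L * parents[, 3]) + 1L
  expect_true(all(parentLin %in% coarse$voxel))
})

test_that("boundary points follow the half-open rule and re-entry is kept", {
  # line lying exactly on the plane y = 1 -> assigned to the higher voxel row
  tr <- traverseStreamline(rbind(c(0.5, 1, 0.5), c(1.5, 1, 0.5)),
                           c(2L, 2L, 1L))
  expect_equal(sort(tr$voxel), c(3L, 4L))  # y-index 1, not 0

  # a loop re-entering its starting voxel appears twice in the visit order
  loop <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5),
                c(2.5, 1.5, 0.5), c(0.5, 1.5, 0.5), c(0.5, 0.6, 0.5))
  vv <- visitedVoxels(loop, c(3L, 2L, 1L))
  expect_equal(sum(vv$voxel == vv$voxel[1]), 2L)

  # single-voxel streamline: one visit at t = 0
  one <- visitedVoxels(rbind(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8)),
                       c(1L, 1L, 1L))
  expect_equal(one$voxel, 1L)
  expect_equal(one$t, 0)
})

test_that("degenerate inputs are handled per contract", {
  # repeated points are skipped silently
  tr <- traverseStreamline(rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5),
                                 c(1.5, 0.5, 0.5)), c(2L, 1L, 1L))
  expect_equal(tr$length, c(0.5, 0.5))
  # exiting the grid names the offending location
  expect_error(
    traverseStreamline(rbind(c(0.5, 0.5, 0.5), c(4.5, 0.5, 0.5)),
                       c(2L, 1L, 1L)),
    "exits the grid")
  expect_error(traverseStreamline(matrix(c(0.5, 0.5, 0.5), 1, 3),
                                  c(2L, 1L, 1L)),
               "at least 2 points")
})

test_that("a full affine maps world coordinates into voxel space", {
  aff <- diag(c(2, 2, 2, 1))          # 2 mm voxels, corner at origin
  tr <- traverseStreamline(rbind(c(1, 1, 1), c(5, 1, 1)), c(3L, 1L, 1L),
                           affine = aff)
  expect_equal(tr$voxel, 1:3)
  expect_equal(tr$length, c(1, 2, 1))
  expect_error(
    traverseStreamline(rbind(c(1, 1, 1), c(5, 1, 1)), c(3L, 1L, 1L),
                       affine = matrix(0, 4, 4)),
    "not invertible")
})

test_that("segmentTable stacks per-streamline traversals", {
  tg <- Tractogram(list(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5)),
                        rbind(c(0.5, 1.5, 0.5), c(1.5, 1.5, 0.5))))
  st <- segmentTable(tg, c(3L, 2L, 1L))
  expect_s4_class(st, "SegmentTable")
  expect_equal(st@nStreamlines, 2L)
  expect_equal(sort(unique(st@streamline)), 1:2)
  expect_equal(sum(st@length[st@streamline == 1L]), 2)
  expect_equal(sum(st@length[st@streamline == 2L]), 1)
})
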