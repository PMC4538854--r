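test_that("spherical cell matches the brute-force centroid-in-ball count", {
  g <- voxelGrid(c(50, 50, 30))
  cell <- makeSphereCell(g)   # 30 um diameter, h = 3
  # independent enumeration: integer offsets within radius 5 voxels
  off <- expand.grid(i = -6:6, j = -6:6, k = -6:6)
  expected <- sum(off$i^2 + off$j^2 + off$k^2 <= 5^2)
  expect_identical(length(cellVoxels(cell)), expected)
  expect_identical(expected, 515L)
  # nucleus ball: 9 um diameter -> radius 1.5 voxels
  expect_identical(length(nucleusVoxels(cell)),
                   sum(off$i^2 + off$j^2 + off$k^2 <= 1.5^2))
})

test_that("degenerate and out-of-bounds spheres behave as specified", {
  g <- voxelGrid(c(20, 20, 20))
  tiny <- makeSphereCell(g, diameter = 2)   # below voxel size
  expect_identical(length(cellVoxels(tiny)), 1L)
  expect_error(makeSphereCell(g, center = c(0, 0, 0), diameter = 30),
               "margin")
})

test_that("surface of a solid cube is the cube minus its centre", {
  cell <- cubeCell(3L)
  surf <- surfaceVoxels(cell)
  expect_length(surf, 26L)
  expect_setequal(setdiff(cellVoxels(cell), surf),
                  erode6(cell@grid, cellVoxels(cell)))
})

test_that("single-voxel cell is its own surface", {
  g <- voxelGrid(c(10, 10, 10))
  cell <- cellFromIjk(g, rbind(c(5, 5, 5)))
  expect_identical(surfaceVoxels(cell), cellVoxels(cell))
})

test_that("surface equals set minus 6-erosion for random blobs", {
  g <- voxelGrid(c(16, 16, 16))
  for (s in 1:50) {
    vox <- randomBlob(g, 40L, seed = s)
    cell <- new("CellState", grid = g, voxels = vox,
                zones = rep(2L, length(vox)), nucleus = integer(0),
                step = 0L,
                trajectory = matrix(colMeans(voxelCentroids(g, vox)), 1, 3))
    expect_setequal(surfaceVoxels(cell), setdiff(vox, erode6(g, vox)))
  }
})

test_that("candidate additions enumerate boundary pairs", {
  g <- voxelGrid(c(10, 10, 10))
  one <- cellFromIjk(g, rbind(c(5, 5, 5)))
  expect_identical(nrow(candidateAdditions(one)), 6L)
  corner <- cellFromIjk(g, rbind(c(0, 5, 5)))   # at a face boundary
  expect_identical(nrow(candidateAdditions(corner)), 5L)
  bar <- cellFromIjk(g, rbind(c(4, 5, 5), c(5, 5, 5)))   # 2x1x1 bar
  expect_identical(nrow(candidateAdditions(bar)), 10L)
  # pairs always straddle the boundary
  pr <- candidateAdditions(bar)
  expect_true(all(pr[, "parent"] %in% cellVoxels(bar)))
  expect_false(any(pr[, "candidate"] %in% cellVoxels(bar)))
})

test_that("zone classification gives a one-voxel cortex shell and is idempotent", {
  cube <- cubeCell(3L)
  z <- cellZones(cube)
  expect_identical(sum(names(z) == "CORTEX"), 26L)
  expect_identical(sum(names(z) == "CYTOPLASM"), 1L)
  # with the centre voxel as nucleus there is no cytoplasm left
  ctr <- setdiff(cellVoxels(cube), surfaceVoxels(cube))
  cube2 <- cubeCell(3L, nucleus = ctr)
  z2 <- cellZones(cube2)
  expect_identical(sum(names(z2) == "CORTEX"), 26L)
  expect_identical(sum(names(z2) == "NUCLEUS"), 1L)
  expect_identical(sum(names(z2) == "CYTOPLASM"), 0L)
  expect_identical(classifyZones(cube2)@zones, cube2@zones)
  # a 30 um sphere has a one-voxel-thick cortex: eroding the cell removes
  # exactly the cortex
  g <- voxelGrid(c(50, 50, 30))
  sph <- makeSphereCell(g)
  zs <- cellZones(sph)
  inner <- erode6(g, cellVoxels(sph))
  expect_setequal(cellVoxels(sph)[names(zs) == "CORTEX"],
                  setdiff(cellVoxels(sph), union(inner, nucleusVoxels(sph))))
})

test_that("centroid is the unweighted mean of voxel centroids", {
  g <- voxelGrid(c(20, 20, 20))
  sph <- makeSphereCell(g, center = c(30, 30, 30), diameter = 18)
  expect_equal(cellCentroid(sph), c(31.5, 31.5, 31.5))  # snapped centre
  two <- cellFromIjk(g, rbind(c(0, 5, 5), c(2, 5, 5)))
  expect_equal(cellCentroid(two), c(4.5, 16.5, 16.5))
  one <- cellFromIjk(g, rbind(c(3, 3, 3)))
  expect_equal(cellCentroid(one), c(10.5, 10.5, 10.5))
})

test_that("label grid overlays the cell on the matrix background", {
  g <- voxelGrid(c(10, 10, 10))
  cell <- cellFromIjk(g, rbind(c(5, 5, 5)))
  lab <- labelGrid(cell)
  expect_identical(sum(lab != 0L), 1L)
  expect_identical(lab[cellVoxels(cell)], 1L)  # single voxel is cortex
})
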