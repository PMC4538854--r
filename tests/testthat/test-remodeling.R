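test_that("stiffness gradients hit the documented mid-plane values", {
  g <- voxelGrid(c(100, 4, 4))   # 300 um along x
  hom <- buildStiffnessField(g, "homogeneous", E = 50)
  expect_true(all(hom@E == 50))
  lin <- buildStiffnessField(g, "linear", Efrom = 45, Eto = 65)
  x <- voxelCentroids(g)[, 1]
  mid <- abs(x - 150) < 3
  expect_equal(mean(lin@E[mid]), 55, tolerance = 1e-2)
  expect_true(all(lin@E >= 45 - 0.2 & lin@E <= 65 + 0.2))
  ex <- buildStiffnessField(g, "exponential", Efrom = 1, Eto = 100)
  expect_equal(mean(log(ex@E[mid])), log(10), tolerance = 1e-2)
  expect_error(buildStiffnessField(g, "linear", Efrom = -1, Eto = 10),
               "positive")
})

test_that("contact degradation is multiplicative and cumulative", {
  g <- voxelGrid(c(20, 20, 20))
  cell <- makeSphereCell(g, diameter = 12)
  ecm <- buildStiffnessField(g, "homogeneous", E = 50)
  expect_identical(degradeEcm(ecm, cell, 0)@E, ecm@E)
  d1 <- degradeEcm(ecm, cell, 0.01)
  touched <- d1@E < 50
  expect_true(any(touched))
  expect_equal(unique(d1@E[touched]), 49.5)
  # the touched set is exactly the ECM voxels face-adjacent to the cell
  nb <- voxelmig:::.neighbors6(g, cellVoxels(cell))
  ring <- setdiff(unique(nb[!is.na(nb)]), cellVoxels(cell))
  expect_setequal(which(touched), ring)
  # 100 contact steps: E = 50 * 0.99^100
  dn <- ecm
  for (i in 1:100) dn <- degradeEcm(dn, cell, 0.01)
  expect_equal(unique(dn@E[dn@E < 50]), 50 * 0.99^100, tolerance = 1e-10)
  expect_true(all(diff(range(dn@degradation[ring])) < 1e-12))
  # monotone non-increasing everywhere
  expect_true(all(dn@E <= ecm@E + 1e-12))
})

test_that("porous generator hits porosity, determinism and percolation", {
  g <- voxelGrid(c(50, 50, 30))
  cell <- makeSphereCell(g)
  for (seed in 1:3) {
    set.seed(seed)
    ecm <- generatePorousEcm(g, porosity = 0.9, meanPore = 20,
                             cellRegion = cellVoxels(cell), E = 5)
    ach <- attr(ecm, "achievedPorosity")
    expect_gte(ach, 0.88); expect_lte(ach, 0.92)
    expect_true(isTRUE(ecm@porous))
    expect_true(all(ecm@void[cellVoxels(cell)]))
    expect_true(all(ecm@E[!ecm@void] == 5))
    expect_gt(attr(ecm, "meanChord"), 0)
  }
  # determinism under a fixed seed
  set.seed(11); a <- generatePorousEcm(g, 0.9, 20, cellVoxels(cell))
  set.seed(11); b <- generatePorousEcm(g, 0.9, 20, cellVoxels(cell))
  expect_identical(a@void, b@void)
  # porosity 0: fully solid
  set.seed(1)
  solid <- generatePorousEcm(g, 0, 20, NULL)
  expect_true(!any(solid@void))
})

test_that("degradation leaves a softened trail along the trajectory", {
  spec <- scenarioSpec("CASE1_DEGRADE", deskScale = TRUE, steps = 6,
                       replicates = 1, seed = 2)
  run <- suppressWarnings(runScenario(spec))
  # rebuild the field by replaying: instead check the run recorded movement
  # and that a fresh degrade call would have softened the contact ring
  ev <- eventLog(run)
  expect_gt(max(ev$nAdded, na.rm = TRUE), 0)
  # trail: re-run the loop manually and track degraded voxels vs trajectory
  set.seed(2)
  g <- voxelGrid(c(50, 50, 30))
  cell <- makeSphereCell(g)
  ecm <- buildStiffnessField(g, "linear", Efrom = 45, Eto = 65)
  cache <- new.env(parent = emptyenv())
  for (s in 1:6) {
    mech <- suppressWarnings(
      mechanoEquilibrium(cell, ecm, cache = cache, rtol = 1e-4, tol = 0.01))
    cell <- migrationStep(cell, ecm, NULL, mech)$cell
    ecm <- degradeEcm(ecm, cell, 0.01)
  }
  soft <- which(ecm@degradation > 0)
  expect_gt(length(soft), 0)
  # every degraded voxel hugs the swept cell volume: within the largest
  # cell radius (plus one voxel of contact ring) of some visited centroid
  tr <- trajectory(cell)
  rmax <- max(sqrt(rowSums(sweep(voxelCentroids(g, cellVoxels(cell)), 2,
                                 cellCentroid(cell))^2)))
  ctr <- voxelCentroids(g, soft)
  mind <- apply(ctr, 1, function(p)
    min(sqrt(colSums((t(tr) - p)^2))))
  expect_true(all(mind <= rmax + 2 * g@h))
})

test_that("porous mode: candidates are pore voxels, never solid matrix", {
  g <- voxelGrid(c(20, 20, 20))
  set.seed(2)
  cell <- makeSphereCell(g, diameter = 12)
  ecm <- generatePorousEcm(g, porosity = 0.5, meanPore = 12,
                           cellRegion = cellVoxels(cell))
  pr <- candidateAdditions(cell, ecm)
  expect_true(all(ecm@void[pr[, "candidate"]]))
  expect_false(any(pr[, "candidate"] %in% cellVoxels(cell)))
})
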