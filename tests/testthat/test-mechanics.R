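p <- cellMaterialParams()

test_that("mechanosensing law reproduces hand-evaluated values", {
  expect_equal(activeStress1d(-0.4, p, "cytoplasm"), -0.4)
  expect_equal(activeStress1d(0, p, "cytoplasm"), 15 / 5.5 * 0.4,
               tolerance = 1e-12)
  expect_equal(activeStress1d(0.15, p, "cytoplasm"), 1.65)  # peak
  expect_equal(activeStress1d(0.5, p, "cytoplasm"), 0.5)    # pure passive
  # nucleus transmits only passive stress
  expect_equal(activeStress1d(c(-0.2, 0.1), p, "nucleus"), c(-0.2, 0.1))
})

test_that("mechanosensing law is continuous at all branch boundaries", {
  eps <- 1e-9
  for (pp in list(p, cellMaterialParams(Kpas = 2, Kact = 7, epsMin = -0.3,
                                        epsMax = 0.5, sigmaMaxCortex = 3,
                                        sigmaMaxCytoplasm = 2))) {
    for (zone in c("cortex", "cytoplasm")) {
      smax <- pp$sigmaMax[[toupper(zone)]]
      for (b in c(pp$epsMin, smax / pp$Kact, pp$epsMax)) {
        lo <- activeStress1d(b - eps, pp, zone)
        hi <- activeStress1d(b + eps, pp, zone)
        expect_lt(abs(hi - lo), 1e-6)
      }
    }
  }
})

test_that("single-voxel closed form has the free and rigid limits", {
  expect_equal(singleVoxelOracle(0, p), 0)
  expect_equal(singleVoxelOracle(1e6, p), 15 / 5.5 * 0.4, tolerance = 1e-4)
  # monotone non-decreasing, saturating over the biological range
  E <- c(0.1, 0.5, 1, 5, 10, 50, 100, 1000)
  s <- singleVoxelOracle(E, p)
  expect_true(all(diff(s) > 0))
  # saturation: the late increments are much smaller than the early ones
  expect_lt(s[8] - s[6], 0.1 * (s[3] - s[1]))
})

test_that("zero eigenstress gives identically zero displacement", {
  g <- voxelGrid(c(8, 8, 8))
  sol <- assembleAndSolve(g, E = 10, nu = 0.3)
  expect_equal(max(abs(sol$displacements)), 0)
})

test_that("a single contractile voxel pulls the matrix inward, decaying", {
  n <- 15
  g <- voxelGrid(c(n, n, n))
  N <- nVoxels(g)
  mid <- n %/% 2
  cvox <- mid * n * n + mid * n + mid + 1L
  sig <- matrix(0, N, 3); sig[cvox, ] <- 1
  sol <- assembleAndSolve(g, E = 10, nu = 0.3, eigenstress = sig,
                          rtol = 1e-9)
  U <- sol$displacements
  ctr <- (c(mid, mid, mid) + 0.5) * g@h
  nodes <- as.matrix(expand.grid(x = 0:n, y = 0:n, z = 0:n)) * g@h
  rel <- sweep(nodes, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  inward <- rowSums(U * rel)
  expect_true(all(inward[r > 0] <= 1e-12))   # all point toward the voxel
  # magnitude decays with distance (inner vs outer node shells)
  m2 <- mean(sqrt(rowSums(U[r > 4.5 & r < 5.5, ]^2)))
  m4 <- mean(sqrt(rowSums(U[r > 9 & r < 10.5, ]^2)))
  expect_gt(m2, 2 * m4)
})

test_that("FE mechanosensing equilibrium matches the closed form within 5%", {
  n <- 15
  g <- voxelGrid(c(n, n, n))
  N <- nVoxels(g)
  mid <- n %/% 2
  cvox <- mid * n * n + mid * n + mid + 1L
  for (E in c(0.1, 1, 5, 10, 50, 100, 1000)) {
    Ev <- rep(E, N); nuv <- rep(0.3, N)
    Ev[cvox] <- p$Kpas; nuv[cvox] <- 0
    sigAct <- rep(voxelmig:::.actuatorStress(0, p, "cytoplasm"), 3)
    ctx <- NULL; u0 <- NULL; st <- NULL
    for (it in 1:300) {
      es <- matrix(0, N, 3); es[cvox, ] <- sigAct
      sol <- assembleAndSolve(g, Ev, nuv, eigenstress = es, rtol = 1e-9,
                              u0 = u0, context = ctx)
      ctx <- sol$context; u0 <- sol$u
      eps <- voxelmig:::.vm_fe_strains(ctx$ptr, sol$u, cvox)
      st <- activeStress1d(as.vector(eps), p, rep("cytoplasm", 3))
      new <- st - p$Kpas * as.vector(eps)
      if (max(abs(new - sigAct)) < 1e-9) break
      sigAct <- sigAct + 0.3 * (new - sigAct)
    }
    expect_equal(mean(st), singleVoxelOracle(E, p), tolerance = 0.05)
  }
})

test_that("sphere equilibrium: cortex stress exceeds cytoplasm stress", {
  g <- voxelGrid(c(50, 50, 30))
  cell <- makeSphereCell(g)
  ecm <- buildStiffnessField(g, "homogeneous", E = 50)
  mech <- mechanoEquilibrium(cell, ecm, p)
  z <- cellZones(cell)
  sv <- volumetricStress(mech)
  expect_gt(mean(sv[names(z) == "CORTEX"]), mean(sv[names(z) == "CYTOPLASM"]))
  # volumetric stress is the mean of the axial stresses
  expect_equal(sv, rowMeans(mech@sigma))
  expect_equal(sqrt(sum(maxStressDir(mech)^2)), 1)
  # tightening the solver tolerance barely moves the cortex mean
  mech2 <- mechanoEquilibrium(cell, ecm, p, tol = 5e-4, rtol = 1e-8)
  c1 <- mean(sv[names(z) == "CORTEX"])
  c2 <- mean(volumetricStress(mech2)[names(z) == "CORTEX"])
  expect_lt(abs(c1 - c2) / c1, 1e-3)
})

test_that("max-stress direction follows the hottest voxel with index ties", {
  g <- voxelGrid(c(10, 10, 10))
  ijk <- rbind(c(3, 5, 5), c(4, 5, 5), c(5, 5, 5))
  cell <- cellFromIjk(g, ijk)
  sv <- c(0.1, 0.1, 0.9)   # max at +x end
  ms <- maxStressDirection(sv, cell)
  expect_equal(ms$dir, c(1, 0, 0))
  # tie: smallest linear index (the -x voxel) wins
  ms2 <- maxStressDirection(c(0.9, 0.1, 0.9), cell)
  expect_equal(ms2$dir, c(-1, 0, 0))
  # degenerate: maximum at the centroid voxel falls back to prev
  ms3 <- maxStressDirection(c(0.1, 0.9, 0.1), cell, prev = c(0, 1, 0))
  expect_equal(ms3$dir, c(0, 1, 0))
})
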