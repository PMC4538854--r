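test_that("analytic fields give a linear profile and uniform flow", {
  g <- voxelGrid(c(100, 5, 5))   # 300 um along x
  env <- analyticFields(g, c(1, 0, 0), Cin = 1, Cout = 0)
  x <- voxelCentroids(g)[, 1]
  expect_equal(env@C, 1 - x / 300, tolerance = 1e-12)
  # concentration drop across one 3-um voxel on a 300-um domain
  expect_equal(env@dCref, 0.01)
  expect_true(all(env@flowDir[, 1] == 1))
  # gradient along y only
  gy <- voxelGrid(c(5, 100, 5))
  envy <- analyticFields(gy, c(0, 1, 0))
  expect_equal(diff(range(envy@C[voxelmig:::.ijk(gy, 1:nVoxels(gy))[, 2] == 50])), 0)
  # equal boundary values: flat field
  flat <- analyticFields(g, c(1, 0, 0), Cin = 1, Cout = 1)
  expect_equal(diff(range(flat@C)), 0)
})

test_that("Darcy solve is exact for a homogeneous gel", {
  g <- voxelGrid(c(50, 4, 4))   # L = 150 um
  pars <- transportParams()     # kappa 1e-13 m^2, mu 1e-3 Pa s
  env <- solveDarcy(g, pars, axis = "x", pIn = 40, pOut = 0)
  # linear pressure drop
  x <- voxelCentroids(g)[, 1]
  expect_equal(env@pressure, 40 * (1 - x / 150), tolerance = 1e-8)
  # |u| = kappa dP / (mu L); with L = 1.5 mm this is ~2.67 um/s, here
  # the domain is 10x shorter so 10x faster
  uref <- 1e-13 * 40 / (1e-3 * 150e-6) * 1e6
  expect_equal(unique(round(env@speed, 9)), round(uref, 9))
  expect_true(all(env@flowDir[, 1] == 1))
  # doubling the permeability doubles the speed
  env2 <- solveDarcy(g, pars, kappa = rep(2e-13, nVoxels(g)), axis = "x")
  expect_equal(env2@speed, 2 * env@speed, tolerance = 1e-10)
})

test_that("Darcy solve fails without a conducting path", {
  g <- voxelGrid(c(10, 4, 4))
  k <- rep(1e-13, nVoxels(g))
  k[voxelmig:::.ijk(g, 1:nVoxels(g))[, 1] == 5] <- NA  # blocking wall
  expect_error(solveDarcy(g, transportParams(), kappa = k),
               "conducting path|singular")
})

test_that("steady advection-diffusion matches the 1-D closed form", {
  n <- 100
  g <- voxelGrid(c(n, 3, 3), h = 3)
  pars <- transportParams(D = 1e-9)
  L <- n * 3e-6                      # m
  for (pe in c(0, 2, 5)) {
    u <- pe * pars$D / L * 1e6       # um/s giving the target Peclet
    vel <- cbind(rep(u, nVoxels(g)), 0, 0)
    C <- solveAdvectionDiffusion(g, vel, pars, Cin = 1, Cout = 0)
    x <- (voxelCentroids(g)[, 1] * 1e-6) / L
    cref <- if (pe == 0) 1 - x else (exp(pe * x) - exp(pe)) / (1 - exp(pe))
    expect_lt(max(abs(C - cref)), 0.02)
    # discrete maximum principle: bounded by the boundary values
    expect_true(all(C <= 1 + 1e-12 & C >= -1e-12))
  }
})

test_that("strong advection triggers the Peclet accuracy warning", {
  g <- voxelGrid(c(20, 3, 3))
  vel <- cbind(rep(1000, nVoxels(g)), 0, 0)
  expect_warning(solveAdvectionDiffusion(g, vel, transportParams()),
                 "Peclet")
})

test_that("environment fields are frozen during migration", {
  g <- voxelGrid(c(40, 40, 30))
  env <- analyticFields(g, c(1, 0, 0))
  before <- list(env@C, env@flowDir, env@speed)
  set.seed(7)
  cell <- makeSphereCell(g, diameter = 18)
  ecm <- buildStiffnessField(g, "homogeneous", E = 50)
  mech <- mechanoEquilibrium(cell, ecm)
  st <- migrationStep(cell, ecm, env, mech,
                      dynamicsParams(useChemical = TRUE, useFlow = TRUE))
  expect_identical(list(env@C, env@flowDir, env@speed), before)
})
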