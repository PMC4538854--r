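#' @include dynamics.R transport.R remodeling.R metrics.R
NULL

.SCENARIOS <- c("HOMOG50", "CASE1_LINEAR", "CASE2_EXP", "CASE1_DEGRADE",
                "MIG_A", "MIG_B", "MIG_C", "MIG_D", "MIG_E", "POROUS")

#' Scenario specification
#'
#' Pure-data description of one named experiment: domain, step count, which
#' stimulus factors are active, gradient axes, replicate count and base seed.
#' The named scenarios map to the documented factor/gradient combinations:
#' \describe{
#'   \item{HOMOG50}{homogeneous 50 kPa ECM, mechanical factors only.}
#'   \item{CASE1_LINEAR / MIG_A}{linear stiffness gradient 45-65 kPa along x,
#'     mechanical factors only.}
#'   \item{CASE2_EXP}{exponential gradient 1-100 kPa along x, mechanical.}
#'   \item{CASE1_DEGRADE}{as CASE1_LINEAR with contact degradation (d=0.01).}
#'   \item{MIG_B}{uniform flow along x only.}
#'   \item{MIG_C}{flow and chemical gradient along x.}
#'   \item{MIG_D}{flow along x, linear stiffness gradient along y.}
#'   \item{MIG_E}{flow and chemical gradient along x, stiffness gradient
#'     along y.}
#'   \item{POROUS}{random porous matrix (porosity ~0.9, mean pore ~20 um,
#'     solid 5 kPa), flow along x.}
#' }
#'
#' @param id scenario name (see above).
#' @param domain domain size in um (default 300 x 300 x 120; the desk-scale
#'   setting uses 150 x 150 x 90).
#' @param h voxel size (um).
#' @param steps number of migration steps (default 100; dt = 5 min).
#' @param dt step duration (min).
#' @param replicates number of replicates (seeds \code{seed + 0:(r-1)}).
#' @param seed base seed.
#' @param deskScale use the reduced 150 x 150 x 90 um domain.
#' @param cellDiameter,nucleusDiameter initial cell geometry (um).
#' @param margin mechanics window padding (voxels).
#' @param degradeFraction contact degradation fraction per step (scenarios
#'   with degradation active).
#' @param overrides named list overriding any \code{\link{dynamicsParams}} or
#'   \code{\link{cellMaterialParams}} argument.
#' @return list of class \code{ScenarioSpec}.
#' @examples
#' spec <- scenarioSpec("HOMOG50", deskScale = TRUE, steps = 5,
#'                      replicates = 1)
#' @export
scenarioSpec <- function(id, domain = c(300, 300, 120), h = 3, steps = 100L,
                         dt = 5, replicates = 1L, seed = 1L,
                         deskScale = FALSE, cellDiameter = 30,
                         nucleusDiameter = 9, margin = 4L,
                         degradeFraction = 0.01, overrides = list()) {
  id <- match.arg(id, .SCENARIOS)
  if (deskScale) domain <- c(150, 150, 90)
  factors <- switch(id,
    HOMOG50 = , CASE1_LINEAR = , CASE2_EXP = , CASE1_DEGRADE = , MIG_A =
      c(stress = TRUE, stressDir = TRUE, chemical = FALSE, flow = FALSE),
    MIG_B = c(stress = FALSE, stressDir = FALSE, chemical = FALSE,
              flow = TRUE),
    MIG_C = c(stress = FALSE, stressDir = FALSE, chemical = TRUE,
              flow = TRUE),
    MIG_D = c(stress = TRUE, stressDir = TRUE, chemical = FALSE,
              flow = TRUE),
    MIG_E = c(stress = TRUE, stressDir = TRUE, chemical = TRUE, flow = TRUE),
    POROUS = c(stress = TRUE, stressDir = TRUE, chemical = FALSE,
               flow = TRUE))
  stiffness <- switch(id,
    HOMOG50 = , MIG_B = , MIG_C = list(kind = "homogeneous", E = 50),
    CASE1_LINEAR = , CASE1_DEGRADE = , MIG_A =
      list(kind = "linear", Efrom = 45, Eto = 65, axis = "x"),
    CASE2_EXP = list(kind = "exponential", Efrom = 1, Eto = 100, axis = "x"),
    MIG_D = , MIG_E = list(kind = "linear", Efrom = 45, Eto = 65,
                           axis = "y"),
    POROUS = list(kind = "porous", E = 5, porosity = 0.9, meanPore = 20))
  structure(list(id = id, domain = domain, h = h, steps = as.integer(steps),
                 dt = dt, replicates = as.integer(replicates),
                 seed = as.integer(seed), deskScale = deskScale,
                 cellDiameter = cellDiameter,
                 nucleusDiameter = nucleusDiameter,
                 margin = as.integer(margin), factors = factors,
                 stiffness = stiffness,
                 degrade = id == "CASE1_DEGRADE",
                 degradeFraction = degradeFraction,
                 needsEnv = factors[["chemical"]] || factors[["flow"]],
                 overrides = overrides),
            class = "ScenarioSpec")
}

.applyOverrides <- function(fn, overrides) {
  args <- overrides[names(overrides) %in% names(formals(fn))]
  do.call(fn, args)
}

#' Run a migration scenario
#'
#' Builds the environment fields and the initial spherical cell, then loops
#' mechanics, the stochastic shape update, and (optionally) ECM degradation
#' for the requested number of steps and replicates. Replicates differ only
#' by seed; a fixed seed reproduces the run bit for bit.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param verbose print per-replicate progress.
#' @return A \linkS4class{MigrationRun}.
#' @export
runScenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  grid <- voxelGrid(round(spec$domain / spec$h), spec$h)
  cellP <- .applyOverrides(cellMaterialParams, spec$overrides)
  dynBase <- spec$overrides[names(spec$overrides) %in%
                              names(formals(dynamicsParams))]
  dynP <- do.call(dynamicsParams, c(dynBase, list(
    dt = spec$dt,
    useStress = spec$factors[["stress"]],
    useStressDir = spec$factors[["stressDir"]],
    useChemical = spec$factors[["chemical"]],
    useFlow = spec$factors[["flow"]])))
  events <- vector("list", spec$replicates)
  cells <- vector("list", spec$replicates)
  seeds <- spec$seed + seq_len(spec$replicates) - 1L
  for (rep in seq_len(spec$replicates)) {
    set.seed(seeds[rep])
    cell <- makeSphereCell(grid, diameter = spec$cellDiameter,
                           nucleusDiameter = spec$nucleusDiameter)
    if (identical(spec$stiffness$kind, "porous")) {
      ecm <- generatePorousEcm(grid, porosity = spec$stiffness$porosity,
                               meanPore = spec$stiffness$meanPore,
                               cellRegion = cellVoxels(cell),
                               E = spec$stiffness$E)
    } else {
      ecm <- do.call(buildStiffnessField, c(list(grid = grid),
                                            spec$stiffness))
    }
    # concentration increases along +x so the chemotactic drive points in
    # the +x "applied gradient" direction, matching the flow direction
    env <- if (spec$needsEnv)
      analyticFields(grid, c(1, 0, 0), Cin = 0, Cout = 1) else NULL
    cache <- new.env(parent = emptyenv())
    ctr <- cellCentroid(cell)
    log <- data.frame(step = 0L, time = 0, nAdded = NA_integer_,
                      nRemoved = NA_integer_, nOrphaned = NA_integer_,
                      x = ctr[1], y = ctr[2], z = ctr[3],
                      nVoxels = length(cellVoxels(cell)),
                      meanSigmaV = NA_real_, maxDisp = NA_real_,
                      shapeFactor = shapeFactor(cell),
                      spreadArea = spreadArea(cell))
    truncated <- FALSE
    # with both stress factors disabled the mechanical solution cannot
    # influence the trajectory (it enters only through those factors), so
    # the solve is skipped and stress outputs are not recorded
    needMech <- spec$factors[["stress"]] || spec$factors[["stressDir"]]
    for (s in seq_len(spec$steps)) {
      mech <- if (needMech)
        mechanoEquilibrium(cell, ecm, cellP, margin = spec$margin,
                           cache = cache, rtol = 2e-4, tol = 0.03)
      else new("MechSolution", window = matrix(0L, 2L, 3L),
               displacements = matrix(0, 1L, 3L),
               eps = matrix(0, 0L, 3L), sigma = matrix(0, 0L, 3L),
               sigmaV = rep(0, length(cellVoxels(cell))),
               dDsigma = c(1, 0, 0), maxVoxel = cellVoxels(cell)[1L],
               iterations = 0L)
      st <- tryCatch(migrationStep(cell, ecm, env, mech, dynP, cellP),
                     error = function(e) e)
      if (inherits(st, "error")) {
        # a fragmentation event stripped the cell to its nucleus: keep the
        # trajectory recorded so far and stop this replicate
        warning(sprintf("%s replicate %d truncated at step %d: %s",
                        spec$id, rep, s, conditionMessage(st)))
        truncated <- TRUE
        break
      }
      cell <- st$cell
      if (spec$degrade) ecm <- degradeEcm(ecm, cell, spec$degradeFraction)
      ctr <- cellCentroid(cell)
      log <- rbind(log, data.frame(
        step = s, time = s * spec$dt, nAdded = st$nAdded,
        nRemoved = st$nRemoved, nOrphaned = st$nOrphaned,
        x = ctr[1], y = ctr[2], z = ctr[3],
        nVoxels = length(cellVoxels(cell)),
        meanSigmaV = if (needMech) mean(volumetricStress(mech)) else NA_real_,
        maxDisp = if (needMech) attr(mech, "maxEcmDisp") else NA_real_,
        shapeFactor = shapeFactor(cell), spreadArea = spreadArea(cell)))
    }
    attr(log, "truncated") <- truncated
    events[[rep]] <- log
    cells[[rep]] <- cell
    if (verbose)
      message(sprintf("%s replicate %d/%d: %d voxels, centroid (%.1f, %.1f, %.1f)",
                      spec$id, rep, spec$replicates,
                      length(cellVoxels(cell)), ctr[1], ctr[2], ctr[3]))
  }
  new("MigrationRun", scenario = unclass(spec), events = events,
      cells = cells, seeds = as.integer(seeds))
}

#' Ensemble summary over replicates
#'
#' @param run a \linkS4class{MigrationRun}.
#' @param tEnd evaluate speeds up to this time (min).
#' @return list with \code{mean}, \code{sd} (named vectors over the metrics)
#'   and the per-replicate table. The standard deviation of a single run
#'   is 0 by convention.
#' @export
replicateSummary <- function(run, tEnd = NULL) {
  tab <- trajectoryMetrics(run, tEnd)
  metr <- tab[, c("Vm", "Veff", "backwardFraction", "shapeFactor",
                  "spreadArea")]
  sds <- apply(metr, 2L, function(x) if (length(x) > 1L) sd(x) else 0)
  list(mean = colMeans(metr), sd = sds, perRun = tab)
}
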