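#' @include voxelmig-package.R
NULL

# Integer label codes shared across the package (x-fastest linear indexing)
.LABEL <- c(ECM = 0L, CORTEX = 1L, CYTOPLASM = 2L, NUCLEUS = 3L, VOID = 4L)

#' Regular voxel lattice
#'
#' A box-shaped lattice of cubic voxels. Voxel \code{(i, j, k)} (0-based) has
#' its centroid at \code{origin + ((i, j, k) + 0.5) * h}; linear indices are
#' 1-based with x fastest.
#'
#' @slot dims integer(3), voxel counts per axis.
#' @slot h voxel edge length (micrometres).
#' @slot origin numeric(3), position of the lattice corner (micrometres).
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", h = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("dims must be three positive integers")
    if (length(object@h) != 1L || object@h <= 0)
      return("voxel size h must be a single positive number")
    if (length(object@origin) != 3L) return("origin must be length 3")
    TRUE
  })

#' State of the migrating cell
#'
#' The set of voxels currently occupied by the cell, their zone assignment
#' (cortex / cytoplasm / nucleus), the rigid nucleus ball, and the centroid
#' trajectory accumulated over migration steps.
#'
#' @slot grid the \linkS4class{VoxelGrid} the cell lives on.
#' @slot voxels integer, sorted linear indices of cell voxels.
#' @slot zones integer, zone code per cell voxel (parallel to \code{voxels}).
#' @slot nucleus integer, linear indices of the nucleus ball.
#' @slot step integer step counter.
#' @slot trajectory numeric matrix, one centroid row (micrometres) per step,
#'   \code{step + 1} rows.
#' @export
setClass("CellState",
  representation(grid = "VoxelGrid", voxels = "integer", zones = "integer",
                 nucleus = "integer", step = "integer", trajectory = "matrix"),
  validity = function(object) {
    if (length(object@voxels) == 0L) return("cell voxel set is empty")
    if (is.unsorted(object@voxels)) return("cell voxels must be sorted")
    if (length(object@zones) != length(object@voxels))
      return("zones must parallel voxels")
    if (!all(object@nucleus %in% object@voxels))
      return("nucleus voxels must be cell voxels")
    if (nrow(object@trajectory) != object@step + 1L)
      return("trajectory must have step + 1 rows")
    TRUE
  })

#' Extracellular-matrix material field
#'
#' Per-voxel Young's modulus (kPa) with a global Poisson ratio, the cumulative
#' degradation fraction, and (in porous mode) the pore-space mask. Migratable
#' space is ECM in continuum mode and pore voxels in porous mode.
#'
#' @slot E numeric, per-voxel Young's modulus (kPa).
#' @slot E0 numeric, undegraded modulus (kPa).
#' @slot nu single numeric, ECM Poisson ratio.
#' @slot degradation numeric, per-voxel cumulative degradation fraction.
#' @slot void logical, per-voxel pore mask (porous mode), or length 0.
#' @slot porous logical flag.
#' @export
setClass("EcmField",
  representation(E = "numeric", E0 = "numeric", nu = "numeric",
                 degradation = "numeric", void = "logical", porous = "logical"),
  validity = function(object) {
    if (any(object@E < 0)) return("E must be non-negative")
    if (object@nu < 0 || object@nu >= 0.5) return("nu must be in [0, 0.5)")
    TRUE
  })

#' Chemical and interstitial-flow environment
#'
#' Steady per-voxel concentration, flow direction, flow speed and pressure on
#' the lattice. Computed once before migration and held fixed.
#'
#' @slot C numeric, concentration per voxel (mol/m^3).
#' @slot flowDir numeric matrix (n x 3), unit flow direction per voxel.
#' @slot speed numeric, flow speed per voxel (um/s).
#' @slot pressure numeric, pressure per voxel (Pa), may be length 0.
#' @slot Cmax single numeric, maximum concentration of the species.
#' @slot dCref single numeric, reference adjacent-voxel concentration
#'   difference used to normalize the chemotactic factor.
#' @export
setClass("EnvFields",
  representation(C = "numeric", flowDir = "matrix", speed = "numeric",
                 pressure = "numeric", Cmax = "numeric", dCref = "numeric"),
  prototype(C = numeric(0), flowDir = matrix(0, 0, 3), speed = numeric(0),
            pressure = numeric(0), Cmax = 1, dCref = 1))

# constructor avoiding new()'s partial matching of the `C` slot onto `Class`
.envFields <- function(C, flowDir, speed, pressure, Cmax, dCref) {
  obj <- new("EnvFields")
  obj@C <- C; obj@flowDir <- flowDir; obj@speed <- speed
  obj@pressure <- pressure; obj@Cmax <- Cmax; obj@dCref <- dCref
  obj
}

#' Mechanical equilibrium solution
#'
#' Result of one coupled mechanosensing solve: nodal displacements on the
#' computational window, per-cell-voxel directional strains and active
#' stresses, the volumetric stress, and the direction of maximum stress.
#'
#' @slot window integer matrix (2 x 3): first/last voxel (1-based, inclusive)
#'   of the computational window along each axis.
#' @slot displacements numeric matrix (window nodes x 3), micrometres.
#' @slot eps numeric matrix (n_cell x 3), axial cell strains.
#' @slot sigma numeric matrix (n_cell x 3), transmitted stresses (kPa).
#' @slot sigmaV numeric, volumetric stress per cell voxel (kPa).
#' @slot dDsigma numeric(3), unit direction of maximum stress.
#' @slot maxVoxel integer, linear index of the maximum-stress voxel.
#' @slot iterations integer, fixed-point iterations used.
#' @export
setClass("MechSolution",
  representation(window = "matrix", displacements = "matrix", eps = "matrix",
                 sigma = "matrix", sigmaV = "numeric", dDsigma = "numeric",
                 maxVoxel = "integer", iterations = "integer"))

#' A completed migration simulation
#'
#' Holds the scenario configuration, one event log per replicate and the final
#' cell states. Replicates differ only by seed.
#'
#' @slot scenario list, the scenario configuration (pure data).
#' @slot events list of data.frames, one per replicate: per-step event counts,
#'   centroid, mean volumetric stress, shape metrics.
#' @slot cells list of final \linkS4class{CellState} objects.
#' @slot seeds integer, seed used for each replicate.
#' @export
setClass("MigrationRun",
  representation(scenario = "list", events = "list", cells = "list",
                 seeds = "integer"))
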