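#' @include AllClasses.R
NULL

#' @describeIn voxelGrid Number of voxels in the lattice.
#' @export
nVoxels <- function(grid) prod(grid@dims)

#' Accessors for lattice and cell objects
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setMethod("gridDims", "VoxelGrid", function(x) x@dims)
#' @rdname accessors
#' @export
setMethod("gridDims", "CellState", function(x) x@grid@dims)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@h)
#' @rdname accessors
#' @export
setMethod("voxelSize", "CellState", function(x) x@grid@h)

#' @rdname accessors
#' @export
setGeneric("cellVoxels", function(x) standardGeneric("cellVoxels"))
#' @rdname accessors
#' @export
setMethod("cellVoxels", "CellState", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("cellZones", function(x) standardGeneric("cellZones"))
#' @rdname accessors
#' @export
setMethod("cellZones", "CellState", function(x)
  setNames(x@zones, names(.LABEL)[match(x@zones, .LABEL)]))

#' @rdname accessors
#' @export
setGeneric("nucleusVoxels", function(x) standardGeneric("nucleusVoxels"))
#' @rdname accessors
#' @export
setMethod("nucleusVoxels", "CellState", function(x) x@nucleus)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x, ...) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setMethod("trajectory", "CellState", function(x, ...) x@trajectory)
#' @rdname accessors
#' @param replicate which replicate (for runs).
#' @export
setMethod("trajectory", "MigrationRun", function(x, replicate = 1L, ...) {
  ev <- x@events[[replicate]]
  as.matrix(ev[, c("x", "y", "z")])
})

#' @rdname accessors
#' @export
setGeneric("volumetricStress", function(x) standardGeneric("volumetricStress"))
#' @rdname accessors
#' @export
setMethod("volumetricStress", "MechSolution", function(x) x@sigmaV)

#' @rdname accessors
#' @export
setGeneric("maxStressDir", function(x) standardGeneric("maxStressDir"))
#' @rdname accessors
#' @export
setMethod("maxStressDir", "MechSolution", function(x) x@dDsigma)

#' @rdname accessors
#' @export
setGeneric("eventLog", function(x, ...) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setMethod("eventLog", "MigrationRun", function(x, replicate = 1L, ...)
  x@events[[replicate]])

setMethod("show", "VoxelGrid", function(object) {
  d <- object@dims
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, h = %g um (%g x %g x %g um)\n",
              d[1], d[2], d[3], object@h,
              d[1] * object@h, d[2] * object@h, d[3] * object@h))
})

setMethod("show", "CellState", function(object) {
  z <- table(factor(names(.LABEL)[match(object@zones, .LABEL)],
                    levels = c("CORTEX", "CYTOPLASM", "NUCLEUS")))
  ctr <- colMeans(voxelCentroids(object@grid, object@voxels))
  cat(sprintf(
    "CellState: %d voxels (%d cortex, %d cytoplasm, %d nucleus), step %d\n",
    length(object@voxels), z[["CORTEX"]], z[["CYTOPLASM"]], z[["NUCLEUS"]],
    object@step))
  cat(sprintf("  centroid: (%.1f, %.1f, %.1f) um\n", ctr[1], ctr[2], ctr[3]))
})

setMethod("show", "MechSolution", function(object) {
  cat(sprintf(
    "MechSolution: %d cell voxels, mean sigma_v = %.3f kPa, %d iterations\n",
    length(object@sigmaV), mean(object@sigmaV), object@iterations))
  cat(sprintf("  d_dsigma = (%.2f, %.2f, %.2f), peak |u| = %.3f um\n",
              object@dDsigma[1], object@dDsigma[2], object@dDsigma[3],
              max(sqrt(rowSums(object@displacements^2)))))
})

setMethod("show", "MigrationRun", function(object) {
  cat(sprintf("MigrationRun: scenario %s, %d replicate(s), %d steps\n",
              object@scenario$id, length(object@events),
              object@scenario$steps))
})
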