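#' @include AllClasses.R
NULL

#' Create a voxel lattice
#'
#' @param dims integer(3): voxel counts along x, y, z.
#' @param h voxel edge length in micrometres (default 3).
#' @param origin lattice corner position in micrometres.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- voxelGrid(c(50, 50, 30))
#' nVoxels(g)
#' @export
voxelGrid <- function(dims, h = 3, origin = c(0, 0, 0)) {
  new("VoxelGrid", dims = as.integer(dims), h = as.numeric(h),
      origin = as.numeric(origin))
}

## ---- lattice index helpers (1-based linear indices, x fastest) ----

.ijk <- function(grid, idx) {
  d <- grid@dims
  v0 <- idx - 1L
  i <- v0 %% d[1L]
  j <- (v0 %/% d[1L]) %% d[2L]
  k <- v0 %/% (d[1L] * d[2L])
  cbind(i, j, k)  # 0-based
}

.lin <- function(grid, ijk) {
  d <- grid@dims
  as.integer(ijk[, 3L] * (d[1L] * d[2L]) + ijk[, 2L] * d[1L] + ijk[, 1L] + 1L)
}

#' Voxel centroid coordinates
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param idx linear voxel indices (default: all voxels).
#' @return Matrix (length(idx) x 3) of centroid positions in micrometres.
#' @export
voxelCentroids <- function(grid, idx = seq_len(nVoxels(grid))) {
  ijk <- .ijk(grid, idx)
  out <- sweep((ijk + 0.5) * grid@h, 2L, grid@origin, "+")
  dimnames(out) <- NULL
  out
}

# 6-neighbour linear indices; NA outside the lattice. Returns n x 6 matrix in
# the order +x, -x, +y, -y, +z, -z.
.neighbors6 <- function(grid, idx) {
  d <- grid@dims
  ijk <- .ijk(grid, idx)
  n <- length(idx)
  out <- matrix(NA_integer_, n, 6L)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(6L)) {
    nb <- sweep(ijk, 2L, shifts[s, ], "+")
    ok <- nb[, 1L] >= 0L & nb[, 1L] < d[1L] &
          nb[, 2L] >= 0L & nb[, 2L] < d[2L] &
          nb[, 3L] >= 0L & nb[, 3L] < d[3L]
    out[ok, s] <- .lin(grid, nb[ok, , drop = FALSE])
  }
  out
}

# unit step direction of neighbour slot s (matches .neighbors6 column order)
.faceDirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.ballVoxels <- function(grid, center, radius) {
  # voxels whose centroid lies within `radius` um of `center`
  h <- grid@h
  d <- grid@dims
  lo <- pmax(floor((center - grid@origin - radius) / h), 0)
  hi <- pmin(ceiling((center - grid@origin + radius) / h), d - 1)
  if (any(hi < lo)) return(integer(0))
  box <- as.matrix(expand.grid(i = lo[1L]:hi[1L], j = lo[2L]:hi[2L],
                               k = lo[3L]:hi[3L]))
  ctr <- sweep((box + 0.5) * h, 2L, grid@origin, "+")
  keep <- rowSums(sweep(ctr, 2L, center)^2) <= radius^2
  sort(.lin(grid, box[keep, , drop = FALSE]))
}

.occupancy <- function(grid, voxels) {
  occ <- logical(nVoxels(grid))
  occ[voxels] <- TRUE
  occ
}

## ---- cell construction and surface operations ----

#' Create an initially spherical cell
#'
#' All voxels whose centroid lies within \code{diameter/2} of \code{center}
#' become cell voxels; the inner ball of \code{nucleusDiameter/2} is the
#' (rigid, passive) nucleus. The sphere must fit with at least a 5-voxel ECM
#' margin on every side so the fixed domain boundary does not interfere with
#' mechanosensing.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param center sphere centre in micrometres (default: domain centre).
#' @param diameter cell diameter in micrometres (default 30).
#' @param nucleusDiameter nucleus diameter in micrometres (default 9).
#' @return A \linkS4class{CellState} with zones assigned.
#' @examples
#' g <- voxelGrid(c(50, 50, 30))
#' cell <- makeSphereCell(g)
#' length(cellVoxels(cell))
#' @export
makeSphereCell <- function(grid, center = NULL, diameter = 30,
                           nucleusDiameter = 9) {
  extent <- grid@dims * grid@h
  if (is.null(center)) center <- grid@origin + extent / 2
  # snap to the nearest voxel centroid so the digital sphere is symmetric
  center <- grid@origin +
    (floor((center - grid@origin) / grid@h) + 0.5) * grid@h
  margin <- 5 * grid@h
  r <- diameter / 2
  rel <- center - grid@origin
  if (any(rel - r < margin) || any(extent - rel - r < margin))
    stop("cell sphere does not fit in the domain with a 5-voxel ECM margin")
  vox <- .ballVoxels(grid, center, r)
  if (length(vox) == 0L) {  # diameter below voxel size: voxel containing center
    ijk <- floor((center - grid@origin) / grid@h)
    vox <- .lin(grid, rbind(ijk))
  }
  nuc <- intersect(.ballVoxels(grid, center, nucleusDiameter / 2), vox)
  cell <- new("CellState", grid = grid, voxels = vox,
              zones = rep(.LABEL[["CYTOPLASM"]], length(vox)),
              nucleus = as.integer(nuc), step = 0L,
              trajectory = matrix(colMeans(voxelCentroids(grid, vox)), 1L, 3L))
  classifyZones(cell)
}

#' Surface voxels of the cell
#'
#' Cell voxels with at least one of their six face neighbours outside the
#' cell (ECM or pore space). Out-of-domain faces do not count.
#'
#' @param cell a \linkS4class{CellState}.
#' @return Sorted integer vector of linear voxel indices.
#' @export
surfaceVoxels <- function(cell) {
  occ <- .occupancy(cell@grid, cell@voxels)
  nb <- .neighbors6(cell@grid, cell@voxels)
  free <- matrix(FALSE, nrow(nb), 6L)
  inb <- !is.na(nb)
  free[inb] <- !occ[nb[inb]]
  cell@voxels[rowSums(free) > 0L]
}

#' Candidate voxel additions
#'
#' All face-adjacent (cell voxel, free neighbour) pairs where the neighbour
#' belongs to the migratable space: ECM voxels in continuum mode, pore (void)
#' voxels in porous mode. Candidates outside the lattice are dropped.
#'
#' @param cell a \linkS4class{CellState}.
#' @param ecm an \linkS4class{EcmField}, or NULL for all-ECM surroundings.
#' @return Integer matrix with columns \code{parent}, \code{candidate},
#'   \code{face} (neighbour slot 1..6).
#' @export
candidateAdditions <- function(cell, ecm = NULL) {
  grid <- cell@grid
  occ <- .occupancy(grid, cell@voxels)
  nb <- .neighbors6(grid, cell@voxels)
  ok <- !is.na(nb)
  ok[ok] <- !occ[nb[ok]]
  if (!is.null(ecm) && isTRUE(ecm@porous)) {
    # migratable space is the pore network
    ok[ok] <- ecm@void[nb[ok]]
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(parent = cell@voxels[idx[, 1L]],
        candidate = nb[idx],
        face = idx[, 2L])
}

#' Assign cortex / cytoplasm / nucleus zones
#'
#' The cortex is the set of cell voxels with at least one non-cell face
#' neighbour (the surface shell) excluding the nucleus; remaining cell voxels
#' are cytoplasm. The nucleus set itself is never altered here. A warning is
#' raised if a nucleus voxel is exposed to non-cell space (the stepping
#' routine re-centres the nucleus).
#'
#' @param cell a \linkS4class{CellState}.
#' @return The cell with updated zone codes (idempotent).
#' @export
classifyZones <- function(cell) {
  surf <- surfaceVoxels(cell)
  zones <- rep(.LABEL[["CYTOPLASM"]], length(cell@voxels))
  zones[cell@voxels %in% surf] <- .LABEL[["CORTEX"]]
  isnuc <- cell@voxels %in% cell@nucleus
  if (any(cell@nucleus %in% surf))
    warning("nucleus voxel exposed to non-cell space; will be re-centred")
  zones[isnuc] <- .LABEL[["NUCLEUS"]]
  cell@zones <- as.integer(zones)
  cell
}

#' Geometric cell centroid
#'
#' Unweighted mean of the member voxel centroids, in micrometres.
#'
#' @param cell a \linkS4class{CellState}.
#' @return numeric(3).
#' @export
cellCentroid <- function(cell) {
  if (length(cell@voxels) == 0L) stop("cell has no voxels")
  colMeans(voxelCentroids(cell@grid, cell@voxels))
}

# Largest 6-connected component of `voxels` containing the seed set;
# used after stochastic removal to keep the cell simply connected.
.connectedTo <- function(grid, voxels, seeds) {
  d <- grid@dims
  keep <- .vm_component(d[1L], d[2L], d[3L], as.integer(voxels),
                        as.integer(seeds))
  voxels[keep[voxels]]
}

#' Full label grid
#'
#' Combines the ECM / pore background with the current cell: per-voxel codes
#' 0 = ECM, 1 = cortex, 2 = cytoplasm, 3 = nucleus, 4 = void.
#'
#' @param cell a \linkS4class{CellState}.
#' @param ecm an \linkS4class{EcmField} or NULL.
#' @return Integer vector of length \code{nVoxels(grid)}.
#' @export
labelGrid <- function(cell, ecm = NULL) {
  lab <- rep(.LABEL[["ECM"]], nVoxels(cell@grid))
  if (!is.null(ecm) && isTRUE(ecm@porous)) lab[ecm@void] <- .LABEL[["VOID"]]
  lab[cell@voxels] <- cell@zones
  lab
}
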