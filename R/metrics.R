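#' @include domain.R
NULL

.trajMatrix <- function(traj) {
  if (is(traj, "CellState")) traj@trajectory
  else if (is(traj, "MigrationRun")) trajectory(traj)
  else as.matrix(traj)
}

#' Mean migration speed
#'
#' Average over steps of the per-step centroid displacement divided by the
#' step duration, up to \code{tEnd}.
#'
#' @param traj a trajectory matrix (rows = centroids, um), a
#'   \linkS4class{CellState} or a \linkS4class{MigrationRun}.
#' @param dt step duration (min).
#' @param tEnd evaluate up to this time (min); default full trajectory.
#' @return Speed in um/min.
#' @examples
#' tr <- cbind(seq(0, 10), 0, 0)   # 1 um per step
#' meanSpeed(tr, dt = 5)           # 0.2
#' @export
meanSpeed <- function(traj, dt = 5, tEnd = NULL) {
  m <- .trajMatrix(traj)
  if (nrow(m) < 2L) stop("need at least two centroids")
  ns <- nrow(m) - 1L
  if (!is.null(tEnd)) ns <- min(ns, floor(tEnd / dt))
  if (ns < 1L) return(0)
  steps <- diff(m[seq_len(ns + 1L), , drop = FALSE])
  mean(sqrt(rowSums(steps^2))) / dt
}

#' Effective migration speed
#'
#' Net start-to-end centroid displacement over the elapsed time.
#'
#' @inheritParams meanSpeed
#' @return Speed in um/min.
#' @export
effectiveSpeed <- function(traj, dt = 5, tEnd = NULL) {
  m <- .trajMatrix(traj)
  if (nrow(m) < 2L) stop("need at least two centroids")
  ns <- nrow(m) - 1L
  if (!is.null(tEnd)) ns <- min(ns, floor(tEnd / dt))
  if (ns < 1L) stop("tEnd must cover at least one step")
  sqrt(sum((m[ns + 1L, ] - m[1L, ])^2)) / (ns * dt)
}

#' Migration directionality
#'
#' Per-step turn angles relative to a reference axis and the fraction of
#' steps moving backward (negative component along the axis). Zero-length
#' steps are skipped.
#'
#' @inheritParams meanSpeed
#' @param axis reference direction (default +x).
#' @return list with \code{angles} (degrees) and \code{backwardFraction}.
#' @export
directionality <- function(traj, axis = c(1, 0, 0)) {
  m <- .trajMatrix(traj)
  axis <- axis / sqrt(sum(axis^2))
  steps <- diff(m)
  len <- sqrt(rowSums(steps^2))
  steps <- steps[len > 0, , drop = FALSE]
  len <- len[len > 0]
  if (length(len) == 0L)
    return(list(angles = numeric(0), backwardFraction = NA_real_))
  ca <- as.vector(steps %*% axis) / len
  list(angles = acos(pmin(pmax(ca, -1), 1)) * 180 / pi,
       backwardFraction = mean(as.vector(steps %*% axis) < 0))
}

#' Cell shape factor (aspect ratio)
#'
#' Square root of the ratio of the largest to the smallest principal second
#' moment of the voxel-centroid cloud, with the per-voxel \code{h^2/12}
#' correction so a single voxel gives exactly 1.
#'
#' @param cell a \linkS4class{CellState}.
#' @return Dimensionless ratio >= 1.
#' @export
shapeFactor <- function(cell) {
  xyz <- voxelCentroids(cell@grid, cell@voxels)
  if (nrow(xyz) == 1L) return(1)
  m <- cov(xyz) * (nrow(xyz) - 1) / nrow(xyz) +
    diag(3) * cell@grid@h^2 / 12
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev))
}

#' Exposed cell surface area
#'
#' Number of cell-voxel faces exposed to non-cell space (including the domain
#' boundary) times the voxel face area (9 um^2 at the default 3 um voxel).
#' Optionally the projected x-y footprint area instead.
#'
#' @param cell a \linkS4class{CellState}.
#' @param method "faces" (default) or "projected".
#' @return Area in um^2.
#' @examples
#' g <- voxelGrid(c(20, 20, 20))
#' cell <- makeSphereCell(g, diameter = 2)  # single voxel
#' spreadArea(cell)                         # 54
#' @export
spreadArea <- function(cell, method = c("faces", "projected")) {
  method <- match.arg(method)
  if (method == "projected") {
    ijk <- .ijk(cell@grid, cell@voxels)
    return(nrow(unique(ijk[, 1:2, drop = FALSE])) * cell@grid@h^2)
  }
  occ <- .occupancy(cell@grid, cell@voxels)
  nb <- .neighbors6(cell@grid, cell@voxels)
  exposed <- is.na(nb)
  exposed[!is.na(nb)] <- !occ[nb[!is.na(nb)]]
  sum(exposed) * cell@grid@h^2
}

#' Per-replicate trajectory metrics
#'
#' @param run a \linkS4class{MigrationRun}.
#' @param tEnd evaluate speeds up to this time (min).
#' @return data.frame with one row per replicate: mean speed, effective
#'   speed, backward fraction, final shape factor and spread area.
#' @export
trajectoryMetrics <- function(run, tEnd = NULL) {
  dt <- run@scenario$dt
  do.call(rbind, lapply(seq_along(run@events), function(r) {
    tr <- trajectory(run, r)
    if (nrow(tr) < 2L)  # zero-step run: speeds 0 by convention
      return(data.frame(replicate = r, Vm = 0, Veff = 0,
                        backwardFraction = NA_real_,
                        shapeFactor = shapeFactor(run@cells[[r]]),
                        spreadArea = spreadArea(run@cells[[r]])))
    data.frame(replicate = r,
               Vm = meanSpeed(tr, dt, tEnd),
               Veff = effectiveSpeed(tr, dt, tEnd),
               backwardFraction = directionality(tr)$backwardFraction,
               shapeFactor = shapeFactor(run@cells[[r]]),
               spreadArea = spreadArea(run@cells[[r]]))
  }))
}
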