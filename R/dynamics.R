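#' @include mechanics.R
NULL

#' Probability-law parameters
#'
#' Constants of the voxel addition/removal probability
#' \code{p = p0 + pMax * (1 - exp(-k0 * (sum lambda_i F_i) * dt))}, for both
#' event signs, with per-factor sensitivity constants and enable switches.
#'
#' @param p0Add,p0Rem minimum probabilities.
#' @param pMaxAdd,pMaxRem probability ranges (p0 + pMax <= 1).
#' @param k0Add,k0Rem temporal rates (1/min).
#' @param lamSigmaAdd,lamSigmaRem stress-magnitude sensitivities.
#' @param lamDsigmaAdd,lamDsigmaRem stress-direction sensitivities.
#' @param lamCAdd,lamCRem chemical sensitivities.
#' @param lamFAdd,lamFRem flow sensitivities.
#' @param dt time step (min).
#' @param useStress,useStressDir,useChemical,useFlow factor switches.
#' @param chemNorm normalization of the chemotactic factor:
#'   \code{"gradient"} (reference = maximum adjacent-voxel concentration
#'   difference over the domain, so the factor spans [0, 1] for a uniform
#'   gradient) or \code{"cmax"} (reference = maximum concentration).
#' @param repellent flip the chemotactic response.
#' @return list of class \code{DynamicsParams}.
#' @examples
#' p <- dynamicsParams()
#' probability(c(1, 1, 1, 1), p, "add")  # ~0.471
#' @export
dynamicsParams <- function(p0Add = 0.1, p0Rem = 0.1, pMaxAdd = 0.8,
                           pMaxRem = 0.4, k0Add = 0.4, k0Rem = 0.4,
                           lamSigmaAdd = 0.0035, lamSigmaRem = 0.0035,
                           lamDsigmaAdd = 0.004, lamDsigmaRem = 0.004,
                           lamCAdd = 0.3, lamCRem = 0.3,
                           lamFAdd = 0.004, lamFRem = 0.004,
                           dt = 5,
                           useStress = TRUE, useStressDir = TRUE,
                           useChemical = FALSE, useFlow = FALSE,
                           chemNorm = c("gradient", "cmax"),
                           repellent = FALSE) {
  stopifnot(p0Add >= 0, p0Rem >= 0, p0Add + pMaxAdd <= 1,
            p0Rem + pMaxRem <= 1, dt > 0)
  structure(list(p0 = c(add = p0Add, rem = p0Rem),
                 pMax = c(add = pMaxAdd, rem = pMaxRem),
                 k0 = c(add = k0Add, rem = k0Rem),
                 lamSigma = c(add = lamSigmaAdd, rem = lamSigmaRem),
                 lamDsigma = c(add = lamDsigmaAdd, rem = lamDsigmaRem),
                 lamC = c(add = lamCAdd, rem = lamCRem),
                 lamF = c(add = lamFAdd, rem = lamFRem),
                 dt = dt,
                 use = c(stress = useStress, stressDir = useStressDir,
                         chemical = useChemical, flow = useFlow),
                 chemNorm = match.arg(chemNorm),
                 repellent = repellent),
            class = "DynamicsParams")
}

#' Stress-magnitude stimulus factor
#'
#' For addition, \code{(sigma_v / sigma_max) * cos(theta)} when the candidate
#' direction is within 90 degrees of the maximum-stress direction, else 0;
#' for removal, \code{(sigma_v / sigma_max) * |sin(theta)|} beyond 90
#' degrees, else 0. \code{sigma_v} is clipped to \code{[0, sigma_max]}.
#'
#' @param sigmaV voxel volumetric stress (kPa).
#' @param sigmaMax peak cell stress (kPa).
#' @param theta angle to the maximum-stress direction (radians).
#' @param sign "add" or "rem".
#' @return Factor in [0, 1] (vectorized).
#' @export
factorStress <- function(sigmaV, sigmaMax, theta, sign = c("add", "rem")) {
  sign <- match.arg(sign)
  ratio <- pmin(pmax(sigmaV, 0), sigmaMax) / sigmaMax
  if (sign == "add") ifelse(theta < pi / 2, ratio * cos(theta), 0)
  else ifelse(theta < pi / 2, 0, ratio * abs(sin(theta)))
}

#' Stress-direction (polarization) stimulus factor
#'
#' @inheritParams factorStress
#' @return Factor in [0, 1].
#' @export
factorStressGradient <- function(theta, sign = c("add", "rem")) {
  sign <- match.arg(sign)
  if (sign == "add") ifelse(theta < pi / 2, cos(theta), 0)
  else ifelse(theta < pi / 2, 0, abs(sin(theta)))
}

#' Chemotactic stimulus factor
#'
#' Adjacent-voxel concentration difference normalized by a reference value:
#' positive differences favour addition, negative ones favour removal (signs
#' flip for a repellent species).
#'
#' @param dC concentration difference (candidate minus current for addition;
#'   voxel minus cell-centroid voxel for removal).
#' @param Cref normalizing reference (mol/m^3).
#' @param sign "add" or "rem".
#' @param repellent flip the response.
#' @return Factor in [0, 1].
#' @export
factorChemical <- function(dC, Cref, sign = c("add", "rem"),
                           repellent = FALSE) {
  sign <- match.arg(sign)
  if (repellent) dC <- -dC
  r <- pmin(abs(dC) / Cref, 1)
  if (sign == "add") ifelse(dC > 0, r, 0) else ifelse(dC < 0, r, 0)
}

#' Flow-alignment stimulus factor
#'
#' Identical in form to the stress-direction factor but measured against the
#' local flow direction.
#'
#' @param phi angle to the flow direction (radians).
#' @param sign "add" or "rem".
#' @return Factor in [0, 1].
#' @export
factorFlow <- function(phi, sign = c("add", "rem")) {
  factorStressGradient(phi, sign)
}

#' Voxel event probability
#'
#' The cumulative-form probability law combining the four stimulus factors.
#' Disabled factors contribute zero regardless of their value.
#'
#' @param factors numeric(4) or an n x 4 matrix: columns F_sigma, F_dsigma,
#'   F_C, F_F (each in [0, 1]).
#' @param params a \code{\link{dynamicsParams}} object.
#' @param sign "add" or "rem".
#' @return Probability in \code{[p0, p0 + pMax]}.
#' @export
probability <- function(factors, params, sign = c("add", "rem")) {
  sign <- match.arg(sign)
  if (is.null(dim(factors))) factors <- matrix(factors, ncol = 4L)
  s <- substr(sign, 1, 3)
  u <- params$use
  expo <- (if (u[["stress"]]) params$lamSigma[[s]] * factors[, 1L] else 0) +
    (if (u[["stressDir"]]) params$lamDsigma[[s]] * factors[, 2L] else 0) +
    (if (u[["chemical"]]) params$lamC[[s]] * factors[, 3L] else 0) +
    (if (u[["flow"]]) params$lamF[[s]] * factors[, 4L] else 0)
  params$p0[[s]] + params$pMax[[s]] * (1 - exp(-params$k0[[s]] * expo *
                                                 params$dt))
}

# angle between rows of unit matrix `a` and unit vector or matrix `b`
.angleTo <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 3L, byrow = TRUE)
  d <- rowSums(a * b)
  acos(pmin(pmax(d, -1), 1))
}

#' Advance the cell one time step
#'
#' From a frozen snapshot of the current shape: every candidate ECM (or, in
#' porous mode, pore) voxel adjacent to the cell receives one addition trial,
#' its probability computed from the most stressed adjacent surface voxel
#' (angles measured between the candidate offset and the maximum-stress and
#' flow directions, concentration difference candidate minus parent); every
#' non-nucleus surface voxel receives one removal trial (angles measured
#' between the centroid-to-voxel direction and the same references).
#' Additions win conflicts. The largest 6-connected component containing the
#' nucleus is kept (orphans revert to matrix), the nucleus ball re-snaps to
#' the new centroid, zones are re-classified and the centroid is appended to
#' the trajectory.
#'
#' Random variates are drawn with R's generator in sorted-candidate order, so
#' a fixed seed reproduces the step exactly.
#'
#' @param cell a \linkS4class{CellState}.
#' @param ecm an \linkS4class{EcmField}.
#' @param env an \linkS4class{EnvFields} (may be NULL when chemical and flow
#'   factors are disabled).
#' @param mech the current \linkS4class{MechSolution}.
#' @param params a \code{\link{dynamicsParams}} object.
#' @param cellParams a \code{\link{cellMaterialParams}} object (for
#'   sigma_max per zone).
#' @return list with the updated \code{cell}, and an event summary
#'   (\code{nAdded}, \code{nRemoved}, \code{nOrphaned}).
#' @export
migrationStep <- function(cell, ecm, env, mech, params = dynamicsParams(),
                          cellParams = cellMaterialParams()) {
  grid <- cell@grid
  ctr <- cellCentroid(cell)
  dDs <- mech@dDsigma
  zoneName <- .zoneName(cell@zones)
  smax <- unname(cellParams$sigmaMax[zoneName])
  smax[smax <= 0] <- cellParams$sigmaMax[["CYTOPLASM"]]
  sv <- mech@sigmaV
  Cref <- if (!is.null(env) && params$chemNorm == "cmax") env@Cmax
          else if (!is.null(env)) env@dCref else 1

  ## ---- additions: one trial per unique candidate voxel ----
  pairs <- candidateAdditions(cell, ecm)
  add <- integer(0)
  if (nrow(pairs) > 0L) {
    # parent = adjacent surface voxel with maximal sigma_v (deterministic)
    psv <- sv[match(pairs[, "parent"], cell@voxels)]
    ord <- order(pairs[, "candidate"], -psv, pairs[, "parent"])
    pr <- pairs[ord, , drop = FALSE]
    first <- !duplicated(pr[, "candidate"])
    pr <- pr[first, , drop = FALSE]
    psv <- psv[ord][first]
    dirs <- .faceDirs[pr[, "face"], , drop = FALSE]
    theta <- .angleTo(dirs, dDs)
    pidx <- match(pr[, "parent"], cell@voxels)
    Fs <- factorStress(psv, smax[pidx], theta, "add")
    Fd <- factorStressGradient(theta, "add")
    if (!is.null(env)) {
      phi <- .angleTo(dirs, env@flowDir[pr[, "parent"], , drop = FALSE])
      dC <- env@C[pr[, "candidate"]] - env@C[pr[, "parent"]]
      Fc <- factorChemical(dC, Cref, "add", params$repellent)
      Ff <- factorFlow(phi, "add")
    } else { Fc <- Ff <- numeric(nrow(pr)) }
    p <- probability(cbind(Fs, Fd, Fc, Ff), params, "add")
    o2 <- order(pr[, "candidate"])        # fixed draw order
    u <- runif(nrow(pr))
    add <- pr[o2, "candidate"][u < p[o2]]
  }

  ## ---- removals: one trial per non-nucleus surface voxel ----
  surf <- setdiff(surfaceVoxels(cell), cell@nucleus)
  rem <- integer(0)
  if (length(surf) > 0L) {
    offs <- voxelCentroids(grid, surf) - matrix(ctr, length(surf), 3L,
                                                byrow = TRUE)
    nrm <- sqrt(rowSums(offs^2)); nrm[nrm == 0] <- 1
    dirs <- offs / nrm
    theta <- .angleTo(dirs, dDs)
    sidx <- match(surf, cell@voxels)
    Fs <- factorStress(sv[sidx], smax[sidx], theta, "rem")
    Fd <- factorStressGradient(theta, "rem")
    if (!is.null(env)) {
      phi <- .angleTo(dirs, env@flowDir[surf, , drop = FALSE])
      ctrVox <- .lin(grid, rbind(pmin(pmax(floor((ctr - grid@origin) /
                                                   grid@h), 0),
                                      grid@dims - 1L)))
      dC <- env@C[surf] - env@C[ctrVox]
      Fc <- factorChemical(dC, Cref, "rem", params$repellent)
      Ff <- factorFlow(phi, "rem")
    } else { Fc <- Ff <- numeric(length(surf)) }
    p <- probability(cbind(Fs, Fd, Fc, Ff), params, "rem")
    u <- runif(length(surf))              # surf is sorted
    rem <- surf[u < p]
  }
  rem <- setdiff(rem, add)                # addition wins

  ## ---- apply, repair connectivity, re-snap nucleus ----
  newSet <- sort(union(setdiff(cell@voxels, rem), add))
  kept <- .connectedTo(grid, newSet, cell@nucleus)
  nOrphan <- length(newSet) - length(kept)
  if (length(kept) <= length(cell@nucleus))
    stop("cell reduced to its nucleus: simulation aborted at step ",
         cell@step + 1L)
  newCtr <- colMeans(voxelCentroids(grid, kept))
  # nucleus ball re-snapped to the voxel centroid nearest the new centroid
  nucCtr <- voxelCentroids(grid,
                           .lin(grid, rbind(pmin(pmax(floor((newCtr -
                             grid@origin) / grid@h), 0), grid@dims - 1L))))
  oldNucCtr <- colMeans(voxelCentroids(grid, cell@nucleus))
  nucR <- max(sqrt(rowSums(sweep(voxelCentroids(grid, cell@nucleus), 2L,
                                 oldNucCtr)^2)))
  nuc <- .ballVoxels(grid, nucCtr[1L, ], max(nucR, grid@h / 2) + 1e-9)
  kept <- sort(union(kept, nuc))
  out <- new("CellState", grid = grid, voxels = as.integer(kept),
             zones = rep(.LABEL[["CYTOPLASM"]], length(kept)),
             nucleus = as.integer(nuc), step = cell@step + 1L,
             trajectory = rbind(cell@trajectory,
                                colMeans(voxelCentroids(grid, kept))))
  out <- suppressWarnings(classifyZones(out))
  d <- grid@dims
  ijk <- .ijk(grid, out@voxels)
  if (any(ijk == 0L) || any(sweep(ijk, 2L, d - 1L) == 0L))
    warning("cell touches the domain boundary frame")
  list(cell = out, nAdded = length(add), nRemoved = length(rem),
       nOrphaned = nOrphan)
}
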