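#' @include domain.R
NULL

#' Cell material parameters
#'
#' The two-spring mechanosensing idealization: actin stiffness \code{Kact} and
#' passive cytoskeleton stiffness \code{Kpas} act per axis, with an acto-myosin
#' actuator whose transmitted stress peaks at \code{sigmaMax} (higher at the
#' cortex than in the cytoplasm) and vanishes outside the strain interval
#' \code{[epsMin, epsMax]}. The nucleus is purely passive.
#'
#' @param Kpas passive stiffness (kPa).
#' @param Kact actin stiffness (kPa).
#' @param epsMin,epsMax minimum / maximum cell strain (dimensionless).
#' @param sigmaMaxCortex,sigmaMaxCytoplasm peak actuator stress (kPa).
#' @return A list of class \code{CellMaterialParams}.
#' @export
cellMaterialParams <- function(Kpas = 1, Kact = 10, epsMin = -0.4,
                               epsMax = 0.4, sigmaMaxCortex = 2.5,
                               sigmaMaxCytoplasm = 1.5) {
  stopifnot(Kpas > 0, Kact > 0, epsMin < 0,
            sigmaMaxCortex / Kact < epsMax, sigmaMaxCytoplasm / Kact < epsMax)
  structure(list(Kpas = Kpas, Kact = Kact, epsMin = epsMin, epsMax = epsMax,
                 sigmaMax = c(CORTEX = sigmaMaxCortex,
                              CYTOPLASM = sigmaMaxCytoplasm,
                              NUCLEUS = 0)),
            class = "CellMaterialParams")
}

.zoneName <- function(zone) {
  if (is.numeric(zone)) names(.LABEL)[match(zone, .LABEL)] else toupper(zone)
}

#' One-dimensional mechanosensing stress
#'
#' Piecewise stress transmitted to the matrix by a cell voxel along one axis
#' as a function of its strain: pure passive resistance below \code{epsMin}
#' and above \code{epsMax}, and actuator branches rising to the peak at
#' \code{sigmaMax/Kact} in between. Nucleus voxels transmit only their passive
#' stress.
#'
#' @param eps cell strain (vectorized).
#' @param params a \code{\link{cellMaterialParams}} object.
#' @param zone "cortex", "cytoplasm" or "nucleus" (or label codes),
#'   vectorized.
#' @return Stress in kPa.
#' @examples
#' p <- cellMaterialParams()
#' activeStress1d(0, p, "cytoplasm")      # ~1.091 kPa
#' activeStress1d(0.15, p, "cytoplasm")   # peak, 1.65 kPa
#' @export
activeStress1d <- function(eps, params, zone) {
  zone <- .zoneName(zone)
  n <- max(length(eps), length(zone))
  eps <- rep_len(eps, n); zone <- rep_len(zone, n)
  smax <- unname(params$sigmaMax[zone])
  Kp <- params$Kpas; Ka <- params$Kact
  e1 <- params$epsMin; e2 <- params$epsMax
  out <- Kp * eps  # passive branches and the nucleus
  act <- zone != "NUCLEUS"
  mid1 <- act & eps > e1 & eps <= smax / Ka
  mid2 <- act & eps > smax / Ka & eps < e2
  out[mid1] <- Ka * smax[mid1] / (Ka * e1 - smax[mid1]) *
    (e1 - eps[mid1]) + Kp * eps[mid1]
  out[mid2] <- Ka * smax[mid2] / (Ka * e2 - smax[mid2]) *
    (e2 - eps[mid2]) + Kp * eps[mid2]
  out
}

# actuator-only part (total minus passive), entering the FE solve as an
# element eigenstress
.actuatorStress <- function(eps, params, zone) {
  activeStress1d(eps, params, zone) - params$Kpas * eps
}

# derivative of the actuator stress wrt strain (piecewise constant)
.actuatorSlope <- function(eps, params, zone) {
  zone <- .zoneName(zone)
  n <- max(length(eps), length(zone))
  eps <- rep_len(eps, n); zone <- rep_len(zone, n)
  smax <- unname(params$sigmaMax[zone])
  Ka <- params$Kact; e1 <- params$epsMin; e2 <- params$epsMax
  out <- numeric(n)
  act <- zone != "NUCLEUS"
  mid1 <- act & eps > e1 & eps <= smax / Ka
  mid2 <- act & eps > smax / Ka & eps < e2
  out[mid1] <- -Ka * smax[mid1] / (Ka * e1 - smax[mid1])
  out[mid2] <- -Ka * smax[mid2] / (Ka * e2 - smax[mid2])
  out
}

#' Closed-form single-voxel mechanosensing solution
#'
#' Theoretical transmitted stress of one contracting cell voxel completely
#' surrounded by elastic ECM of modulus \code{E}: the mechanosensing element
#' in series with a matrix confinement spring proportional to \code{E}. The
#' proportionality constant \code{5.26/(1 + nu)} is the stiffness of a cubic
#' cavity in a large elastic lattice under uniform per-axis contraction
#' (about 2.6 times the spherical-cavity value \code{2E/(1+nu)}; see the
#' methods vignette). Solved by bisection on the compatibility equation to
#' 1e-10.
#'
#' @param E ECM Young's modulus (kPa), vectorized.
#' @param params a \code{\link{cellMaterialParams}} object.
#' @param zone cell zone for the voxel (default cytoplasm).
#' @param nu ECM Poisson ratio.
#' @return Transmitted stress in kPa (0 at E = 0; the rigid-limit plateau as
#'   E grows).
#' @examples
#' p <- cellMaterialParams()
#' singleVoxelOracle(c(0, 1e6), p)  # 0 and ~1.091 kPa
#' @export
singleVoxelOracle <- function(E, params, zone = "cytoplasm", nu = 0.3) {
  vapply(E, function(e) {
    if (e <= 0) return(0)
    keff <- 5.26 * e / (1 + nu)  # cubic-cavity lattice confinement
    g <- function(x) activeStress1d(x, params, zone) + keff * x
    lo <- params$epsMin - 0.2; hi <- 0
    if (g(lo) > 0 || g(hi) < 0) return(0)  # no contraction equilibrium
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-10) break
    }
    activeStress1d((lo + hi) / 2, params, zone)
  }, numeric(1))
}

## ---- finite-element plumbing ----

# Lame parameters (kPa) from E, nu
.lame <- function(E, nu) {
  list(lam = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Assemble and solve the voxel elasticity problem
#'
#' One trilinear 8-node hexahedral element per voxel with homogeneous
#' Dirichlet conditions (u = 0) on the lattice boundary. Voxels with
#' \code{E = 0} or \code{NA} (pore space) are excluded from assembly; their
#' isolated nodes are pinned. Cell voxels carry a per-axis initial
#' (eigen)stress. The sparse system is solved by SSOR-preconditioned
#' conjugate gradients.
#'
#' @param grid a \linkS4class{VoxelGrid} (the computational window).
#' @param E per-voxel Young's modulus (kPa); 0/NA excludes the voxel.
#' @param nu per-voxel Poisson ratio (scalar recycled).
#' @param eigenstress numeric matrix (nVoxels x 3) of per-axis prestress
#'   (kPa), or NULL for none.
#' @param rtol relative residual tolerance (default 1e-8).
#' @param maxit maximum CG iterations.
#' @param u0 optional warm-start solution (active dof vector).
#' @param context optional cached FE context from a previous call on the same
#'   window (as returned in the result), reused to skip pattern construction.
#' @param omega SSOR relaxation parameter.
#' @return list with \code{displacements} (nodes x 3, um), \code{u} (active
#'   dof vector), \code{iters}, \code{relres}, and the reusable
#'   \code{context}.
#' @export
assembleAndSolve <- function(grid, E, nu = 0.3, eigenstress = NULL,
                             rtol = 1e-8, maxit = 5000L, u0 = NULL,
                             context = NULL, omega = 1.3) {
  d <- grid@dims
  nel <- prod(d)
  E <- rep_len(E, nel); nu <- rep_len(nu, nel)
  active <- !is.na(E) & E > 0
  if (!any(active)) stop("no active (solid or cell) voxels to assemble")
  reuse <- !is.null(context) && identical(context$active, active) &&
    identical(context$dims, d)
  if (!reuse) context <- list(ptr = .vm_fe_setup(d[1L], d[2L], d[3L], grid@h,
                                                 active),
                              active = active, dims = d, E = NULL, nu = NULL)
  if (!identical(context$E, E) || !identical(context$nu, nu)) {
    lam <- mu <- numeric(nel)
    lm <- .lame(E[active], nu[active])
    lam[active] <- lm$lam; mu[active] <- lm$mu
    .vm_fe_assemble(context$ptr, lam, mu)
    context$E <- E; context$nu <- nu
  }
  if (is.null(eigenstress)) eigenstress <- matrix(0, nel, 3L)
  f <- .vm_fe_load(context$ptr, eigenstress)
  sol <- .vm_fe_solve(context$ptr, f,
                      if (is.null(u0)) numeric(0) else u0,
                      rtol, as.integer(maxit), omega)
  if (sol$relres > 10 * rtol && sol$relres > 1e-6)
    stop(sprintf("elasticity solve did not converge: relative residual %.2e",
                 sol$relres))
  list(displacements = .vm_fe_expand(context$ptr, sol$u), u = sol$u,
       iters = sol$iters, relres = sol$relres, context = context)
}

#' Direction of maximum cell stress
#'
#' Unit vector from the cell centroid to the centroid of the cell voxel with
#' maximal volumetric stress. Exact ties resolve to the smallest linear voxel
#' index. If the maximum-stress voxel coincides with the centroid the
#' previous direction (or +x at the first step) is kept.
#'
#' @param sigmaV volumetric stress per cell voxel (kPa).
#' @param cell a \linkS4class{CellState}.
#' @param prev previous direction, used as the degenerate-case fallback.
#' @return list(dir = unit numeric(3), maxVoxel = linear index).
#' @export
maxStressDirection <- function(sigmaV, cell, prev = c(1, 0, 0)) {
  i <- which.max(sigmaV)  # first maximum = smallest index (voxels sorted)
  vmax <- cell@voxels[i]
  ctr <- cellCentroid(cell)
  v <- voxelCentroids(cell@grid, vmax)[1L, ] - ctr
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(list(dir = prev / sqrt(sum(prev^2)), maxVoxel = vmax))
  list(dir = v / nv, maxVoxel = vmax)
}

# Computational window: cell bounding box padded by `margin` voxels, clipped
# to the lattice. Returns 2x3 matrix of 1-based inclusive voxel ranges.
.cellWindow <- function(cell, margin) {
  ijk <- .ijk(cell@grid, cell@voxels)
  d <- cell@grid@dims
  lo <- pmax(apply(ijk, 2L, min) - margin, 0L)
  hi <- pmin(apply(ijk, 2L, max) + margin, d - 1L)
  rbind(lo, hi) + 1L
}

# map full-grid linear indices into window linear indices (both 1-based)
.toWindow <- function(grid, win, idx) {
  ijk <- .ijk(grid, idx)
  wd <- win[2L, ] - win[1L, ] + 1L
  rel <- sweep(ijk, 2L, win[1L, ] - 1L)
  as.integer(rel[, 3L] * (wd[1L] * wd[2L]) + rel[, 2L] * wd[1L] +
               rel[, 1L] + 1L)
}

#' Coupled mechanosensing equilibrium
#'
#' Fixed-point iteration between the elastic solve and the mechanosensing
#' law: per-axis cell strains from the last solve feed the actuator stress,
#' which is applied as an element eigenstress, until the volumetric stress
#' changes by less than \code{tol}. The solve runs on a moving window (cell
#' bounding box plus \code{margin} voxels, clipped to the lattice) with fixed
#' displacements on the window boundary; a warning is issued if the cell
#' comes within 5 voxels of the true domain boundary.
#'
#' @param cell a \linkS4class{CellState}.
#' @param ecm an \linkS4class{EcmField}.
#' @param params a \code{\link{cellMaterialParams}} object.
#' @param tol convergence tolerance on max |change in sigma_v| (kPa).
#' @param maxIter maximum fixed-point iterations.
#' @param margin window padding in voxels.
#' @param cache an environment carried across steps to reuse the window
#'   pattern, warm-start displacements and actuator state, or NULL.
#' @param rtol relative residual tolerance of the inner CG solves.
#' @return A \linkS4class{MechSolution}.
#' @export
mechanoEquilibrium <- function(cell, ecm, params = cellMaterialParams(),
                               tol = 1e-3, maxIter = 50L, margin = 6L,
                               cache = NULL, rtol = 1e-7) {
  grid <- cell@grid
  d <- grid@dims
  ijk <- .ijk(grid, cell@voxels)
  if (any(ijk < 5L) || any(sweep(ijk, 2L, d - 1L) > -5L))
    warning("cell is within 5 voxels of the fixed domain boundary")
  need <- .cellWindow(cell, margin)
  win <- NULL
  if (is.environment(cache) && !is.null(cache$win)) {
    # keep the previous window while the padded bounding box still fits
    # inside it (hysteresis avoids rebuilding the pattern every step)
    if (all(need[1L, ] >= cache$win[1L, ]) &&
        all(need[2L, ] <= cache$win[2L, ]))
      win <- cache$win
  }
  if (is.null(win)) win <- .cellWindow(cell, margin + 2L)
  wd <- win[2L, ] - win[1L, ] + 1L
  wgrid <- voxelGrid(wd, grid@h,
                     grid@origin + (win[1L, ] - 1L) * grid@h)
  # full-grid indices of all window voxels
  wijk <- as.matrix(expand.grid(i = (win[1, 1]:win[2, 1]) - 1L,
                                j = (win[1, 2]:win[2, 2]) - 1L,
                                k = (win[1, 3]:win[2, 3]) - 1L))
  wfull <- .lin(grid, wijk)
  nelw <- prod(wd)
  Ew <- ecm@E[wfull]
  nuw <- rep(ecm@nu, nelw)
  if (isTRUE(ecm@porous)) {
    # pore space gets a vanishing background stiffness: it regularizes
    # solid islands that would otherwise carry rigid-body modes, at a
    # confinement 1e-2 of the solid phase (negligible against K_pas)
    wv <- ecm@void[wfull]
    Ew[wv] <- max(ecm@E[!ecm@void], 1) * 1e-2
    nuw[wv] <- 0
  }
  # overlay cell material: passive stiffness, per-axis independence (nu = 0)
  cw <- .toWindow(grid, win, cell@voxels)
  Ew[cw] <- params$Kpas
  nuw[cw] <- 0
  zone <- .zoneName(cell@zones)
  ctx <- NULL; sigAct <- NULL; u0 <- NULL; prevDir <- c(1, 0, 0)
  if (is.environment(cache)) {
    if (identical(cache$win, win)) { ctx <- cache$ctx; u0 <- cache$u }
    if (!is.null(cache$dir)) prevDir <- cache$dir
    if (!is.null(cache$sigActByVoxel)) {
      m <- match(cell@voxels, cache$sigActVoxels)
      sigAct <- cache$sigActByVoxel[m, , drop = FALSE]
      init <- .actuatorStress(0, params, zone)   # newly gained voxels
      for (ax in 1:3) sigAct[is.na(sigAct[, ax]), ax] <-
        init[is.na(sigAct[, ax])]
    }
  }
  if (is.null(sigAct))
    sigAct <- matrix(.actuatorStress(0, params, zone), length(cw), 3L)
  sigmaV <- rep(Inf, length(cw))
  eps <- matrix(0, length(cw), 3L)
  sigTot <- matrix(0, length(cw), 3L)
  iters <- 0L; cgTotal <- 0L
  epsPrev <- NULL; actPrev <- NULL   # local-stiffness secant estimates
  kLoc <- NULL
  sol <- NULL
  for (it in seq_len(maxIter)) {
    es <- matrix(0, nelw, 3L)
    es[cw, ] <- sigAct
    sol <- assembleAndSolve(wgrid, Ew, nuw, eigenstress = es, rtol = rtol,
                            u0 = u0, context = ctx)
    ctx <- sol$context; u0 <- sol$u; cgTotal <- cgTotal + sol$iters
    eps <- .vm_fe_strains(ctx$ptr, sol$u, cw)
    sigTot <- matrix(activeStress1d(as.vector(eps), params,
                                    rep(zone, 3L)), ncol = 3L)
    sigNew <- rowMeans(sigTot)
    dmax <- max(abs(sigNew - ifelse(is.finite(sigmaV), sigmaV, 0)))
    sigmaV <- sigNew
    iters <- it
    if (dmax < tol) break
    # Per-component damped update. The plain iteration has local gain
    # -s'/(Kpas + k) with s' the actuator branch slope and k the confinement
    # stiffness the voxel axis sees; the deadbeat damping for the scalar
    # problem is (Kpas + k) / (Kpas + k + s'). k is estimated by secant from
    # consecutive iterates (stiff default before an estimate exists).
    sigActNew <- sigTot - params$Kpas * eps
    if (is.null(kLoc)) {
      # initial confinement estimate from the surrounding moduli (cubic
      # cavity ~ 4E); free pore-facing voxels start heavily damped, which
      # avoids branch-hopping limit cycles
      nbE <- .neighbors6(grid, cell@voxels)
      Efull <- ecm@E
      if (isTRUE(ecm@porous)) Efull[ecm@void] <- 0
      Efull[cell@voxels] <- 0   # neighbouring cell voxels do not confine
      eloc <- matrix(Efull[ifelse(is.na(nbE), NA, nbE)], nrow(nbE))
      kLoc <- matrix(4 * rowMeans(eloc, na.rm = TRUE), length(cw), 3L)
      kLoc[!is.finite(kLoc)] <- 0
    }
    if (!is.null(epsPrev)) {
      de <- eps - epsPrev
      da <- sigAct - actPrev
      est <- -(params$Kpas * de + da) / de
      ok <- is.finite(est) & abs(de) > 1e-9
      kLoc[ok] <- pmin(pmax(est[ok], 0.01), 1e4)
    }
    epsPrev <- eps; actPrev <- sigAct
    sp <- matrix(.actuatorSlope(as.vector(eps), params, rep(zone, 3L)),
                 ncol = 3L)
    alpha <- (params$Kpas + kLoc) / pmax(params$Kpas + kLoc + sp, 0.2)
    alpha <- pmin(pmax(alpha, 0.05), 1)
    # late-stage safeguard against residual limit cycles
    if (it > maxIter / 2) alpha <- pmin(alpha, 0.25)
    sigAct <- sigAct + alpha * (sigActNew - sigAct)
    # softening-branch snap-through: where the branch slope exceeds the
    # local confinement no damped iteration converges; solve the local
    # series problem directly and jump to its nearest stable root
    bad <- which(-sp > 0.8 * (params$Kpas + kLoc))
    if (length(bad)) {
      zon3 <- rep(zone, 3L)
      for (b in bad) {
        k <- kLoc[b]
        egrid <- seq(params$epsMin - 0.2, params$epsMax + 0.2,
                     length.out = 121L)
        hh <- activeStress1d(egrid, params, zon3[b]) + k * egrid
        sgn <- which(hh[-1] * hh[-length(hh)] <= 0)
        if (!length(sgn)) next
        pick <- sgn[which.min(abs(egrid[sgn] - eps[b]))]
        lo <- egrid[pick]; hi <- egrid[pick + 1L]
        for (bi in 1:40) {
          mid <- (lo + hi) / 2
          if ((activeStress1d(mid, params, zon3[b]) + k * mid) *
              (activeStress1d(lo, params, zon3[b]) + k * lo) <= 0)
            hi <- mid else lo <- mid
        }
        er <- (lo + hi) / 2
        aRoot <- activeStress1d(er, params, zon3[b]) - params$Kpas * er
        sigAct[b] <- 0.5 * (sigAct[b] + aRoot)  # damped move to the root
      }
    }
    if (it == maxIter)
      stop(sprintf(
        "mechanosensing fixed point did not converge: d(sigma_v) = %.2e kPa",
        dmax))
  }
  ms <- maxStressDirection(sigmaV, cell, prev = prevDir)
  # peak displacement over nodes of solid matrix elements (the reported
  # "ECM displacement" excludes cell and pore space)
  solidW <- rep(TRUE, nelw)
  solidW[cw] <- FALSE
  if (isTRUE(ecm@porous)) solidW[ecm@void[wfull]] <- FALSE
  sIjk <- .ijk(wgrid, which(solidW))
  nn <- wd + 1L
  nodeIds <- integer(0)
  if (nrow(sIjk)) {
    base <- sIjk[, 3L] * (nn[1L] * nn[2L]) + sIjk[, 2L] * nn[1L] +
      sIjk[, 1L] + 1L
    offs <- c(0L, 1L, nn[1L], nn[1L] + 1L, nn[1L] * nn[2L],
              nn[1L] * nn[2L] + 1L, nn[1L] * nn[2L] + nn[1L],
              nn[1L] * nn[2L] + nn[1L] + 1L)
    nodeIds <- unique(as.vector(outer(base, offs, "+")))
  }
  maxEcmDisp <- if (length(nodeIds))
    max(sqrt(rowSums(sol$displacements[nodeIds, , drop = FALSE]^2))) else 0
  if (is.environment(cache)) {
    cache$win <- win; cache$ctx <- ctx; cache$u <- u0
    cache$cgIters <- cgTotal
    cache$dir <- ms$dir
    cache$sigActVoxels <- cell@voxels
    cache$sigActByVoxel <- sigTot - params$Kpas * eps
  }
  out <- new("MechSolution", window = unname(win),
             displacements = sol$displacements, eps = eps, sigma = sigTot,
             sigmaV = sigmaV, dDsigma = ms$dir, maxVoxel = ms$maxVoxel,
             iterations = iters)
  attr(out, "maxEcmDisp") <- maxEcmDisp
  out
}
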