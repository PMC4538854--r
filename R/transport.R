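#' @include domain.R
NULL

#' Transport parameters
#'
#' Fluid and solute constants for the steady interstitial-flow and
#' concentration solves. Source terms (reaction, Brinkman mass source, body
#' force) are fixed at zero. The default viscosity is that of water
#' (1e-3 Pa s); see the methods vignette for the rationale.
#'
#' @param deltaP pressure drop across the gel (Pa).
#' @param D solute diffusivity (m^2/s).
#' @param kappa gel permeability (m^2).
#' @param mu fluid dynamic viscosity (Pa s).
#' @param rho fluid density (kg/m^3).
#' @param porosity gel porosity (dimensionless).
#' @param Cin,Cout inlet / outlet concentration (mol/m^3).
#' @return list of class \code{TransportParams}.
#' @export
transportParams <- function(deltaP = 40, D = 1e-9, kappa = 1e-13, mu = 1e-3,
                            rho = 1e3, porosity = 0.9, Cin = 1, Cout = 0) {
  stopifnot(D > 0, kappa > 0, mu > 0, rho > 0,
            porosity > 0, porosity <= 1)
  structure(list(deltaP = deltaP, D = D, kappa = kappa, mu = mu, rho = rho,
                 porosity = porosity, Cin = Cin, Cout = Cout),
            class = "TransportParams")
}

.axisIndex <- function(axis) {
  if (is.character(axis)) match(tolower(axis), c("x", "y", "z")) else axis
}

#' Analytic environment fields
#'
#' The reported gel-region condition: concentration decreasing linearly from
#' inlet to outlet along \code{direction}, uniform flow speed, and a uniform
#' flow direction. This reproduces the interpolated central-box fields of the
#' microdevice without re-solving it.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param direction unit 3-vector of the gradient / flow direction.
#' @param Cin,Cout concentrations at the upstream / downstream domain faces
#'   (mol/m^3).
#' @param speed uniform flow speed (um/s).
#' @return An \linkS4class{EnvFields}.
#' @examples
#' env <- analyticFields(voxelGrid(c(20, 10, 10)), c(1, 0, 0))
#' range(env@C)
#' @export
analyticFields <- function(grid, direction = c(1, 0, 0), Cin = 1, Cout = 0,
                           speed = 3) {
  direction <- direction / sqrt(sum(direction^2))
  ctr <- voxelCentroids(grid)
  s <- as.vector(ctr %*% direction)
  # project to [0, 1] across the domain extent along `direction`
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) %*%
    diag(grid@dims * grid@h)
  sc <- as.vector(sweep(corners, 2L, grid@origin, "+") %*% direction)
  frac <- (s - min(sc)) / (max(sc) - min(sc))
  C <- Cin + (Cout - Cin) * frac
  n <- nVoxels(grid)
  dCref <- max(abs(Cin - Cout) * grid@h / (max(sc) - min(sc)), .Machine$double.eps)
.envFields(C, matrix(direction, n, 3L, byrow = TRUE), rep(speed, n),
             numeric(0), max(Cin, Cout), dCref)
}

# 7-point finite-volume Laplacian solve: div(coef grad u) = 0 with Dirichlet
# values on the two faces of `axis` and no-flux elsewhere. `coef` per voxel;
# harmonic face averaging; NA/0 coef voxels are excluded.
.fvSolve <- function(grid, coef, axis, uIn, uOut) {
  d <- grid@dims
  n <- prod(d)
  ax <- .axisIndex(axis)
  act <- which(!is.na(coef) & coef > 0)
  if (length(act) == 0L) stop("no conducting voxels")
  id <- rep(NA_integer_, n)
  id[act] <- seq_along(act)
  nb <- .neighbors6(grid, act)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag <- numeric(length(act)); rhs <- numeric(length(act))
  for (s in 1:6) {
    other <- nb[, s]
    ok <- !is.na(other) & !is.na(id[ifelse(is.na(other), 1L, other)])
    tf <- 2 * coef[act[ok]] * coef[other[ok]] /
      (coef[act[ok]] + coef[other[ok]])   # harmonic face transmissibility
    ii <- c(ii, id[act[ok]]); jj <- c(jj, id[other[ok]]); xx <- c(xx, -tf)
    diag[id[act[ok]]] <- diag[id[act[ok]]] + tf
  }
  # Dirichlet boundary faces along `axis` (half-cell distance -> factor 2)
  ijk <- .ijk(grid, act)
  lo <- ijk[, ax] == 0L
  hi <- ijk[, ax] == d[ax] - 1L
  diag[id[act[lo]]] <- diag[id[act[lo]]] + 2 * coef[act[lo]]
  rhs[id[act[lo]]] <- rhs[id[act[lo]]] + 2 * coef[act[lo]] * uIn
  diag[id[act[hi]]] <- diag[id[act[hi]]] + 2 * coef[act[hi]]
  rhs[id[act[hi]]] <- rhs[id[act[hi]]] + 2 * coef[act[hi]] * uOut
  A <- Matrix::sparseMatrix(i = c(ii, seq_along(act)),
                            j = c(jj, seq_along(act)),
                            x = c(xx, diag),
                            dims = c(length(act), length(act)))
  u <- tryCatch(as.vector(Matrix::solve(A, rhs)),
                error = function(e)
                  stop("singular transport system: no conducting path ",
                       "between the inlet and outlet faces"))
  out <- rep(NA_real_, n)
  out[act] <- u
  out
}

#' Steady Darcy flow through the gel
#'
#' Cell-centred finite-volume solve of \code{div((kappa/mu) grad P) = 0} with
#' Dirichlet pressures on the two opposite faces of \code{axis} and no-flux
#' walls elsewhere; the Darcy velocity is \code{u = -(kappa/mu) grad P}. In
#' porous mode pass a per-voxel permeability (pore voxels high, solid low).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param params a \code{\link{transportParams}} object.
#' @param kappa optional per-voxel permeability (m^2); default homogeneous
#'   \code{params$kappa}.
#' @param axis flow axis ("x", "y" or "z").
#' @param pIn,pOut inlet / outlet pressures (Pa); default
#'   \code{params$deltaP} and 0.
#' @return An \linkS4class{EnvFields} with pressure (Pa), flow direction and
#'   speed (um/s); concentration is filled with \code{params$Cin}.
#' @export
solveDarcy <- function(grid, params = transportParams(), kappa = NULL,
                       axis = "x", pIn = params$deltaP, pOut = 0) {
  d <- grid@dims
  n <- nVoxels(grid)
  if (is.null(kappa)) kappa <- rep(params$kappa, n)
  # a conducting path must join the inlet and outlet faces
  ax <- .axisIndex(axis)
  cond <- which(!is.na(kappa) & kappa > 0)
  ijk <- .ijk(grid, cond)
  seeds <- cond[ijk[, ax] == 0L]
  reach <- if (length(seeds))
    .vm_component(d[1L], d[2L], d[3L], as.integer(cond), as.integer(seeds))
  else logical(n)
  if (!any(reach[cond][.ijk(grid, cond)[, ax] == d[ax] - 1L]))
    stop("singular transport system: no conducting path between the ",
         "inlet and outlet faces")
  P <- .fvSolve(grid, kappa / params$mu, axis, pIn, pOut)
  # velocity from central pressure differences (Pa / um -> convert to m)
  hum <- grid@h * 1e-6
  vel <- matrix(0, n, 3L)
  idx <- seq_len(n)
  nb <- .neighbors6(grid, idx)
  for (axn in 1:3) {
    plus <- nb[, 2 * axn - 1]; minus <- nb[, 2 * axn]
    pp <- ifelse(is.na(plus), NA, P[ifelse(is.na(plus), 1L, plus)])
    pm <- ifelse(is.na(minus), NA, P[ifelse(is.na(minus), 1L, minus)])
    gradP <- ifelse(!is.na(pp) & !is.na(pm), (pp - pm) / (2 * hum),
             ifelse(!is.na(pp), (pp - P) / hum,
             ifelse(!is.na(pm), (P - pm) / hum, 0)))
    vel[, axn] <- -(kappa / params$mu) * gradP * 1e6  # m/s -> um/s
  }
  vel[is.na(vel)] <- 0
  spd <- sqrt(rowSums(vel^2))
  dir <- vel / ifelse(spd > 0, spd, 1)
  dir[spd == 0, ] <- 0
.envFields(rep(params$Cin, n), dir, spd, ifelse(is.na(P), 0, P),
             max(params$Cin, params$Cout), .Machine$double.eps)
}

#' Steady advection-diffusion concentration field
#'
#' First-order upwind finite-volume solve of
#' \code{div(u C - D grad C) = 0} with Dirichlet concentrations on the two
#' faces of \code{axis}; conservative and bounded by the boundary values
#' (discrete maximum principle). A warning is given when the cell Peclet
#' number exceeds 2 (accuracy, not validity).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param velocity per-voxel velocity matrix (n x 3, um/s), e.g. from
#'   \code{\link{solveDarcy}}.
#' @param params a \code{\link{transportParams}} object.
#' @param axis gradient axis.
#' @param Cin,Cout boundary concentrations (mol/m^3).
#' @return Per-voxel concentration vector.
#' @export
solveAdvectionDiffusion <- function(grid, velocity, params = transportParams(),
                                    axis = "x", Cin = params$Cin,
                                    Cout = params$Cout) {
  d <- grid@dims
  n <- nVoxels(grid)
  ax <- .axisIndex(axis)
  hum <- grid@h * 1e-6                     # m
  Dum <- params$D                          # m^2/s
  vel <- velocity * 1e-6                   # m/s
  pe <- max(abs(vel)) * hum / Dum
  if (pe > 2)
    warning(sprintf("cell Peclet number %.2f > 2: upwind profile will be diffusive",
                    pe))
  idx <- seq_len(n)
  nb <- .neighbors6(grid, idx)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag <- numeric(n); rhs <- numeric(n)
  diff <- Dum / hum                        # diffusive face conductance / area
  for (s in 1:6) {
    other <- nb[, s]
    axn <- (s + 1L) %/% 2L
    sgn <- if (s %% 2L == 1L) 1 else -1    # face normal sign along axn
    ok <- !is.na(other)
    # face velocity (average), outward-normal component
    vface <- sgn * (vel[idx[ok], axn] + vel[other[ok], axn]) / 2
    up <- pmax(vface, 0)                   # outflow uses own C
    dn <- pmin(vface, 0)                   # inflow uses neighbour C
    diag[idx[ok]] <- diag[idx[ok]] + diff + up
    ii <- c(ii, idx[ok]); jj <- c(jj, other[ok]); xx <- c(xx, -diff + dn)
  }
  # Dirichlet on the two axis faces (half-cell diffusion + upwind inflow)
  ijk <- .ijk(grid, idx)
  for (side in c("lo", "hi")) {
    sel <- if (side == "lo") ijk[, ax] == 0L else ijk[, ax] == d[ax] - 1L
    cb <- if (side == "lo") Cin else Cout
    sgn <- if (side == "lo") -1 else 1
    vface <- sgn * vel[sel, ax]
    up <- pmax(vface, 0); dn <- pmin(vface, 0)
    diag[sel] <- diag[sel] + 2 * diff + up
    rhs[sel] <- rhs[sel] + (2 * diff - dn) * cb
  }
  A <- Matrix::sparseMatrix(i = c(ii, idx), j = c(jj, idx), x = c(xx, diag),
                            dims = c(n, n))
  as.vector(Matrix::solve(A, rhs))
}
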