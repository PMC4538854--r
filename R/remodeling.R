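#' @include domain.R
NULL

#' Build an ECM stiffness field
#'
#' Homogeneous, linear or exponential Young's-modulus profiles along one
#' axis. The linear profile interpolates \code{Efrom} to \code{Eto} across
#' the domain; the exponential profile is \code{E0 * exp(alpha x)} with both
#' constants fitted to the endpoint values (so the mid-plane modulus is the
#' geometric mean of the endpoints).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param kind "homogeneous", "linear" or "exponential".
#' @param E modulus for the homogeneous field (kPa).
#' @param Efrom,Eto endpoint moduli (kPa); defaults 45 to 65 for linear and
#'   1 to 100 for exponential.
#' @param axis gradient axis.
#' @param nu ECM Poisson ratio.
#' @return An \linkS4class{EcmField}.
#' @examples
#' g <- voxelGrid(c(100, 10, 10))
#' f <- buildStiffnessField(g, "linear", Efrom = 45, Eto = 65)
#' range(f@E)
#' @export
buildStiffnessField <- function(grid, kind = c("homogeneous", "linear",
                                               "exponential"),
                                E = 50, Efrom = NULL, Eto = NULL,
                                axis = "x", nu = 0.3) {
  kind <- match.arg(kind)
  n <- nVoxels(grid)
  ax <- .axisIndex(axis)
  if (kind == "homogeneous") {
    stopifnot(E > 0)
    Ev <- rep(E, n)
  } else {
    if (is.null(Efrom)) Efrom <- if (kind == "linear") 45 else 1
    if (is.null(Eto)) Eto <- if (kind == "linear") 65 else 100
    if (Efrom <= 0 || Eto <= 0) stop("stiffness endpoints must be positive")
    frac <- (.ijk(grid, seq_len(n))[, ax] + 0.5) / grid@dims[ax]
    Ev <- if (kind == "linear") Efrom + (Eto - Efrom) * frac
          else Efrom * exp(log(Eto / Efrom) * frac)
  }
  new("EcmField", E = Ev, E0 = Ev, nu = nu, degradation = rep(0, n),
      void = logical(0), porous = FALSE)
}

#' Contact degradation of the ECM
#'
#' Every matrix voxel face-adjacent to the cell this step loses the fraction
#' \code{d} of its current Young's modulus, so \code{n} steps of contact
#' leave \code{E0 * (1 - d)^n}. The cumulative degradation fraction is
#' tracked per voxel.
#'
#' @param ecm an \linkS4class{EcmField}.
#' @param cell a \linkS4class{CellState}.
#' @param d degradation fraction per contact step (default 0.01).
#' @return The updated field.
#' @export
degradeEcm <- function(ecm, cell, d = 0.01) {
  stopifnot(d >= 0, d < 1)
  if (d == 0) return(ecm)
  nb <- .neighbors6(cell@grid, cell@voxels)
  touched <- unique(nb[!is.na(nb)])
  touched <- setdiff(touched, cell@voxels)
  if (isTRUE(ecm@porous)) touched <- touched[!ecm@void[touched]]
  ecm@E[touched] <- ecm@E[touched] * (1 - d)
  ecm@degradation[touched] <- 1 - ecm@E[touched] / ecm@E0[touched]
  ecm
}

#' Generate a random porous ECM
#'
#' Builds a random open-cell matrix as the strut network of a
#' Poisson-Voronoi tessellation: seed points are thrown with mean spacing
#' equal to the target pore size, every voxel is ranked by how close it lies
#' to a three-cell junction (third-nearest minus nearest seed distance), and
#' exactly the target solid fraction of best-ranked voxels becomes matrix.
#' This reproduces the stated porosity and pore size with a connected,
#' percolating solid phase; carving independent spherical voids at this
#' porosity and resolution instead disintegrates the solid into floating
#' debris (the septa between 20 um voids fall below one 3 um voxel). The
#' cell region is treated as pore space (the cell occupies pores), and
#' boundary-disconnected solid fragments are relabelled as pores.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param porosity target void fraction (0, 1).
#' @param meanPore target mean pore diameter (um).
#' @param cellRegion linear indices of the initial cell voxels (carved as
#'   pore space), or NULL.
#' @param E solid-phase Young's modulus (kPa, default 5).
#' @param nu ECM Poisson ratio.
#' @return An \linkS4class{EcmField} with \code{porous = TRUE}; attributes
#'   \code{achievedPorosity} and \code{meanChord} (mean x-chord length of the
#'   pore phase, um) report the realized morphology.
#' @export
generatePorousEcm <- function(grid, porosity = 0.9, meanPore = 20,
                              cellRegion = NULL, E = 5, nu = 0.3) {
  stopifnot(porosity >= 0, porosity < 1, meanPore > 0, E > 0)
  n <- nVoxels(grid)
  void <- logical(n)
  extent <- grid@dims * grid@h
  outside <- rep(TRUE, n)
  if (!is.null(cellRegion)) outside[cellRegion] <- FALSE
  target <- porosity
  percolatesX <- function(void) {
    solid <- which(!void)
    if (!length(solid)) return(FALSE)
    d <- grid@dims
    ijk <- .ijk(grid, solid)
    seeds <- solid[ijk[, 1L] == 0L]
    if (!length(seeds)) return(FALSE)
    comp <- .vm_component(d[1L], d[2L], d[3L], as.integer(solid),
                          as.integer(seeds))
    any(.ijk(grid, solid[comp[solid]])[, 1L] == d[1L] - 1L)
  }
  carveCell <- function(void) {
    if (is.null(cellRegion)) return(void)
    void[cellRegion] <- TRUE
    # guarantee the cell region touches pore space beyond itself
    nb <- .neighbors6(grid, cellRegion)
    ring <- setdiff(unique(nb[!is.na(nb)]), cellRegion)
    if (length(ring) && !any(void[ring])) {
      ctr <- colMeans(voxelCentroids(grid, cellRegion))
      rcell <- max(sqrt(rowSums(sweep(voxelCentroids(grid, cellRegion), 2L,
                                      ctr)^2)))
      void[.ballVoxels(grid, ctr + c(rcell + meanPore / 2, 0, 0),
                       meanPore / 2)] <- TRUE
    }
    void
  }
  if (porosity > 0) {
    ok <- FALSE
    for (attempt in 1:8) {  # fresh seed sets until percolation holds
      # Poisson seeds with mean spacing = target pore diameter
      nSeeds <- max(8L, round(prod(extent) / meanPore^3))
      seeds <- matrix(runif(3 * nSeeds), ncol = 3) %*% diag(extent)
      seeds <- sweep(seeds, 2L, grid@origin, "+")
      ss <- rowSums(seeds^2)
      # junction rank: (third-nearest - nearest) seed distance per voxel
      spread <- numeric(n)
      chunk <- 8192L
      for (lo in seq(1L, n, by = chunk)) {
        hi <- min(lo + chunk - 1L, n)
        ctr <- voxelCentroids(grid, lo:hi)
        D2 <- outer(rowSums(ctr^2), rep(1, nSeeds)) - 2 * ctr %*% t(seeds)
        D2 <- sweep(D2, 2L, ss, "+")
        d1 <- do.call(pmin, as.data.frame(D2))
        D2[cbind(seq_len(nrow(D2)), max.col(-D2))] <- Inf
        d2 <- do.call(pmin, as.data.frame(D2))
        D2[cbind(seq_len(nrow(D2)), max.col(-D2))] <- Inf
        d3 <- do.call(pmin, as.data.frame(D2))
        spread[lo:hi] <- sqrt(pmax(d3, 0)) - sqrt(pmax(d1, 0))
      }
      # the target solid fraction of best-ranked voxels becomes matrix;
      # boundary-disconnected fragments carry no load and are relabelled
      # as pores, so the kept fraction is adjusted until the net porosity
      # hits the target
      fracSolid <- 1 - target
      for (adj in 1:6) {
        thr <- quantile(spread[outside], fracSolid, names = FALSE)
        void <- spread > thr
        solid <- which(!void)
        ijkS <- .ijk(grid, solid)
        onFace <- rowSums(ijkS == 0L) > 0L |
          rowSums(sweep(ijkS, 2L, grid@dims - 1L) == 0L) > 0L
        if (any(onFace)) {
          comp <- .vm_component(grid@dims[1L], grid@dims[2L], grid@dims[3L],
                                as.integer(solid), as.integer(solid[onFace]))
          void[solid[!comp[solid]]] <- TRUE
        }
        ach <- mean(void[outside])
        if (abs(ach - target) <= 0.015) break
        fracSolid <- max(min(fracSolid + (ach - target), 0.9), 0.01)
      }
      void <- carveCell(void)
      if (abs(ach - target) <= 0.025 && percolatesX(void)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not generate a percolating matrix at porosity %.2f (achieved %.3f)",
        target, ach))
  } else {
    void <- carveCell(void)
  }
  Ev <- rep(E, n)
  Ev[void] <- 0
  # mean x-chord of the pore phase
  vd <- array(void, dim = grid@dims)
  runs <- apply(vd, c(2, 3), function(col) {
    r <- rle(col)
    r$lengths[r$values]
  })
  chord <- mean(unlist(runs)) * grid@h
  out <- new("EcmField", E = Ev, E0 = Ev, nu = nu, degradation = rep(0, n),
             void = void, porous = TRUE)
  attr(out, "achievedPorosity") <- mean(void[outside])
  attr(out, "meanChord") <- chord
  out
}
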