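# Small lattices and hand-built cells used across the tests.

# a cell occupying an explicit set of (i, j, k) offsets (0-based)
cellFromIjk <- function(grid, ijk, nucleus = integer(0)) {
  vox <- sort(voxelmig:::.lin(grid, as.matrix(ijk)))
  cell <- new("CellState", grid = grid, voxels = vox,
              zones = rep(2L, length(vox)), nucleus = as.integer(nucleus),
              step = 0L,
              trajectory = matrix(colMeans(voxelCentroids(grid, vox)), 1, 3))
  classifyZones(cell)
}

cubeCell <- function(n = 3L, grid = voxelGrid(c(12, 12, 12)), at = 4L,
                     nucleus = integer(0)) {
  ijk <- as.matrix(expand.grid(i = at + seq_len(n) - 1L,
                               j = at + seq_len(n) - 1L,
                               k = at + seq_len(n) - 1L))
  cellFromIjk(grid, ijk, nucleus)
}

# brute-force 6-erosion of a voxel set: voxels all of whose 6 neighbours
# (in-domain) are also members
erode6 <- function(grid, vox) {
  occ <- logical(nVoxels(grid)); occ[vox] <- TRUE
  nb <- voxelmig:::.neighbors6(grid, vox)
  inside <- !is.na(nb)
  allin <- vapply(seq_along(vox), function(r) {
    v <- nb[r, ]
    all(is.na(v) | occ[replace(v, is.na(v), 1L)]) && !anyNA(v)
  }, logical(1))
  vox[allin]
}

# random connected blob grown from a seed voxel
randomBlob <- function(grid, n, seed) {
  set.seed(seed)
  d <- grid@dims
  start <- voxelmig:::.lin(grid, rbind(floor(d / 2)))
  vox <- start
  occ <- logical(nVoxels(grid)); occ[start] <- TRUE
  while (length(vox) < n) {
    nb <- voxelmig:::.neighbors6(grid, vox)
    cand <- unique(nb[!is.na(nb)])
    cand <- cand[!occ[cand]]
    if (!length(cand)) break
    pick <- cand[sample.int(length(cand), 1L)]
    occ[pick] <- TRUE
    vox <- sort(c(vox, pick))
  }
  vox
}
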