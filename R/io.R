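#' @include domain.R
NULL

#' Write per-voxel arrays as legacy ASCII VTK
#'
#' Writes the lattice as STRUCTURED_POINTS image data with one or more named
#' cell-data arrays (e.g. the label grid, Young's modulus, volumetric
#' stress), readable by ParaView and VTK-based tools.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param arrays named list of per-voxel numeric/integer vectors.
#' @param file output path.
#' @param title dataset title line.
#' @return The file path, invisibly.
#' @export
writeGridVTK <- function(grid, arrays, file, title = "voxelmig fields") {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  d <- grid@dims
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L,
                       d[3] + 1L),
               sprintf("ORIGIN %g %g %g", grid@origin[1], grid@origin[2],
                       grid@origin[3]),
               sprintf("SPACING %g %g %g", grid@h, grid@h, grid@h),
               sprintf("CELL_DATA %d", prod(d))), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (length(a) != prod(d)) stop("array '", nm, "' has wrong length")
    int <- is.integer(a)
    writeLines(sprintf("SCALARS %s %s 1", nm, if (int) "int" else "float"),
               con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(format(a, trim = TRUE, scientific = !int),
                     collapse = " "), con)
  }
  invisible(file)
}

#' Write / read a label grid as run-length text
#'
#' Compact plain-text fixture format: a header with the lattice shape and
#' voxel size followed by \code{value:count} run-length pairs of the linear
#' label sequence (x fastest).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param labels integer per-voxel labels.
#' @param file path.
#' @return \code{writeLabelRle}: the path, invisibly;
#'   \code{readLabelRle}: list with \code{grid} and \code{labels}.
#' @export
writeLabelRle <- function(grid, labels, file) {
  stopifnot(length(labels) == nVoxels(grid))
  r <- rle(as.integer(labels))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("voxelmig-rle %d %d %d %g", grid@dims[1],
                       grid@dims[2], grid@dims[3], grid@h),
               paste(sprintf("%d:%d", r$values, r$lengths),
                     collapse = " ")), con)
  invisible(file)
}

#' @rdname writeLabelRle
#' @export
readLabelRle <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1L], " ")[[1L]]
  if (hdr[1L] != "voxelmig-rle") stop("not a voxelmig run-length file")
  grid <- voxelGrid(as.integer(hdr[2:4]), as.numeric(hdr[5L]))
  pairs <- strsplit(strsplit(lines[2L], " ")[[1L]], ":")
  vals <- as.integer(vapply(pairs, `[`, "", 1L))
  lens <- as.integer(vapply(pairs, `[`, "", 2L))
  list(grid = grid, labels = inverse.rle(list(values = vals,
                                              lengths = lens)))
}

#' Write a migration event log as CSV
#'
#' @param run a \linkS4class{MigrationRun}.
#' @param file path; replicate number is appended for multi-replicate runs.
#' @return The paths written, invisibly.
#' @export
writeEventLog <- function(run, file) {
  paths <- character(0)
  for (r in seq_along(run@events)) {
    p <- if (length(run@events) == 1L) file
         else sub("(\\.[^.]*)?$", sprintf("-rep%d\\1", r), file)
    write.csv(run@events[[r]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
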