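## NIfTI conventions: only scaling + translation are supported. The sform
## (code 2) is diag(voxel_size) with translation origin + voxel_size/2, i.e.
## the CENTER of voxel (0,0,0) maps to origin + s/2 -- NIfTI's center-based
## voxel coordinates against this package's corner-based grid origin.

grid_to_xform <- function(grid) {
  m <- diag(c(grid$voxel_size, 1))
  m[1:3, 4] <- grid$origin + 0.5 * grid$voxel_size
  m
}

xform_to_grid <- function(img) {
  m <- unclass(RNifti::xform(img))
  sc <- c(m[1, 1], m[2, 2], m[3, 3])
  off <- abs(m[1:3, 1:3]) - diag(abs(sc))
  if (max(abs(off)) > 1e-6 || any(sc <= 0))
    stop("only axis-aligned, positively scaled NIfTI orientations are supported")
  d <- dim(img)[1:3]
  voxel_grid(d, sc, m[1:3, 4] - 0.5 * sc)
}

#' Write a scalar (or higher-dimensional) volume as NIfTI-1
#'
#' @param data numeric/logical array; the first three dimensions must match
#'   the grid.
#' @param grid a \code{\link{voxel_grid}}.
#' @param path output path (.nii or .nii.gz).
#' @return invisibly, the path.
#' @export
write_nifti_volume <- function(data, grid, path) {
  if (!identical(dim(data)[1:3], as.integer(grid$dims)))
    stop("volume shape does not match grid dims")
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(grid_to_xform(grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume together with its grid
#'
#' @param path NIfTI file path.
#' @return list with \code{grid} (a \code{\link{voxel_grid}}) and
#'   \code{data} (the array).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # plain array, no NIfTI baggage
  list(grid = xform_to_grid(img), data = data)
}

#' Write an ODF field: 4-D NIfTI plus a plain-text direction table
#'
#' @param odf an \code{\link{odf_field}}.
#' @param path_values output NIfTI path for the (x,y,z,N) sample array.
#' @param path_directions output text path: N rows of unit x y z.
#' @return invisibly, \code{path_values}.
#' @export
write_odf_field <- function(odf, path_values, path_directions) {
  write_nifti_volume(odf$values, odf$grid, path_values)
  utils::write.table(format(odf$sampling$vertices, digits = 17),
                     path_directions, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path_values)
}

#' Read an ODF field from a 4-D NIfTI and a direction table
#'
#' The sampling adjacency is rebuilt by convex-hull triangulation of the
#' direction vertices.
#'
#' @param path_values 4-D NIfTI path, last dimension = number of directions.
#' @param path_directions text path with one unit 3-vector per row.
#' @return an \code{\link{odf_field}}.
#' @export
read_odf_field <- function(path_values, path_directions) {
  vol <- read_nifti_volume(path_values)
  if (length(dim(vol$data)) != 4L)
    stop("ODF volume must be 4-D, got ", length(dim(vol$data)), "-D")
  dirs <- as.matrix(utils::read.table(path_directions))
  if (ncol(dirs) != 3L)
    stop("direction table must have 3 columns, got ", ncol(dirs))
  if (nrow(dirs) != dim(vol$data)[4])
    stop("direction table has ", nrow(dirs), " rows but ODF volume holds ",
         dim(vol$data)[4], " samples per voxel")
  nrm <- sqrt(rowSums(dirs^2))
  bad <- which(abs(nrm - 1) > 1e-6)
  if (length(bad))
    stop("non-unit direction at table row ", bad[1])
  odf_field(vol$grid, sphere_sampling(dirs), vol$data)
}

#' Write a vector field as a 5-D NIfTI (x, y, z, peak, [vx vy vz d])
#'
#' Absent peaks are zero-filled. FA and mask, when present, go to sibling
#' files derived from \code{path} (suffixes \code{_fa}, \code{_mask}).
#'
#' @param field a \code{\link{vector_field}}.
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
write_vector_field <- function(field, path) {
  g <- field$grid
  npk <- max(1L, max(vapply(field$peaks, function(p)
    if (is.null(p)) 0L else nrow(p$directions), integer(1))))
  arr <- array(0, c(g$dims, npk, 4L))
  for (k in seq_len(g$dims[3]) - 1L)
    for (j in seq_len(g$dims[2]) - 1L)
      for (i in seq_len(g$dims[1]) - 1L) {
        ds <- field$peaks[[linear_index(g, c(i, j, k))]]
        if (is.null(ds) || !nrow(ds$directions)) next
        for (q in seq_len(nrow(ds$directions))) {
          arr[i + 1L, j + 1L, k + 1L, q, 1:3] <- ds$directions[q, ]
          arr[i + 1L, j + 1L, k + 1L, q, 4L] <- ds$d[q]
        }
      }
  write_nifti_volume(arr, g, path)
  if (!is.null(field$fa))
    write_nifti_volume(field$fa, g, sibling_path(path, "_fa"))
  if (!is.null(field$wm_mask))
    write_nifti_volume(field$wm_mask, g, sibling_path(path, "_mask"))
  invisible(path)
}

sibling_path <- function(path, suffix) {
  sub("(\\.nii(\\.gz)?)$", paste0(suffix, "\\1"), path)
}

#' Read a vector field written by \code{\link{write_vector_field}}
#'
#' @param path 5-D NIfTI path.
#' @param fa_path,mask_path optional NIfTI paths; defaults to the sibling
#'   files if they exist.
#' @return a \code{\link{vector_field}}.
#' @export
read_vector_field <- function(path, fa_path = NULL, mask_path = NULL) {
  vol <- read_nifti_volume(path)
  if (length(dim(vol$data)) != 5L || dim(vol$data)[5] != 4L)
    stop("vector-field volume must be 5-D with 4 components per peak")
  g <- vol$grid
  peaks <- vector("list", prod(g$dims))
  for (k in seq_len(g$dims[3]) - 1L)
    for (j in seq_len(g$dims[2]) - 1L)
      for (i in seq_len(g$dims[1]) - 1L) {
        slab <- matrix(vol$data[i + 1L, j + 1L, k + 1L, , ], ncol = 4L)
        keep <- slab[, 4] > 0
        li <- linear_index(g, c(i, j, k))
        peaks[[li]] <- if (!any(keep)) empty_direction_set()
        else {
          v <- slab[keep, 1:3, drop = FALSE]
          v <- v / sqrt(rowSums(v^2))
          direction_set(v, slab[keep, 4])
        }
      }
  if (is.null(fa_path) && file.exists(sibling_path(path, "_fa")))
    fa_path <- sibling_path(path, "_fa")
  if (is.null(mask_path) && file.exists(sibling_path(path, "_mask")))
    mask_path <- sibling_path(path, "_mask")
  fa <- if (!is.null(fa_path)) read_nifti_volume(fa_path)$data else NULL
  msk <- if (!is.null(mask_path)) array(read_nifti_volume(mask_path)$data > 0.5,
                                        g$dims) else NULL
  vector_field(g, peaks, fa = fa, wm_mask = msk)
}

## --- tractogram formats ----------------------------------------------------

#' Write a tractogram in TCK or TRK format
#'
#' TCK: text header, float32 little-endian mm triples, streamlines
#' separated by NaN triples, file terminated by an Inf triple. TRK
#' (TrackVis, version 2): 1000-byte header with a voxel-to-world affine
#' built from the grid; points stored in the standard voxel-mm convention
#' ((voxel index + 0.5) * voxel size).
#'
#' @param tract a \code{\link{tractogram}} or list of pathways.
#' @param path output file path.
#' @param format \code{"tck"} or \code{"trk"}; default from the extension.
#' @param grid \code{\link{voxel_grid}} for the TRK header (defaults to the
#'   tractogram's own grid; required for TRK).
#' @return invisibly, the path.
#' @export
write_tractogram <- function(tract, path, format = NULL, grid = NULL) {
  if (inherits(tract, "tractogram")) {
    if (is.null(grid)) grid <- tract$grid
    tract <- tract$pathways
  }
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         tck = write_tck(tract, path),
         trk = write_trk(tract, path, grid),
         stop("unknown tractogram format: ", format))
  invisible(path)
}

#' Read a tractogram (TCK or TRK)
#' @param path input file path.
#' @param format \code{"tck"} or \code{"trk"}; default from the extension.
#' @return a \code{\link{tractogram}} (TRK also restores the grid header).
#' @export
read_tractogram <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         tck = read_tck(path),
         trk = read_trk(path),
         stop("unknown tractogram format: ", format))
}

write_tck <- function(pathways, path) {
  n <- length(pathways)
  fixed <- c("mrtrix tracks", "datatype: Float32LE", sprintf("count: %d", n))
  # the 'file: . <offset>' line must state the byte offset of the binary
  # section, which depends on its own width; iterate to a fixed point
  offset <- 0L
  repeat {
    hdr <- c(fixed, sprintf("file: . %d", offset), "END")
    need <- sum(nchar(hdr, type = "bytes")) + length(hdr)   # newlines
    if (need == offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  for (p in pathways) {
    m <- t(unclass(p))
    writeBin(as.numeric(m), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("TCK header without END")
    if (identical(ln, "END")) break
    if (grepl("^file:", ln))
      offset <- as.integer(sub("^file: *\\. *", "", ln))
  }
  if (is.na(offset)) stop("TCK header lacks a file offset")
  seek(con, offset)
  raw_vals <- readBin(con, numeric(), n = file.size(path), size = 4L,
                      endian = "little")
  m <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  pathways <- list()
  start <- 1L
  for (r in seq_len(nrow(m))) {
    if (all(is.infinite(m[r, ]))) break
    if (all(is.nan(m[r, ]))) {
      if (r > start)
        pathways[[length(pathways) + 1L]] <- pathway(m[start:(r - 1L), , drop = FALSE])
      start <- r + 1L
    }
  }
  tractogram(pathways)
}

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  c(r[seq_len(min(n, length(r)))], raw(max(0L, n - length(r))))
}

write_trk <- function(pathways, path, grid) {
  if (is.null(grid)) stop("TRK output needs a grid for its header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_raw("TRACK", 6L), con)
  writeBin(as.integer(grid$dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(grid$voxel_size), con, size = 4L, endian = "little")
  writeBin(as.numeric(grid$origin), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  writeBin(raw(200L), con)                                   # scalar names
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  writeBin(raw(200L), con)                                   # property names
  writeBin(as.numeric(t(grid_to_xform(grid))), con, size = 4L,
           endian = "little")                                # vox_to_ras
  writeBin(raw(444L), con)                                   # reserved
  writeBin(pad_raw("RAS", 4L), con)                          # voxel_order
  writeBin(raw(4L), con)                                     # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L,
           endian = "little")                                # image orientation
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap flags
  writeBin(length(pathways), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  for (p in pathways) {
    pts <- unclass(p)
    # voxel-mm storage: (voxel coords + 0.5) * voxel size
    vmm <- sweep(pts, 2L, grid$origin)                       # = (v + 0.5) * s
    writeBin(nrow(pts), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(vmm)), con, size = 4L, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 6L)[1:5])
  if (!identical(magic, "TRACK")) stop("not a TRK file: ", path)
  dims <- readBin(con, integer(), 3L, size = 2L, endian = "little")
  vsize <- readBin(con, numeric(), 3L, size = 4L, endian = "little")
  origin_field <- readBin(con, numeric(), 3L, size = 4L, endian = "little")
  n_scalars <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  invisible(readBin(con, raw(), 200L))
  n_props <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  invisible(readBin(con, raw(), 200L))
  v2r <- matrix(readBin(con, numeric(), 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  invisible(readBin(con, raw(), 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  invisible(readBin(con, integer(), 2L, size = 4L, endian = "little"))
  grid <- voxel_grid(dims, vsize, v2r[1:3, 4] - 0.5 * vsize)
  pathways <- vector("list", n_count)
  for (t in seq_len(n_count)) {
    np <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    vals <- readBin(con, numeric(), np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) invisible(readBin(con, numeric(), n_props, size = 4L,
                                        endian = "little"))
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    pathways[[t]] <- pathway(sweep(m, 2L, grid$origin, "+"))
  }
  tractogram(pathways, grid = grid)
}

#' Read seed voxels from a text table or a NIfTI mask
#'
#' Text files: whitespace-separated rows of 0-based voxel indices i j k.
#' NIfTI files: every voxel with a value > 0.5 becomes a seed.
#'
#' @param path input path (.txt/.tsv/.csv or .nii/.nii.gz).
#' @return integer matrix of 0-based voxel triples.
#' @export
read_seeds <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    vol <- read_nifti_volume(path)
    w <- which(vol$data > 0.5, arr.ind = TRUE)
    seeds <- w[, 1:3, drop = FALSE] - 1L
    storage.mode(seeds) <- "integer"
    dimnames(seeds) <- NULL
    return(seeds)
  }
  tb <- utils::read.table(path, comment.char = "#")
  if (ncol(tb) < 3L) stop("seed table must have 3 columns (i j k, 0-based)")
  seeds <- as.matrix(tb[, 1:3])
  storage.mode(seeds) <- "integer"
  dimnames(seeds) <- NULL
  seeds
}
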