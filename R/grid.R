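#' Voxel grid geometry
#'
#' An axis-aligned voxel grid. Voxel indices are 0-based integer triples;
#' voxel \code{(i,j,k)} occupies the half-open box
#' \code{[origin + i*s, origin + (i+1)*s)} per axis (\code{s} = voxel size)
#' and its center is \code{origin + (i + 0.5)*s}. World units are mm.
#' Only scaling and translation are supported (no oblique rotation).
#'
#' @param dims integer triple (nx, ny, nz), all >= 1.
#' @param voxel_size positive length-3 numeric, mm (scalar recycled).
#' @param origin length-3 numeric, mm: world coordinate of the corner of
#'   voxel (0,0,0).
#' @return An object of class \code{voxel_grid}.
#' @examples
#' g <- voxel_grid(c(20, 20, 20), 1)
#' voxel_center(g, c(0, 0, 0))
#' @export
voxel_grid <- function(dims, voxel_size = 1, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0))
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(dims = dims, voxel_size = voxel_size, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, size %s mm, origin (%s) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$voxel_size), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

grid_check_index <- function(grid, idx) {
  idx <- as.integer(round(idx))
  if (length(idx) != 3L || any(idx < 0L) || any(idx >= grid$dims))
    stop("voxel index out of bounds: (", paste(idx, collapse = ","), ")")
  idx
}

#' World coordinate of a voxel center
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param idx 0-based integer triple, in bounds.
#' @return length-3 numeric, mm.
#' @export
voxel_center <- function(grid, idx) {
  idx <- grid_check_index(grid, idx)
  grid$origin + (idx + 0.5) * grid$voxel_size
}

#' Voxel containing a world point
#'
#' Half-open box convention: a point on a facet shared by two voxels belongs
#' to the voxel with the larger index. The outer surface of the grid is
#' closed (to 1e-9 of a voxel): points on the far boundary belong to the
#' last voxel, so facet points of boundary voxels stay addressable. Returns
#' NA triple for points outside the grid.
#'
#' @inheritParams voxel_center
#' @param point length-3 numeric, mm.
#' @return 0-based integer triple or NA triple.
#' @export
world_to_voxel <- function(grid, point) {
  rel <- (point - grid$origin) / grid$voxel_size
  tol <- 1e-9
  rel[rel < 0 & rel > -tol] <- 0
  idx <- floor(rel)
  hi <- idx >= grid$dims & rel <= grid$dims + tol
  idx[hi] <- grid$dims[hi] - 1L
  if (any(idx < 0) || any(idx >= grid$dims)) return(rep(NA_integer_, 3L))
  as.integer(idx)
}

#' 26-connected neighborhood of a voxel
#'
#' All in-bounds voxels differing by at most 1 per axis, the voxel itself
#' excluded; interior voxels have exactly 26 neighbors, boundary voxels fewer.
#'
#' @inheritParams voxel_center
#' @return integer matrix, one 0-based triple per row.
#' @export
neighbors26 <- function(grid, idx) {
  idx <- grid_check_index(grid, idx)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  nb <- sweep(off, 2L, idx, "+")
  keep <- nb[, 1] >= 0L & nb[, 2] >= 0L & nb[, 3] >= 0L &
    nb[, 1] < grid$dims[1] & nb[, 2] < grid$dims[2] & nb[, 3] < grid$dims[3]
  nb <- nb[keep, , drop = FALSE]
  dimnames(nb) <- NULL
  storage.mode(nb) <- "integer"
  nb
}

#' Perpendicular distance from a point to an infinite line
#'
#' @param p length-3 numeric point, mm.
#' @param a length-3 numeric point on the line, mm.
#' @param u unit length-3 direction of the line.
#' @return non-negative distance, mm. Invariant under \code{u -> -u}.
#' @export
point_line_distance <- function(p, a, u) {
  if (abs(sum(u * u) - 1) > 1e-6) stop("direction u must be unit length")
  w <- p - a
  w <- w - sum(w * u) * u
  sqrt(sum(w * w))
}

## --- direction sets and vector fields -------------------------------------

#' Per-voxel set of diffusion directions with probabilities
#'
#' The per-voxel matrix of unit fiber axes \code{v_i} with diffusion
#' probabilities \code{d_i}. Direction sign carries no meaning (\code{v} and
#' \code{-v} denote the same axis).
#'
#' @param directions n x 3 matrix of unit row vectors (n may be 0).
#' @param d length-n numeric of strictly positive probabilities.
#' @return object of class \code{direction_set}.
#' @export
direction_set <- function(directions, d) {
  directions <- matrix(as.numeric(directions), ncol = 3L)
  d <- as.numeric(d)
  stopifnot(nrow(directions) == length(d))
  if (nrow(directions) > 0L) {
    nrm <- sqrt(rowSums(directions^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
    if (any(d <= 0)) stop("probabilities must be strictly positive")
  }
  structure(list(directions = directions, d = d), class = "direction_set")
}

empty_direction_set <- function() direction_set(matrix(0, 0L, 3L), numeric(0))

#' @export
print.direction_set <- function(x, ...) {
  cat("direction_set with", nrow(x$directions), "axis/axes\n")
  if (nrow(x$directions) > 0L)
    print(cbind(round(x$directions, 4), d = round(x$d, 4)))
  invisible(x)
}

linear_index <- function(grid, idx) {
  1L + idx[1] + grid$dims[1] * (idx[2] + grid$dims[2] * idx[3])
}

#' Vector field: per-voxel direction sets over a grid
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param peaks list of \code{\link{direction_set}} (or NULL for empty),
#'   length prod(dims), in column-major (x fastest) linear order; or a
#'   function \code{f(idx)} called per voxel.
#' @param fa optional numeric array dims(grid) in [0,1].
#' @param wm_mask optional logical array dims(grid).
#' @return object of class \code{vector_field}.
#' @export
vector_field <- function(grid, peaks, fa = NULL, wm_mask = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  nvox <- prod(grid$dims)
  if (is.function(peaks)) {
    f <- peaks
    peaks <- vector("list", nvox)
    for (k in seq_len(grid$dims[3]) - 1L)
      for (j in seq_len(grid$dims[2]) - 1L)
        for (i in seq_len(grid$dims[1]) - 1L)
          peaks[[linear_index(grid, c(i, j, k))]] <- f(c(i, j, k))
  }
  stopifnot(length(peaks) == nvox)
  if (!is.null(fa)) {
    if (!identical(dim(fa), as.integer(grid$dims)))
      stop("fa volume shape does not match grid dims")
    if (any(fa < -1e-9 | fa > 1 + 1e-9, na.rm = TRUE))
      stop("fa values must lie in [0,1]")
  }
  if (!is.null(wm_mask) && !identical(dim(wm_mask), as.integer(grid$dims)))
    stop("wm_mask shape does not match grid dims")
  structure(list(grid = grid, peaks = peaks, fa = fa, wm_mask = wm_mask),
            class = "vector_field")
}

#' Direction set at a voxel
#' @param field a \code{\link{vector_field}}.
#' @param idx 0-based voxel triple.
#' @return a \code{\link{direction_set}} (possibly empty).
#' @export
field_peaks_at <- function(field, idx) {
  ds <- field$peaks[[linear_index(field$grid, grid_check_index(field$grid, idx))]]
  if (is.null(ds)) empty_direction_set() else ds
}

field_fa_at <- function(field, idx) {
  if (is.null(field$fa)) return(NA_real_)
  field$fa[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L]
}

field_in_mask <- function(field, idx) {
  if (is.null(field$wm_mask)) return(TRUE)
  isTRUE(field$wm_mask[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L])
}

#' @export
print.vector_field <- function(x, ...) {
  n <- vapply(x$peaks, function(p) if (is.null(p)) 0L else nrow(p$directions),
              integer(1))
  cat("vector_field over ", paste(x$grid$dims, collapse = " x "),
      " grid: ", sum(n > 0L), " voxels with peaks (max ", max(n), "/voxel); ",
      if (is.null(x$fa)) "no FA" else "FA attached", "; ",
      if (is.null(x$wm_mask)) "no mask" else "WM mask attached", "\n",
      sep = "")
  invisible(x)
}

## --- tracking parameters ---------------------------------------------------

#' Tracking parameters
#'
#' Stopping and selection thresholds for chain extraction and tracking.
#' Defaults are the operating point used throughout: angle threshold 60
#' degrees, fiber length threshold 70 mm, FA threshold 0.15.
#'
#' @param theta_th axial angle threshold between consecutive directions,
#'   degrees, in (0, 90].
#' @param L_th maximum fiber length, mm.
#' @param FA_th minimum fractional anisotropy, in [0, 1).
#' @param d_th line-to-neighbor-center distance threshold, mm. Default
#'   \code{NA} means half the voxel diagonal of the grid in use.
#' @param step output sampling step along fitted pathways, mm.
#' @param mode one of \code{"nurbs_t"}, \code{"nurbs_g"}, \code{"streamline"}.
#' @return object of class \code{tracking_params}.
#' @export
tracking_params <- function(theta_th = 60, L_th = 70, FA_th = 0.15,
                            d_th = NA_real_, step = 0.5,
                            mode = c("nurbs_t", "nurbs_g", "streamline")) {
  mode <- match.arg(mode)
  stopifnot(theta_th > 0, theta_th <= 90, L_th > 0,
            FA_th >= 0, FA_th < 1, is.na(d_th) || d_th > 0, step > 0)
  structure(list(theta_th = theta_th, L_th = L_th, FA_th = FA_th,
                 d_th = d_th, step = step, mode = mode),
            class = "tracking_params")
}

# resolve the default d_th against a concrete grid
resolve_d_th <- function(params, grid) {
  if (is.na(params$d_th)) 0.5 * sqrt(sum(grid$voxel_size^2)) else params$d_th
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(
    "tracking_params: mode=%s theta_th=%g deg, L_th=%g mm, FA_th=%g, d_th=%s, step=%g mm\n",
    x$mode, x$theta_th, x$L_th, x$FA_th,
    if (is.na(x$d_th)) "auto (half voxel diagonal)" else paste0(x$d_th, " mm"),
    x$step))
  invisible(x)
}

## --- pathways and tractograms ---------------------------------------------

#' Construct a pathway (3-D polyline in mm)
#'
#' @param points m x 3 numeric matrix of mm world coordinates, m >= 2.
#' @param seed_voxel 0-based voxel triple the pathway was seeded from.
#' @param termination_reason character: one per end, from
#'   \code{c("angle","length","fa","no_candidate","mask_exit")}.
#' @return matrix of class \code{pathway} with metadata attributes.
#' @export
pathway <- function(points, seed_voxel = c(NA_integer_, NA_integer_, NA_integer_),
                    termination_reason = "no_candidate") {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 2L) stop("a pathway needs at least 2 points")
  structure(points, class = c("pathway", "matrix"),
            seed_voxel = as.integer(seed_voxel),
            termination_reason = termination_reason)
}

pathway_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(unclass(p))^2)))
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("pathway: %d points, %.2f mm, seed (%s), termination: %s\n",
              nrow(x), pathway_length(x),
              paste(attr(x, "seed_voxel"), collapse = ","),
              paste(attr(x, "termination_reason"), collapse = "/")))
  invisible(x)
}

#' Bundle a list of pathways into a tractogram
#' @param pathways list of \code{\link{pathway}} objects.
#' @param grid the generating \code{\link{voxel_grid}} (kept for I/O headers).
#' @return object of class \code{tractogram}.
#' @export
tractogram <- function(pathways, grid = NULL) {
  stopifnot(is.list(pathways))
  structure(list(pathways = pathways, grid = grid), class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$pathways)

#' @export
print.tractogram <- function(x, ...) {
  len <- vapply(x$pathways, pathway_length, numeric(1))
  cat(sprintf("tractogram: %d pathway(s)", length(x$pathways)))
  if (length(x$pathways))
    cat(sprintf(", length %.1f-%.1f mm (median %.1f)",
                min(len), max(len), stats::median(len)))
  cat("\n")
  invisible(x)
}

#' @export
summary.tractogram <- function(object, ...) {
  reasons <- unlist(lapply(object$pathways, attr, "termination_reason"))
  len <- vapply(object$pathways, pathway_length, numeric(1))
  out <- list(n = length(object$pathways),
              length_mm = if (length(len)) summary(len) else NULL,
              termination = if (length(reasons)) table(reasons) else NULL)
  class(out) <- "summary.tractogram"
  out
}

#' @export
print.summary.tractogram <- function(x, ...) {
  cat("tractogram with", x$n, "pathway(s)\n")
  if (!is.null(x$length_mm)) { cat("lengths (mm):\n"); print(x$length_mm) }
  if (!is.null(x$termination)) { cat("termination reasons:\n"); print(x$termination) }
  invisible(x)
}

#' Plot a tractogram as a 2-D projection
#' @param x a \code{\link{tractogram}}.
#' @param axes which two world axes to project on (default x, y).
#' @param col line color(s), recycled over pathways.
#' @param ... passed to \code{plot.default}.
#' @export
plot.tractogram <- function(x, axes = c(1, 2), col = "steelblue", ...) {
  if (!length(x$pathways)) { plot.new(); return(invisible(x)) }
  all_pts <- do.call(rbind, lapply(x$pathways, unclass))
  lab <- c("x (mm)", "y (mm)", "z (mm)")
  graphics::plot(all_pts[, axes[1]], all_pts[, axes[2]], type = "n",
                 xlab = lab[axes[1]], ylab = lab[axes[2]], asp = 1, ...)
  col <- rep_len(col, length(x$pathways))
  for (i in seq_along(x$pathways))
    graphics::lines(x$pathways[[i]][, axes[1]], x$pathways[[i]][, axes[2]],
                    col = col[i])
  invisible(x)
}

## --- small vector helpers shared across modules ----------------------------

normalize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

# axial (orientation-free) angle between two unit vectors, radians in [0, pi/2]
axial_angle <- function(u, v) {
  acos(min(1, abs(sum(u * v))))
}
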