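#' Spherical sampling scheme with triangulation adjacency
#'
#' Stores unit sampling vertices together with a symmetric vertex adjacency
#' obtained from the convex hull of the vertex cloud (for points on a sphere
#' the hull is the spherical Delaunay triangulation). Hull facets are found
#' by direct enumeration: a vertex triple spans a facet iff all remaining
#' vertices lie on one side of its plane; near-coplanar configurations
#' contribute all supporting triples, which only adds edges within the
#' coplanar polygon. Quadratic-to-quartic in N, fine for the shell sizes
#' used in HARDI sampling schemes (N of order 64).
#'
#' @param vertices N x 3 matrix of unit vectors, N >= 4.
#' @return object of class \code{sphere_sampling} with fields
#'   \code{vertices} and \code{adjacency} (list of integer neighbor indices).
#' @export
sphere_sampling <- function(vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  n <- nrow(vertices)
  if (n < 4L) stop("need at least 4 sampling vertices")
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("sampling vertices must be unit vectors")
  vertices <- vertices / nrm
  adj <- hull_adjacency(vertices)
  deg <- lengths(adj)
  if (any(deg < 3L)) stop("degenerate sampling: vertex with fewer than 3 hull neighbors")
  structure(list(vertices = vertices, adjacency = adj),
            class = "sphere_sampling")
}

# convex-hull edge adjacency by brute-force facet enumeration
hull_adjacency <- function(v) {
  n <- nrow(v)
  adj <- lapply(seq_len(n), function(i) integer(0))
  tol <- 1e-9
  trips <- utils::combn(n, 3L)
  for (t in seq_len(ncol(trips))) {
    i <- trips[1L, t]; j <- trips[2L, t]; k <- trips[3L, t]
    nrm <- crossprod3(v[j, ] - v[i, ], v[k, ] - v[i, ])
    if (sum(nrm * nrm) < 1e-18) next            # collinear triple
    s <- v %*% nrm - sum(nrm * v[i, ])
    if (all(s <= tol) || all(s >= -tol)) {
      adj[[i]] <- c(adj[[i]], j, k)
      adj[[j]] <- c(adj[[j]], i, k)
      adj[[k]] <- c(adj[[k]], i, j)
    }
  }
  lapply(adj, function(a) sort(unique(a)))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.sphere_sampling <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("sphere_sampling: %d vertices, hull adjacency degrees %d-%d\n",
              nrow(x$vertices), min(deg), max(deg)))
  invisible(x)
}

#' Near-uniform antipodally symmetric sampling of the sphere
#'
#' A Fibonacci lattice on the upper hemisphere, mirrored through the
#' origin. Antipodal symmetry matches diffusion sampling schemes (the
#' signal is axial), and guarantees the two maxima of an axial peak are
#' exact antipodes, so they merge into one fiber axis.
#'
#' @param n total number of vertices, even (default 64, a common HARDI
#'   shell size).
#' @return a \code{\link{sphere_sampling}}.
#' @export
fibonacci_sphere <- function(n = 64L) {
  n <- as.integer(n)
  if (n < 8L || n %% 2L != 0L) stop("n must be an even integer >= 8")
  m <- n %/% 2L
  i <- seq_len(m) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / m
  r <- sqrt(pmax(0, 1 - z^2))
  upper <- cbind(r * cos(phi), r * sin(phi), z)
  sphere_sampling(rbind(upper, -upper))
}

#' ODF field: per-voxel spherical samples over a grid
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param sampling a \code{\link{sphere_sampling}} with N vertices.
#' @param values 4-D numeric array (nx, ny, nz, N) of non-negative samples.
#' @return object of class \code{odf_field}.
#' @export
odf_field <- function(grid, sampling, values) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(sampling, "sphere_sampling"))
  expected <- c(grid$dims, nrow(sampling$vertices))
  if (!identical(dim(values), as.integer(expected)))
    stop("ODF value array must have shape (nx, ny, nz, N)")
  if (any(values < 0)) stop("ODF samples must be non-negative")
  structure(list(grid = grid, sampling = sampling, values = values),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat(sprintf("odf_field: %s grid, %d samples/voxel\n",
              paste(x$grid$dims, collapse = " x "), nrow(x$sampling$vertices)))
  invisible(x)
}

#' Mean-thresholded local maxima of one voxel's ODF samples
#'
#' A vertex is retained if its value is a strict local maximum over its hull
#' neighborhood AND strictly above the mean of all samples in the voxel.
#' Near-antipodal duplicates (axial angle < 5 degrees) are merged, keeping
#' the larger value; the retained values are normalized to per-voxel
#' probabilities summing to 1, sorted by descending probability.
#'
#' @param values length-N non-negative numeric, one per sampling vertex.
#' @param sampling the \code{\link{sphere_sampling}}.
#' @return a \code{\link{direction_set}} (possibly empty: e.g. a constant
#'   profile has no strict maxima above its mean).
#' @export
local_maxima_above_mean <- function(values, sampling) {
  n <- nrow(sampling$vertices)
  if (length(values) != n) stop("values length does not match sampling")
  if (n == 0L || anyNA(values)) stop("invalid ODF values (empty or NaN)")
  mu <- mean(values)
  is_peak <- vapply(seq_len(n), function(i) {
    values[i] > mu && all(values[i] > values[sampling$adjacency[[i]]])
  }, logical(1))
  idx <- which(is_peak)
  if (!length(idx)) return(empty_direction_set())
  # antipodal merge: keep the larger-valued member of each axis pair
  ord <- idx[order(values[idx], decreasing = TRUE)]
  kept <- integer(0)
  merge_tol <- 5 * pi / 180
  for (i in ord) {
    dup <- FALSE
    for (j in kept)
      if (axial_angle(sampling$vertices[i, ], sampling$vertices[j, ]) < merge_tol) {
        dup <- TRUE; break
      }
    if (!dup) kept <- c(kept, i)
  }
  d <- values[kept] / sum(values[kept])
  o <- order(d, decreasing = TRUE)
  direction_set(sampling$vertices[kept[o], , drop = FALSE], d[o])
}

#' Generalized fractional anisotropy of one voxel's ODF samples
#'
#' The standard deviation / root-mean-square contrast of the spherical
#' samples: \eqn{\sqrt{N \sum_i (\psi_i - \bar\psi)^2 / ((N-1)\sum_i \psi_i^2)}},
#' clipped to [0,1]. Scale-invariant; 0 for an isotropic (constant) profile.
#'
#' @param values length-N non-negative numeric, not all zero.
#' @return scalar in [0,1].
#' @export
generalized_fa <- function(values) {
  if (!length(values) || anyNA(values)) stop("invalid ODF values")
  ss <- sum(values^2)
  if (ss <= 0) stop("all-zero ODF profile has no defined anisotropy")
  n <- length(values)
  g <- sqrt(n * sum((values - mean(values))^2) / ((n - 1) * ss))
  min(1, max(0, g))
}

#' Transform an ODF field into a vector field
#'
#' Applies \code{\link{local_maxima_above_mean}} voxelwise (inside the white
#' matter mask when one is given; masked-out voxels get empty direction
#' sets). Attaches the supplied FA volume, or a generalized-FA volume
#' computed from the ODF samples when none is given.
#'
#' @param odf an \code{\link{odf_field}}.
#' @param fa optional FA array matching the grid.
#' @param wm_mask optional logical array matching the grid.
#' @return a \code{\link{vector_field}}.
#' @export
build_vector_field <- function(odf, fa = NULL, wm_mask = NULL) {
  grid <- odf$grid
  dims <- grid$dims
  if (!is.null(fa) && !identical(dim(fa), as.integer(dims)))
    stop("FA volume shape mismatch")
  if (!is.null(wm_mask) && !identical(dim(wm_mask), as.integer(dims)))
    stop("mask shape mismatch")
  peaks <- vector("list", prod(dims))
  compute_fa <- is.null(fa)
  if (compute_fa) fa <- array(0, dims)
  for (k in seq_len(dims[3]) - 1L)
    for (j in seq_len(dims[2]) - 1L)
      for (i in seq_len(dims[1]) - 1L) {
        li <- linear_index(grid, c(i, j, k))
        vals <- odf$values[i + 1L, j + 1L, k + 1L, ]
        if (!is.null(wm_mask) && !isTRUE(wm_mask[i + 1L, j + 1L, k + 1L])) {
          peaks[[li]] <- empty_direction_set()
        } else {
          peaks[[li]] <- local_maxima_above_mean(vals, odf$sampling)
        }
        if (compute_fa)
          fa[i + 1L, j + 1L, k + 1L] <-
            if (sum(vals^2) > 0) generalized_fa(vals) else 0
      }
  vector_field(grid, peaks, fa = fa, wm_mask = wm_mask)
}
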