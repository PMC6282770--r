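# Independent oracles used by the test suite. These deliberately re-derive
# quantities by different algorithms than the package internals.

# de Boor's pointwise algorithm (repeated affine interpolation of control
# points) for NON-rational B-splines; independent of the basis-function
# route used by nurbs_eval.
deboor_point <- function(knots, degree, ctrl, u) {
  p <- degree
  # 0-based span index k: knots[k] <= u < knots[k+1]
  k0 <- if (u >= 1) max(which(knots < 1)) - 1L else max(which(knots <= u)) - 1L
  d <- ctrl[(k0 - p + 1L):(k0 + 1L), , drop = FALSE]  # rows j = 0..p
  for (r in seq_len(p))
    for (j in p:r) {
      i <- j + k0 - p        # 0-based knot position
      den <- knots[i + p - r + 1L + 1L] - knots[i + 1L]
      alpha <- (u - knots[i + 1L]) / den
      d[j + 1L, ] <- (1 - alpha) * d[j, ] + alpha * d[j + 1L, ]
    }
  d[p + 1L, ]
}

# brute-force line/box intersection: intersect the center line with all six
# facet planes, keep points lying inside their facet
bruteforce_box_intersections <- function(grid, voxel, direction) {
  lo <- grid$origin + voxel * grid$voxel_size
  hi <- lo + grid$voxel_size
  c0 <- voxel_center(grid, voxel)
  hits <- NULL
  for (ax in 1:3)
    for (plane in c(lo[ax], hi[ax])) {
      if (abs(direction[ax]) < 1e-12) next
      t <- (plane - c0[ax]) / direction[ax]
      pt <- c0 + t * direction
      others <- setdiff(1:3, ax)
      if (all(pt[others] >= lo[others] - 1e-9) &&
          all(pt[others] <= hi[others] + 1e-9))
        hits <- rbind(hits, c(t, pt))
    }
  hits <- hits[order(hits[, 1]), , drop = FALSE]
  list(entry = hits[1L, 2:4], exit = hits[nrow(hits), 2:4])
}

# brute-force 26-neighborhood by explicit triple loop
bruteforce_neighbors <- function(grid, idx) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    v <- idx + c(dx, dy, dz)
    if (all(v >= 0) && all(v < grid$dims)) out <- rbind(out, v)
  }
  if (is.null(out)) return(matrix(integer(0), 0L, 3L))
  out <- out[do.call(order, as.data.frame(out)), , drop = FALSE]
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

# numeric minimization oracle for point-to-line distance
numeric_line_distance <- function(p, a, u) {
  f <- function(t) sqrt(sum((p - a - t * u)^2))
  stats::optimize(f, lower = -1e3, upper = 1e3, tol = 1e-12)$objective
}

# exhaustive greedy chain oracle: from a seed node, enumerate at every step
# ALL (neighbor, direction) pairs of the full 3x3x3 block and apply the
# documented constraints and ranking directly; independent loop-based
# re-implementation of the per-step selection.
oracle_chain <- function(seed, seed_dir, field, params, L_budget = NULL) {
  grid <- field$grid
  d_th <- if (is.na(params$d_th)) 0.5 * sqrt(sum(grid$voxel_size^2)) else params$d_th
  theta_max <- params$theta_th * pi / 180
  if (is.null(L_budget)) L_budget <- params$L_th
  vox <- seed
  dir <- seed_dir / sqrt(sum(seed_dir^2))
  visited <- list(paste(seed, collapse = ","))
  path <- list(list(voxel = vox, dir = dir))
  total <- 0
  repeat {
    ctr <- grid$origin + (vox + 0.5) * grid$voxel_size
    best <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- vox + c(dx, dy, dz)
      if (any(nb < 0) || any(nb >= grid$dims)) next
      if (paste(nb, collapse = ",") %in% visited) next
      nctr <- grid$origin + (nb + 0.5) * grid$voxel_size
      off <- nctr - ctr
      if (sum(off * dir) <= 0) next
      if (!is.null(field$wm_mask) && !field$wm_mask[nb[1]+1, nb[2]+1, nb[3]+1]) next
      if (!is.null(field$fa) && field$fa[nb[1]+1, nb[2]+1, nb[3]+1] < params$FA_th) next
      ld <- sqrt(max(0, sum(off^2) - sum(off * dir)^2))
      if (ld >= d_th) next
      ds <- field_peaks_at(field, nb)
      if (!nrow(ds$directions)) next
      for (q in seq_len(nrow(ds$directions))) {
        v <- ds$directions[q, ]
        ang <- acos(min(1, abs(sum(v * dir))))
        if (ang > theta_max + 1e-12) next
        cand <- list(voxel = nb, dir = v, d = ds$d[q], ang = ang, ldist = ld)
        if (is.null(best)) { best <- cand; next }
        better <- FALSE
        if (cand$ldist < best$ldist - 1e-9) better <- TRUE
        else if (abs(cand$ldist - best$ldist) <= 1e-9) {
          if (cand$ang < best$ang - 1e-9) better <- TRUE
          else if (abs(cand$ang - best$ang) <= 1e-9) {
            if (cand$d > best$d + 1e-9) better <- TRUE
            else if (abs(cand$d - best$d) <= 1e-9) {
              ck <- paste(sprintf("%09d", cand$voxel), collapse = ",")
              bk <- paste(sprintf("%09d", best$voxel), collapse = ",")
              if (ck < bk) better <- TRUE
            }
          }
        }
        if (better) best <- cand
      }
    }
    if (is.null(best)) break
    step_len <- sqrt(sum(((best$voxel - vox) * grid$voxel_size)^2))
    if (total + step_len > L_budget) break
    total <- total + step_len
    v <- best$dir
    if (sum(v * dir) < 0) v <- -v
    vox <- best$voxel; dir <- v
    visited <- c(visited, paste(vox, collapse = ","))
    path[[length(path) + 1L]] <- list(voxel = vox, dir = dir)
  }
  path
}

# random tiny vector field for oracle comparisons
random_tiny_field <- function(seed) {
  set.seed(seed)
  dims <- sample(3:6, 3, replace = TRUE)
  grid <- voxel_grid(dims, voxel_size = sample(c(1, 2), 1))
  peaks <- vector("list", prod(dims))
  for (i in seq_along(peaks)) {
    nd <- sample(0:2, 1, prob = c(0.25, 0.5, 0.25))
    peaks[[i]] <- if (nd == 0) direction_set(matrix(0, 0, 3), numeric(0))
    else {
      m <- matrix(rnorm(3 * nd), nd, 3)
      m <- m / sqrt(rowSums(m^2))
      d <- runif(nd, 0.2, 1); d <- d / sum(d)
      direction_set(m, d)
    }
  }
  fa <- array(runif(prod(dims), 0.05, 0.9), dims)
  vector_field(grid, peaks, fa = fa)
}

# first seed voxel of a field that satisfies the chain preconditions
first_valid_seed <- function(field, params) {
  dims <- field$grid$dims
  for (k in seq_len(dims[3]) - 1L)
    for (j in seq_len(dims[2]) - 1L)
      for (i in seq_len(dims[1]) - 1L) {
        ds <- field_peaks_at(field, c(i, j, k))
        if (nrow(ds$directions) &&
            field$fa[i + 1, j + 1, k + 1] >= params$FA_th)
          return(c(i, j, k))
      }
  NULL
}

# straight uniform field along +x on an n^3 grid (1 mm voxels)
straight_field <- function(n = 20L, fa = 0.8) {
  grid <- voxel_grid(c(n, n, n), 1)
  ds <- direction_set(matrix(c(1, 0, 0), 1), 1)
  peaks <- rep(list(ds), n^3)
  vector_field(grid, peaks, fa = array(fa, c(n, n, n)))
}
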