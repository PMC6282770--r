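#' Intersections of a center line with a voxel's boundary box
#'
#' The line through the voxel center along a diffusion direction always
#' crosses the voxel's axis-aligned boundary in exactly two points
#' (slab/ray-box method). The entry point lies on the -direction side, the
#' exit on the +direction side.
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param voxel 0-based integer triple.
#' @param direction unit 3-vector.
#' @return list with \code{entry} and \code{exit}, each a 3-vector, mm.
#' @export
voxel_line_intersections <- function(grid, voxel, direction) {
  voxel <- grid_check_index(grid, voxel)
  u <- as.numeric(direction)
  if (abs(sum(u^2) - 1) > 1e-9) stop("direction must be unit length")
  lo <- grid$origin + voxel * grid$voxel_size
  hi <- lo + grid$voxel_size
  c0 <- voxel_center(grid, voxel)
  # slab method: parametric t along c0 + t*u against each axis slab
  t_lo <- rep(-Inf, 3); t_hi <- rep(Inf, 3)
  for (ax in 1:3) {
    if (abs(u[ax]) > 1e-300) {
      t1 <- (lo[ax] - c0[ax]) / u[ax]
      t2 <- (hi[ax] - c0[ax]) / u[ax]
      t_lo[ax] <- min(t1, t2); t_hi[ax] <- max(t1, t2)
    }
  }
  t_in <- max(t_lo); t_out <- min(t_hi)
  list(entry = c0 + t_in * u, exit = c0 + t_out * u)
}

#' Control sequence: ordered control points with weights and provenance
#' @keywords internal
control_sequence <- function(points, node_of, provenance) {
  structure(list(points = points, node_of = node_of, provenance = provenance),
            class = "control_sequence")
}

#' @export
print.control_sequence <- function(x, ...) {
  cat("control_sequence:", nrow(x$points), "points (",
      paste(sprintf("%s=%d", names(table(x$provenance)), table(x$provenance)),
            collapse = ", "), ")\n")
  invisible(x)
}

# shared engine for the two control-point constructions.
# with_centers: tangent-consistent mode inserts the voxel center between
# entry and exit, making each node's triple collinear along its diffusion
# direction, so the control polygon is locally parallel to the fiber axis.
# Each crossing between consecutive voxels contributes ONE control point:
# the exit of node k and the entry of node k+1 both estimate that crossing,
# so they are unified into their midpoint (for exactly collinear chains the
# two coincide on the shared facet and the midpoint IS that point).
chain_control_points <- function(chain, grid, with_centers) {
  if (!length(chain$nodes)) stop("cannot build control points of an empty chain")
  pts <- NULL; node_of <- integer(0); prov <- character(0)
  # node_of: index of the source node; unified crossing points keep a second
  # attribution in merged_with
  merged_with <- integer(0)
  for (k in seq_along(chain$nodes)) {
    nd <- chain$nodes[[k]]
    io <- voxel_line_intersections(grid, nd$voxel, nd$direction)
    block_pts <- if (with_centers)
      rbind(io$entry, voxel_center(grid, nd$voxel), io$exit)
    else rbind(io$entry, io$exit)
    block_prov <- if (with_centers) c("entry", "center", "exit") else c("entry", "exit")
    for (b in seq_len(nrow(block_pts))) {
      if (k > 1L && b == 1L) {
        # unify this node's entry with the previous node's exit
        pts[nrow(pts), ] <- (pts[nrow(pts), ] + block_pts[b, ]) / 2
        merged_with[nrow(pts)] <- k
        next
      }
      pts <- rbind(pts, block_pts[b, ])
      node_of <- c(node_of, k)
      prov <- c(prov, block_prov[b])
      merged_with <- c(merged_with, NA_integer_)
    }
  }
  rownames(pts) <- NULL
  cs <- control_sequence(pts, node_of, prov)
  cs$merged_with <- merged_with
  cs
}

#' Control points for tangent-consistent (NURBS-T) fitting
#'
#' Per chain node: the entry intersection, the voxel center, and the exit
#' intersection of the node's direction line with the voxel box. Entry,
#' center and exit are collinear along the diffusion direction, so the
#' control polygon runs parallel to the fiber axis through every voxel
#' center, realizing the premise that a pathway's local tangent agrees with
#' the diffusion orientation. The exit of each node and the entry of the
#' next are unified into one crossing point (their midpoint; coincident for
#' collinear chains).
#'
#' @param chain a \code{\link{direction_chain}}.
#' @param grid the \code{\link{voxel_grid}}.
#' @return a \code{control_sequence}.
#' @export
control_points_tangent <- function(chain, grid) {
  chain_control_points(chain, grid, with_centers = TRUE)
}

#' Control points for general (NURBS-G) fitting
#'
#' Per chain node: only the entry and exit intersections of the direction
#' line with the voxel box (no centers, no tangency construction);
#' consecutive crossings unified as in \code{\link{control_points_tangent}}.
#'
#' @inheritParams control_points_tangent
#' @return a \code{control_sequence}.
#' @export
control_points_general <- function(chain, grid) {
  chain_control_points(chain, grid, with_centers = FALSE)
}

#' Convert diffusion probabilities into rational weights
#'
#' Every control point inherits the diffusion probability d of its source
#' node; a merged facet point shared by nodes k and k+1 receives the average
#' (d_k + d_{k+1})/2. The weight vector is then normalized so its maximum is
#' 1 (the scale of rational weights is immaterial to the fitted curve).
#'
#' @param chain the source \code{\link{direction_chain}}.
#' @param sequence a \code{control_sequence} built from \code{chain}.
#' @return numeric weights in (0, 1], one per control point.
#' @export
convert_weights <- function(chain, sequence) {
  d <- vapply(chain$nodes, function(n) n$probability, numeric(1))
  if (any(d <= 0)) stop("all diffusion probabilities must be > 0")
  w <- d[sequence$node_of]
  if (!is.null(sequence$merged_with)) {
    m <- which(!is.na(sequence$merged_with))
    if (length(m))
      w[m] <- (d[sequence$node_of[m]] + d[sequence$merged_with[m]]) / 2
  }
  w / max(w)
}

# fit one chain into a NURBS curve under the given mode; NULL when the chain
# yields fewer than 2 control points. Cubic by default, degree reduced to
# n_ctrl - 1 for short chains.
fit_chain_curve <- function(chain, grid, mode) {
  cs <- if (mode == "nurbs_t") control_points_tangent(chain, grid)
        else control_points_general(chain, grid)
  n_ctrl <- nrow(cs$points)
  if (n_ctrl < 2L) return(NULL)
  w <- convert_weights(chain, cs)
  degree <- min(3L, n_ctrl - 1L)
  nurbs_curve(cs$points, w, degree = degree)
}

#' Track fiber pathways by NURBS curve fitting
#'
#' For every seed voxel: chains are extracted bidirectionally for each of
#' the voxel's diffusion directions, control points are built according to
#' the mode (\code{"nurbs_t"}: facet intersections + voxel centers;
#' \code{"nurbs_g"}: intersections only), diffusion probabilities are
#' converted to rational weights, and the resulting NURBS curve is sampled
#' at the output step. Seeds that fail the mask/FA/direction preconditions
#' are skipped with a warning; chains too short to fit are dropped. Output
#' order is deterministic: seed order, then seed-direction index.
#'
#' @param seeds integer matrix of 0-based voxel triples (one per row), or a
#'   single triple.
#' @param field a \code{\link{vector_field}}.
#' @param params a \code{\link{tracking_params}} with mode
#'   \code{"nurbs_t"} or \code{"nurbs_g"}.
#' @return a \code{\link{tractogram}}.
#' @export
track_fibers <- function(seeds, field, params = tracking_params()) {
  if (params$mode == "streamline") return(track_streamline(seeds, field, params))
  seeds <- seed_matrix(seeds)
  out <- list()
  n_skipped <- 0L
  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    if (!seed_ok(seed, field, params)) { n_skipped <- n_skipped + 1L; next }
    chains <- bidirectional_chains(seed, field, params)
    for (ch in chains) {
      curve <- fit_chain_curve(ch, field$grid, params$mode)
      if (is.null(curve)) next
      out[[length(out) + 1L]] <-
        sample_pathway(curve, params$step, seed_voxel = seed,
                       termination_reason = ch$termination_reason)
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " seed(s) rejected (outside mask, below FA_th, or no direction)")
  tractogram(out, grid = field$grid)
}

seed_matrix <- function(seeds) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3L, byrow = TRUE)
  storage.mode(seeds) <- "integer"
  seeds
}

seed_ok <- function(seed, field, params) {
  ds <- tryCatch(field_peaks_at(field, seed), error = function(e) NULL)
  if (is.null(ds) || !nrow(ds$directions)) return(FALSE)
  if (!field_in_mask(field, seed)) return(FALSE)
  fa <- field_fa_at(field, seed)
  if (!is.na(fa) && fa < params$FA_th) return(FALSE)
  TRUE
}

#' Multidirectional streamline tracking (baseline)
#'
#' Fixed-step integration: from the current position, the direction of the
#' containing voxel with the smallest axial angle to the current heading is
#' followed for one step (default 0.02 mm), under the same stopping rules as
#' chain extraction (axial angle <= theta_th, cumulative length <= L_th,
#' FA >= FA_th, white-matter mask, grid bounds). Launched bidirectionally,
#' one pathway per seed-voxel direction, each side on half the length
#' budget.
#'
#' @inheritParams track_fibers
#' @param integration_step integration step, mm (default 0.02).
#' @return a \code{\link{tractogram}}.
#' @export
track_streamline <- function(seeds, field, params = tracking_params(mode = "streamline"),
                             integration_step = 0.02) {
  seeds <- seed_matrix(seeds)
  out <- list()
  n_skipped <- 0L
  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    if (!seed_ok(seed, field, params)) { n_skipped <- n_skipped + 1L; next }
    ds <- field_peaks_at(field, seed)
    for (q in seq_len(nrow(ds$directions))) {
      v <- ds$directions[q, ]
      fwd <- streamline_one_side(seed, v, field, params, integration_step,
                                 params$L_th / 2)
      back <- streamline_one_side(seed, -v, field, params, integration_step,
                                  params$L_th / 2)
      pts <- rbind(back$points[rev(seq_len(nrow(back$points))), , drop = FALSE],
                   fwd$points[-1L, , drop = FALSE])
      if (nrow(pts) < 2L) next
      out[[length(out) + 1L]] <-
        pathway(pts, seed_voxel = seed,
                termination_reason = c(back$reason, fwd$reason))
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " seed(s) rejected (outside mask, below FA_th, or no direction)")
  tractogram(out, grid = field$grid)
}

streamline_one_side <- function(seed, v0, field, params, h, budget) {
  grid <- field$grid
  pos <- voxel_center(grid, seed)
  heading <- normalize(v0)
  pts <- matrix(NA_real_, floor(budget / h) + 2L, 3L)
  pts[1L, ] <- pos
  n_pts <- 1L
  total <- 0
  theta_max <- params$theta_th * pi / 180
  reason <- "no_candidate"
  repeat {
    if (total + h > budget) { reason <- "length"; break }
    nxt <- pos + h * heading
    vox <- world_to_voxel(grid, nxt)
    if (anyNA(vox)) { reason <- "mask_exit"; break }
    if (!field_in_mask(field, vox)) { reason <- "mask_exit"; break }
    fa <- field_fa_at(field, vox)
    if (!is.na(fa) && fa < params$FA_th) { reason <- "fa"; break }
    ds <- field_peaks_at(field, vox)
    if (!nrow(ds$directions)) { reason <- "no_candidate"; break }
    angs <- vapply(seq_len(nrow(ds$directions)), function(q)
      axial_angle(heading, ds$directions[q, ]), numeric(1))
    qbest <- which.min(angs)
    if (angs[qbest] > theta_max) { reason <- "angle"; break }
    v <- ds$directions[qbest, ]
    if (sum(v * heading) < 0) v <- -v
    heading <- v
    pos <- nxt
    total <- total + h
    n_pts <- n_pts + 1L
    pts[n_pts, ] <- pos
  }
  list(points = pts[seq_len(n_pts), , drop = FALSE], reason = reason)
}
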