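#' Synthetic fiber phantom specification
#'
#' Describes a voxel grid carrying one or two analytically known fiber
#' bundles. Supported geometries: a straight bundle along x, a circular arc,
#' a helix, two bundles crossing at a configurable angle, and a single
#' bundle with a sharp bend. All curves are constant-speed parametric curves
#' in mm world coordinates, placed centrally with a one-voxel margin.
#'
#' @param kind one of \code{"straight"}, \code{"arc"}, \code{"helix"},
#'   \code{"crossing"}, \code{"bend"}.
#' @param grid a \code{\link{voxel_grid}} (default 20 x 20 x 20, 1 mm).
#' @param radius arc/helix radius, mm.
#' @param pitch helix pitch (z advance per turn), mm.
#' @param arc_span arc angular span, degrees.
#' @param crossing_angle angle between the two crossing bundles, degrees.
#' @param bend_angle turning angle at the bend, degrees.
#' @param odf_sharpness concentration of the axial ODF kernel (> 0).
#' @param noise_sigma relative ODF noise level (>= 0).
#' @param seed integer RNG seed fixing all phantom randomness.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(kind = c("straight", "arc", "helix", "crossing", "bend"),
                         grid = voxel_grid(c(20, 20, 20), 1),
                         radius = 10, pitch = 8, arc_span = 90,
                         crossing_angle = 90, bend_angle = 60,
                         odf_sharpness = 40, noise_sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(odf_sharpness > 0, noise_sigma >= 0, radius > 0)
  spec <- structure(list(kind = kind, grid = grid, radius = radius,
                         pitch = pitch, arc_span = arc_span,
                         crossing_angle = crossing_angle,
                         bend_angle = bend_angle,
                         odf_sharpness = odf_sharpness,
                         noise_sigma = noise_sigma, seed = as.integer(seed)),
                    class = "phantom_spec")
  spec$curves <- phantom_curves(spec)   # errors here if geometry does not fit
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, %s grid, %d bundle(s), kappa=%g, noise=%g, seed=%d\n",
              x$kind, paste(x$grid$dims, collapse = "x"), length(x$curves),
              x$odf_sharpness, x$noise_sigma, x$seed))
  invisible(x)
}

# each curve: list(point = f(t), tangent = f(t), length = mm), t in [0,1]
# at constant speed
phantom_curves <- function(spec) {
  g <- spec$grid
  lo <- g$origin
  hi <- g$origin + g$dims * g$voxel_size
  # anchor geometry on the center of the central voxel, so straight bundle
  # axes run through voxel centers rather than along voxel boundaries
  ctr <- g$origin + (floor((g$dims - 1L) / 2) + 0.5) * g$voxel_size
  margin <- g$voxel_size          # one voxel of clearance per axis
  seg_curve <- function(a, b) {
    len <- sqrt(sum((b - a)^2))
    u <- (b - a) / len
    list(point = function(t) a + t * len * u,
         tangent = function(t) u,
         length = len)
  }
  curves <- switch(spec$kind,
    straight = list(seg_curve(c(lo[1] + margin[1], ctr[2], ctr[3]),
                              c(hi[1] - margin[1], ctr[2], ctr[3]))),
    crossing = {
      a <- spec$crossing_angle * pi / 180
      u2 <- c(cos(a), sin(a), 0)
      half <- min((hi - lo) / 2 - margin)
      list(seg_curve(c(ctr[1] - half, ctr[2], ctr[3]),
                     c(ctr[1] + half, ctr[2], ctr[3])),
           seg_curve(ctr - half * u2, ctr + half * u2))
    },
    bend = {
      b <- spec$bend_angle * pi / 180
      u2 <- c(cos(b), sin(b), 0)
      half <- min((hi - lo) / 2 - margin) * 0.9
      a0 <- ctr - c(half, 0, 0)
      a1 <- ctr
      a2 <- ctr + half * u2
      l1 <- half; l2 <- half
      len <- l1 + l2
      list(list(
        point = function(t) {
          s <- t * len
          if (s <= l1) a0 + s * c(1, 0, 0) else a1 + (s - l1) * u2
        },
        tangent = function(t) if (t * len <= l1) c(1, 0, 0) else u2,
        length = len))
    },
    arc = {
      r <- spec$radius
      span <- spec$arc_span * pi / 180
      cc <- ctr - c(0, r / 2, 0)    # apex at ctr + (0, r/2, 0)
      list(list(
        point = function(t) {
          th <- (t - 0.5) * span
          cc + r * c(sin(th), cos(th), 0)
        },
        tangent = function(t) {
          th <- (t - 0.5) * span
          c(cos(th), -sin(th), 0)
        },
        length = r * span))
    },
    helix = {
      r <- spec$radius
      p <- spec$pitch
      z0 <- lo[3] + margin[3]; z1 <- hi[3] - margin[3]
      turns <- (z1 - z0) / p
      om <- 2 * pi * turns
      speed <- sqrt((r * om)^2 + (z1 - z0)^2)
      list(list(
        point = function(t) c(ctr[1] + r * cos(om * t),
                              ctr[2] + r * sin(om * t),
                              z0 + t * (z1 - z0)),
        tangent = function(t) c(-r * om * sin(om * t), r * om * cos(om * t),
                                z1 - z0) / speed,
        length = speed))
    })
  # geometry must fit inside the grid
  for (cv in curves) {
    ts <- seq(0, 1, length.out = 257)
    pts <- t(vapply(ts, cv$point, numeric(3)))
    if (any(sweep(pts, 2L, lo, "<")) || any(sweep(pts, 2L, hi, ">")))
      stop("phantom geometry exceeds the grid")
  }
  curves
}

#' Generate the phantom's vector field and ground truth
#'
#' Voxels threaded by a truth curve (centers within half a voxel diagonal
#' of the curve, with no overhang past the curve ends) receive that curve's
#' unit tangent at the nearest point, with diffusion probability
#' proportional to proximity (normalized per voxel); voxels reached by both
#' bundles of a crossing carry both directions. The white-matter mask and
#' the high-FA region are the wider tube within one full voxel diagonal of
#' the curves (FA 0.8 inside, 0.05 outside), so fitted pathways that cut
#' staircase corners stay in-mask; endpoint ROIs are two-voxel-deep caps at
#' each curve end. Fully deterministic.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{field} (a \code{\link{vector_field}}) and
#'   \code{truth} (a \code{\link{bundle_truth}}).
#' @export
generate_field <- function(spec) {
  g <- spec$grid
  # direction support: voxels whose centers the curve passes within half a
  # voxel diagonal -- the voxels the curve actually threads. The
  # white-matter mask / high-FA region is the wider tube within one full
  # voxel diagonal, so smoothed pathways that cut staircase corners remain
  # inside the mask.
  diag_len <- 0.5 * sqrt(sum(g$voxel_size^2))
  mask_rad <- sqrt(sum(g$voxel_size^2))
  dims <- g$dims
  nvox <- prod(dims)
  peaks <- vector("list", nvox)
  fa <- array(0.05, dims)
  mask <- array(FALSE, dims)
  roi_caps <- lapply(spec$curves, function(cv)
    list(array(FALSE, dims), array(FALSE, dims)))
  cap_depth <- 2 * max(g$voxel_size)
  ends <- lapply(spec$curves, function(cv) list(cv$point(0), cv$point(1)))

  # voxel centers in linear-index order (x fastest)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  centers <- sweep(sweep(idx + 0.5, 2L, g$voxel_size, "*"), 2L, g$origin, "+")

  # per-voxel accumulators of (direction, weight) contributions
  dir_acc <- vector("list", nvox)
  for (b in seq_along(spec$curves)) {
    cv <- spec$curves[[b]]
    n_s <- max(257L, as.integer(ceiling(cv$length / (0.25 * min(g$voxel_size)))) + 1L)
    ts <- seq(0, 1, length.out = n_s)
    S <- t(vapply(ts, cv$point, numeric(3)))
    spacing <- cv$length / (n_s - 1L)
    # vectorized coarse nearest-sample scan, chunked to bound memory
    coarse_d <- numeric(nvox); coarse_i <- integer(nvox)
    ssq <- rowSums(S^2)
    chunk <- 4096L
    for (start in seq(1L, nvox, by = chunk)) {
      rows <- start:min(nvox, start + chunk - 1L)
      cc <- centers[rows, , drop = FALSE]
      d2 <- outer(rowSums(cc^2), ssq, "+") - 2 * (cc %*% t(S))
      ci <- max.col(-d2, ties.method = "first")
      coarse_i[rows] <- ci
      coarse_d[rows] <- sqrt(pmax(0, d2[cbind(seq_along(rows), ci)]))
    }
    near <- which(coarse_d < mask_rad + spacing)
    for (v in near) {
      ctr <- centers[v, ]
      i0 <- coarse_i[v]
      opt <- stats::optimize(function(t) sum((cv$point(t) - ctr)^2),
                             lower = ts[max(1L, i0 - 1L)],
                             upper = ts[min(n_s, i0 + 1L)], tol = 1e-12)
      dist <- sqrt(opt$objective)
      if (dist >= mask_rad) next
      fa[idx[v, 1] + 1L, idx[v, 2] + 1L, idx[v, 3] + 1L] <- 0.8
      mask[idx[v, 1] + 1L, idx[v, 2] + 1L, idx[v, 3] + 1L] <- TRUE
      for (side in 1:2)
        if (sqrt(sum((ends[[b]][[side]] - ctr)^2)) <= cap_depth)
          roi_caps[[b]][[side]][idx[v, 1] + 1L, idx[v, 2] + 1L, idx[v, 3] + 1L] <- TRUE
      if (dist >= diag_len) next
      # directions only on voxels the curve actually threads: the nearest
      # point must be interior, or a curve endpoint must lie strictly
      # inside this voxel (no overhang past the curve ends)
      if (opt$minimum < 1e-6 || opt$minimum > 1 - 1e-6) {
        ep <- if (opt$minimum < 0.5) ends[[b]][[1]] else ends[[b]][[2]]
        vlo <- g$origin + idx[v, ] * g$voxel_size
        vhi <- vlo + g$voxel_size
        if (any(ep <= vlo + 1e-9) || any(ep >= vhi - 1e-9)) next
      }
      tg <- normalize(cv$tangent(opt$minimum))
      w <- 1 - dist / diag_len
      dir_acc[[v]] <- rbind(dir_acc[[v]], c(tg, w))
    }
  }
  for (v in seq_len(nvox)) {
    acc <- dir_acc[[v]]
    if (is.null(acc)) { peaks[[v]] <- empty_direction_set(); next }
    dirs <- NULL; wts <- numeric(0)
    for (r in seq_len(nrow(acc))) {
      tg <- acc[r, 1:3]; w <- acc[r, 4]
      merged <- FALSE
      if (!is.null(dirs))
        for (q in seq_len(nrow(dirs)))
          if (axial_angle(dirs[q, ], tg) < 5 * pi / 180) {
            wts[q] <- wts[q] + w; merged <- TRUE; break
          }
      if (!merged) { dirs <- rbind(dirs, tg); wts <- c(wts, w) }
    }
    peaks[[v]] <- direction_set(dirs, wts / sum(wts))
  }
  # caps must be restricted to bundle support and pairwise disjoint
  taken <- array(FALSE, dims)
  for (b in seq_along(roi_caps))
    for (side in 1:2) {
      roi_caps[[b]][[side]] <- roi_caps[[b]][[side]] & mask & !taken
      taken <- taken | roi_caps[[b]][[side]]
    }
  field <- vector_field(g, peaks, fa = fa, wm_mask = mask)
  truth <- bundle_truth(truth_pathways(spec, step = 0.5),
                        roi_caps, wm_mask = mask, grid = g)
  list(field = field, truth = truth)
}

#' Analytic ground-truth pathways of a phantom
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param step sampling step along each curve, mm.
#' @return list of \code{\link{pathway}}s, one per bundle.
#' @export
truth_pathways <- function(spec, step = 0.5) {
  lapply(spec$curves, function(cv) {
    n <- max(2L, ceiling(cv$length / step) + 1L)
    ts <- seq(0, 1, length.out = n)
    pathway(t(vapply(ts, cv$point, numeric(3))),
            termination_reason = "length")
  })
}

#' Generate synthetic ODF samples for a phantom
#'
#' Per voxel, the ODF profile is a probability-weighted mixture over the
#' voxel's true fiber axes of the antipodally symmetric peaked kernel
#' \eqn{\exp(\kappa((v\cdot\mu)^2 - 1))}, evaluated at the sampling
#' vertices; voxels without fibers get an isotropic (constant) profile.
#' Multiplicative Gaussian noise with relative level \code{noise_sigma} is
#' added and negative samples are clipped at zero. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param sampling a \code{\link{sphere_sampling}}.
#' @return an \code{\link{odf_field}}.
#' @export
generate_odf <- function(spec, sampling = fibonacci_sphere(64L)) {
  if (spec$odf_sharpness <= 0) stop("odf_sharpness must be > 0")
  fld <- generate_field(spec)$field
  g <- spec$grid
  nvert <- nrow(sampling$vertices)
  vals <- array(0, c(g$dims, nvert))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  kap <- spec$odf_sharpness
  for (k in seq_len(g$dims[3]) - 1L)
    for (j in seq_len(g$dims[2]) - 1L)
      for (i in seq_len(g$dims[1]) - 1L) {
        ds <- fld$peaks[[linear_index(g, c(i, j, k))]]
        v <- if (is.null(ds) || !nrow(ds$directions)) rep(1, nvert)
        else {
          cosang <- sampling$vertices %*% t(ds$directions)   # N x naxes
          as.numeric(exp(kap * (cosang^2 - 1)) %*% ds$d)
        }
        if (spec$noise_sigma > 0)
          v <- pmax(0, v + stats::rnorm(nvert, 0, spec$noise_sigma * abs(v)))
        vals[i + 1L, j + 1L, k + 1L, ] <- v
      }
  odf_field(g, sampling, vals)
}
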