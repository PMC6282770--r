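# closest point on a polyline to p: returns squared distance, the segment
# index and the point itself
closest_on_polyline <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  ab <- b - a
  ap <- sweep(a, 2L, p, function(x, y) y - x)     # p - a per segment
  denom <- rowSums(ab^2)
  t <- ifelse(denom > 0, rowSums(ap * ab) / denom, 0)
  t <- pmin(1, pmax(0, t))
  proj <- a + ab * t
  d2 <- rowSums(sweep(proj, 2L, p)^2)
  i <- which.min(d2)
  list(d2 = d2[i], segment = i, point = proj[i, ], t = t[i])
}

check_pathway_pts <- function(x, min_pts) {
  x <- unclass(x)
  if (!is.matrix(x) || ncol(x) != 3L || nrow(x) < min_pts)
    stop("degenerate pathway: need at least ", min_pts, " points")
  x
}

# one-sided mean squared error of a pointwise quantity; fn(i, match) returns
# the squared discrepancy for estimated vertex i matched on the other curve
symmetric_rmse <- function(e, t, fn) {
  one_side <- function(from, to) {
    mean(vapply(seq_len(nrow(from)), function(i) {
      m <- closest_on_polyline(from[i, ], to)
      fn(from, i, to, m)
    }, numeric(1)))
  }
  sqrt((one_side(e, t) + one_side(t, e)) / 2)
}

#' Spatial metric: symmetric RMSE of point-to-curve distances (mm)
#'
#' For each vertex of one polyline, the Euclidean (L2) distance to the
#' nearest point of the other polyline (point-to-segment); the two
#' directed mean squared distances are averaged and square-rooted.
#'
#' @param estimated,truth pathways (m x 3 matrices, mm), >= 2 points each.
#' @return non-negative scalar, mm. 0 iff the polylines coincide.
#' @export
spatial_metric <- function(estimated, truth) {
  e <- check_pathway_pts(estimated, 2L)
  t <- check_pathway_pts(truth, 2L)
  symmetric_rmse(e, t, function(from, i, to, m) m$d2)
}

# finite-difference unit tangents at polyline vertices (central in the
# interior, one-sided at the ends)
polyline_tangents <- function(p) {
  n <- nrow(p)
  tg <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    a <- p[max(1L, i - 1L), ]
    b <- p[min(n, i + 1L), ]
    d <- b - a
    nrm <- sqrt(sum(d^2))
    tg[i, ] <- if (nrm > 0) d / nrm else c(1, 0, 0)
  }
  tg
}

#' Tangent metric: symmetric RMSE of axial tangent angles (radians)
#'
#' At each vertex of one polyline, the axial angle (orientation-free, in
#' [0, pi/2]) between its finite-difference unit tangent and the tangent of
#' the segment of the other polyline containing the matched closest point;
#' symmetric RMSE as in \code{\link{spatial_metric}}.
#'
#' @param estimated,truth pathways with >= 3 points each.
#' @return non-negative scalar, radians.
#' @export
tangent_metric <- function(estimated, truth) {
  e <- check_pathway_pts(estimated, 3L)
  t <- check_pathway_pts(truth, 3L)
  seg_tangent <- function(poly, seg) {
    d <- poly[seg + 1L, ] - poly[seg, ]
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) d / nrm else c(1, 0, 0)
  }
  one_side <- function(from, to) {
    tg <- polyline_tangents(from)
    mean(vapply(seq_len(nrow(from)), function(i) {
      m <- closest_on_polyline(from[i, ], to)
      axial_angle(tg[i, ], seg_tangent(to, m$segment))^2
    }, numeric(1)))
  }
  sqrt((one_side(e, t) + one_side(t, e)) / 2)
}

# discrete curvature at polyline vertices: inverse circumradius of each
# consecutive vertex triple (ends copy their neighbor)
polyline_curvature <- function(p) {
  n <- nrow(p)
  k <- numeric(n)
  for (i in 2:(n - 1L)) {
    A <- p[i - 1L, ]; B <- p[i, ]; C <- p[i + 1L, ]
    a <- sqrt(sum((B - C)^2)); b <- sqrt(sum((A - C)^2)); c <- sqrt(sum((A - B)^2))
    cr <- crossprod3(B - A, C - A)
    area2 <- sqrt(sum(cr^2))        # = 2 * triangle area
    k[i] <- if (a * b * c > 0) 2 * area2 / (a * b * c) else 0
  }
  k[1] <- k[2]; k[n] <- k[n - 1L]
  k
}

#' Curve metric: symmetric RMSE of curvature differences (1/mm)
#'
#' Discrete curvature at each vertex is the inverse radius of the circle
#' circumscribing the vertex and its two neighbors; each vertex's curvature
#' is compared with the curvature at the nearest vertex of the other
#' polyline, and the absolute differences enter a symmetric RMSE.
#'
#' @param estimated,truth pathways with >= 5 points each.
#' @return non-negative scalar, 1/mm.
#' @export
curve_metric <- function(estimated, truth) {
  e <- check_pathway_pts(estimated, 5L)
  t <- check_pathway_pts(truth, 5L)
  ke <- polyline_curvature(e); kt <- polyline_curvature(t)
  one_side <- function(from, kfrom, to, kto) {
    mean(vapply(seq_len(nrow(from)), function(i) {
      m <- closest_on_polyline(from[i, ], to)
      # curvature of the nearest vertex of the matched segment
      j <- if (m$t > 0.5) m$segment + 1L else m$segment
      (kfrom[i] - kto[j])^2
    }, numeric(1)))
  }
  sqrt((one_side(e, ke, t, kt) + one_side(t, kt, e, ke)) / 2)
}

#' Ground-truth bundle description for connectivity evaluation
#'
#' @param curves list of ground-truth \code{\link{pathway}}s, one per bundle.
#' @param endpoint_rois list (one per bundle) of two logical arrays marking
#'   the bundle's endpoint regions (voxel masks on the grid).
#' @param wm_mask logical array: white-matter support.
#' @param grid the \code{\link{voxel_grid}}.
#' @return object of class \code{bundle_truth}.
#' @export
bundle_truth <- function(curves, endpoint_rois, wm_mask, grid) {
  stopifnot(length(curves) == length(endpoint_rois))
  for (r in endpoint_rois) stopifnot(length(r) == 2L)
  structure(list(curves = curves, endpoint_rois = endpoint_rois,
                 wm_mask = wm_mask, grid = grid),
            class = "bundle_truth")
}

roi_lookup_table <- function(truth) {
  # flat list of ROIs with (bundle, side) labels; ROIs must be disjoint
  rois <- list(); lab <- NULL
  for (b in seq_along(truth$endpoint_rois))
    for (s in 1:2) {
      rois[[length(rois) + 1L]] <- truth$endpoint_rois[[b]][[s]]
      lab <- rbind(lab, c(b, s))
    }
  if (length(rois) > 1L) {
    tot <- Reduce(`+`, lapply(rois, function(r) r * 1L))
    if (any(tot > 1L)) stop("endpoint ROIs overlap")
  }
  list(rois = rois, lab = lab)
}

endpoint_roi_id <- function(point, grid, lut) {
  vox <- world_to_voxel(grid, point)
  if (anyNA(vox)) return(0L)
  for (r in seq_along(lut$rois))
    if (isTRUE(lut$rois[[r]][vox[1] + 1L, vox[2] + 1L, vox[3] + 1L]))
      return(r)
  0L
}

#' Global connectivity metrics: VC / IC / NC percentages, VB / IB counts
#'
#' Each pathway is classified by the ROIs containing its two endpoints.
#' An endpoint is attributed to the voxel the pathway reaches it through
#' (the point is nudged 1e-6 of the adjacent segment inward before the
#' half-open voxel lookup), so endpoints lying exactly on a voxel facet --
#' the normal case for curves built from facet intersection points -- stay
#' attached to their terminal voxel. Endpoints in the two ROIs of the same
#' bundle with the whole course inside the white-matter mask (tested at
#' every segment midpoint) form a valid connection; endpoints in ROIs of
#' two different bundles form an invalid connection; anything else is no
#' connection. The three classes partition the pathway set (percentages sum
#' to 100). VB counts distinct true bundles reached by at least one valid
#' connection; IB counts distinct wrong ROI pairs reached by at least one
#' invalid connection.
#'
#' @param pathways list of \code{\link{pathway}}s or a \code{\link{tractogram}}.
#' @param truth a \code{\link{bundle_truth}} with pairwise-disjoint ROIs.
#' @return object of class \code{metric_report}: list with \code{vc},
#'   \code{ic}, \code{nc} (percent), \code{vb}, \code{ib} (counts), and
#'   \code{class} (per-pathway label).
#' @export
connectivity_metrics <- function(pathways, truth) {
  if (inherits(pathways, "tractogram")) pathways <- pathways$pathways
  lut <- roi_lookup_table(truth)
  n <- length(pathways)
  cls <- character(n)
  vb <- integer(0); ib <- character(0)
  eps <- 1e-6
  for (i in seq_len(n)) {
    p <- unclass(pathways[[i]])
    m <- nrow(p)
    head_pt <- p[1L, ] + eps * (p[2L, ] - p[1L, ])
    tail_pt <- p[m, ] + eps * (p[m - 1L, ] - p[m, ])
    r1 <- endpoint_roi_id(head_pt, truth$grid, lut)
    r2 <- endpoint_roi_id(tail_pt, truth$grid, lut)
    if (r1 == 0L || r2 == 0L || r1 == r2) { cls[i] <- "nc"; next }
    b1 <- lut$lab[r1, 1]; b2 <- lut$lab[r2, 1]
    if (b1 == b2) {
      mids <- (p[-1L, , drop = FALSE] + p[-m, , drop = FALSE]) / 2
      inside <- all(apply(mids, 1L, function(pt) {
        vox <- world_to_voxel(truth$grid, pt)
        !anyNA(vox) &&
          isTRUE(truth$wm_mask[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L])
      }))
      if (inside) { cls[i] <- "vc"; vb <- union(vb, b1) } else cls[i] <- "nc"
    } else {
      cls[i] <- "ic"
      ib <- union(ib, paste(sort(c(r1, r2)), collapse = "-"))
    }
  }
  pct <- function(lbl) if (n == 0L) 0 else 100 * sum(cls == lbl) / n
  structure(list(vc = pct("vc"), ic = pct("ic"), nc = pct("nc"),
                 vb = length(vb), ib = length(ib), class = cls),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("connectivity: VC %.1f%%, IC %.1f%%, NC %.1f%% | VB %d, IB %d (n = %d)\n",
              x$vc, x$ic, x$nc, x$vb, x$ib, length(x$class)))
  invisible(x)
}

#' Evaluate a tractogram against ground-truth bundles
#'
#' Pairs every pathway with its best-matching (lowest spatial metric) truth
#' curve, reports the three local metrics per pathway plus the global
#' connectivity metrics.
#'
#' @param tract a \code{\link{tractogram}} or list of pathways.
#' @param truth a \code{\link{bundle_truth}}.
#' @return list with \code{per_pathway} (data.frame: matched bundle, sm, tm,
#'   cm) and \code{connectivity} (a \code{metric_report}).
#' @export
evaluate_tractogram <- function(tract, truth) {
  pw <- if (inherits(tract, "tractogram")) tract$pathways else tract
  rows <- lapply(seq_along(pw), function(i) {
    sms <- vapply(truth$curves, function(tc) spatial_metric(pw[[i]], tc),
                  numeric(1))
    b <- which.min(sms)
    data.frame(pathway = i, bundle = b, sm = sms[b],
               tm = tangent_metric(pw[[i]], truth$curves[[b]]),
               cm = curve_metric(pw[[i]], truth$curves[[b]]))
  })
  list(per_pathway = do.call(rbind, rows),
       connectivity = connectivity_metrics(pw, truth))
}

#' Write a metric report as JSON plus a per-pathway CSV
#'
#' @param evaluation result of \code{\link{evaluate_tractogram}}.
#' @param json_path,csv_path output file paths (NULL to skip either).
#' @return invisibly, the evaluation.
#' @export
write_metric_report <- function(evaluation, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    con <- evaluation$connectivity
    jsonlite::write_json(
      list(vc = con$vc, ic = con$ic, nc = con$nc, vb = con$vb, ib = con$ib,
           mean_sm = mean(evaluation$per_pathway$sm),
           mean_tm = mean(evaluation$per_pathway$tm),
           mean_cm = mean(evaluation$per_pathway$cm)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- evaluation$per_pathway
    df$class <- evaluation$connectivity$class
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(evaluation)
}
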