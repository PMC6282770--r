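#' Clamped, normalized, evenly spaced knot vector
#'
#' End knots repeated degree+1 times (so the curve interpolates its end
#' control points); interior knots uniformly spaced in (0,1).
#'
#' @param n_ctrl number of control points, >= degree + 1.
#' @param degree spline degree p >= 1.
#' @return numeric vector of length \code{n_ctrl + degree + 1} in [0,1].
#' @examples
#' make_knot_vector(6, 3)  # 0,0,0,0, 1/3, 2/3, 1,1,1,1
#' @export
make_knot_vector <- function(n_ctrl, degree) {
  n_ctrl <- as.integer(n_ctrl); degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (n_ctrl < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " control points")
  n_int <- n_ctrl - degree - 1L
  c(rep(0, degree + 1L),
    if (n_int > 0L) seq_len(n_int) / (n_int + 1L),
    rep(1, degree + 1L))
}

#' B-spline basis functions at a parameter value
#'
#' Cox-de Boor recursion over a clamped knot vector, with the right-continuous
#' convention at interior knots (0/0 terms taken as 0) and the u = 1 endpoint
#' assigned to the last basis function.
#'
#' @param knots clamped nondecreasing knot vector in [0,1].
#' @param degree spline degree p.
#' @param u parameter in [0,1].
#' @return numeric vector of the \code{length(knots) - degree - 1} basis
#'   values: non-negative, at most degree+1 nonzero, summing to 1.
#' @export
basis_functions <- function(knots, degree, u) {
  if (u < 0 || u > 1) stop("parameter u outside [0,1]")
  n_basis <- length(knots) - degree - 1L
  # degree-0: indicator of the half-open span; u = 1 belongs to the last
  # non-empty span so the curve is left-continuous at the right end
  if (u >= 1) {
    N <- as.numeric(knots[-length(knots)] < 1 & knots[-1] >= 1)
  } else {
    N <- as.numeric(knots[-length(knots)] <= u & u < knots[-1])
  }
  if (degree == 0L) return(N[seq_len(n_basis)])
  for (p in seq_len(degree)) {
    m <- length(N) - 1L
    left <- knots[seq_len(m)]
    right1 <- knots[seq_len(m) + p]
    right2 <- knots[seq_len(m) + p + 1L]
    a <- ifelse(right1 - left > 0, (u - left) / (right1 - left), 0)
    b <- ifelse(right2 - knots[seq_len(m) + 1L] > 0,
                (right2 - u) / (right2 - knots[seq_len(m) + 1L]), 0)
    N <- a * N[seq_len(m)] + b * N[seq_len(m) + 1L]
  }
  N[seq_len(n_basis)]
}

#' Construct a NURBS curve
#'
#' A nonuniform rational B-spline curve: control points, strictly positive
#' weights and a clamped normalized knot vector. With all weights equal the
#' curve reduces to the ordinary (non-rational) B-spline.
#'
#' @param control_points (n+1) x 3 numeric matrix, mm.
#' @param weights strictly positive numeric of matching length (default all 1).
#' @param degree spline degree (default 3, cubic); must satisfy
#'   n_ctrl >= degree + 1.
#' @param knots optional knot vector; default \code{\link{make_knot_vector}}.
#' @return object of class \code{nurbs_curve}.
#' @export
nurbs_curve <- function(control_points, weights = NULL, degree = 3L,
                        knots = NULL) {
  control_points <- matrix(as.numeric(control_points), ncol = 3L)
  n_ctrl <- nrow(control_points)
  if (is.null(weights)) weights <- rep(1, n_ctrl)
  if (length(weights) != n_ctrl) stop("weights/control point length mismatch")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  degree <- as.integer(degree)
  if (n_ctrl < degree + 1L)
    stop("number of control points (", n_ctrl,
         ") must be >= order (", degree + 1L, ")")
  if (is.null(knots)) knots <- make_knot_vector(n_ctrl, degree)
  if (length(knots) != n_ctrl + degree + 1L) stop("knot vector length mismatch")
  if (is.unsorted(knots)) stop("knot vector must be nondecreasing")
  structure(list(degree = degree, control_points = control_points,
                 weights = as.numeric(weights), knots = as.numeric(knots)),
            class = "nurbs_curve")
}

#' @export
print.nurbs_curve <- function(x, ...) {
  cat(sprintf("nurbs_curve: degree %d, %d control points, weights in [%.3g, %.3g]\n",
              x$degree, nrow(x$control_points),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Evaluate a NURBS curve
#'
#' Rational evaluation \eqn{C(u) = \sum_i N_i(u) w_i P_i / \sum_i N_i(u) w_i}.
#'
#' @param curve a \code{\link{nurbs_curve}}.
#' @param u numeric vector of parameters in [0,1].
#' @return length(u) x 3 matrix of points, mm.
#' @export
nurbs_eval <- function(curve, u) {
  out <- matrix(NA_real_, length(u), 3L)
  for (k in seq_along(u)) {
    N <- basis_functions(curve$knots, curve$degree, u[k])
    wN <- N * curve$weights
    s <- sum(wN)
    if (s <= 0) stop("internal error: zero rational weight sum")
    out[k, ] <- colSums(curve$control_points * wN) / s
  }
  out
}

#' @rdname nurbs_eval
#' @param object a \code{\link{nurbs_curve}}.
#' @param ... unused.
#' @export
predict.nurbs_curve <- function(object, u = seq(0, 1, length.out = 101), ...) {
  nurbs_eval(object, u)
}

# cumulative chord length of the curve over a parameter partition, refined by
# doubling until the total converges within tol
nurbs_arclength_table <- function(curve, tol) {
  m <- max(64L, 16L * nrow(curve$control_points))
  u <- seq(0, 1, length.out = m + 1L)
  pts <- nurbs_eval(curve, u)
  total <- sum(sqrt(rowSums(diff(pts)^2)))
  repeat {
    m2 <- 2L * m
    u2 <- seq(0, 1, length.out = m2 + 1L)
    pts2 <- nurbs_eval(curve, u2)
    total2 <- sum(sqrt(rowSums(diff(pts2)^2)))
    if (abs(total2 - total) < tol || m2 >= 16384L) {
      u <- u2; pts <- pts2; total <- total2
      break
    }
    m <- m2; u <- u2; pts <- pts2; total <- total2
  }
  list(u = u, cum = c(0, cumsum(sqrt(rowSums(diff(pts)^2)))), total = total)
}

#' Sample a NURBS curve into a pathway at (approximately) fixed arc-length step
#'
#' Chord-length reparameterization on a refined parameter grid; sample points
#' are near-equally spaced at \code{step} mm, and the first and last points
#' are the exact curve endpoints.
#'
#' @param curve a \code{\link{nurbs_curve}}.
#' @param step target spacing, mm (> 0).
#' @param seed_voxel,termination_reason metadata forwarded to
#'   \code{\link{pathway}}.
#' @return a \code{\link{pathway}}.
#' @export
sample_pathway <- function(curve, step,
                           seed_voxel = c(NA_integer_, NA_integer_, NA_integer_),
                           termination_reason = "no_candidate") {
  stopifnot(step > 0)
  spread <- max(abs(sweep(curve$control_points, 2L,
                          curve$control_points[1L, ])))
  if (spread < 1e-12) {
    warning("degenerate curve: all control points coincide")
    p <- curve$control_points[1L, ]
    return(pathway(rbind(p, p), seed_voxel, termination_reason))
  }
  tab <- nurbs_arclength_table(curve, tol = 1e-4 * step)
  targets <- seq(0, tab$total, by = step)
  if (targets[length(targets)] < tab$total - 1e-12)
    targets <- c(targets, tab$total)
  u_s <- stats::approx(tab$cum, tab$u, xout = targets, ties = "ordered")$y
  pts <- nurbs_eval(curve, u_s)
  pts[1L, ] <- nurbs_eval(curve, 0)
  pts[nrow(pts), ] <- nurbs_eval(curve, 1)
  # drop interior points that collapsed onto a neighbor (flat cum table)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  keep[length(keep)] <- TRUE
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L) pts <- rbind(nurbs_eval(curve, 0), nurbs_eval(curve, 1))
  pathway(pts, seed_voxel, termination_reason)
}
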