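line_pathway <- function(from, to, n = 21) {
  pathway(cbind(seq(from[1], to[1], length.out = n),
                seq(from[2], to[2], length.out = n),
                seq(from[3], to[3], length.out = n)))
}

circle_pathway <- function(r, n = 126, z = 0) {
  th <- seq(0, 2 * pi, length.out = n)
  pathway(cbind(r * cos(th), r * sin(th), z))
}

test_that("spatial metric: identity, exact parallel offset, brute-force oracle", {
  a <- line_pathway(c(0, 0, 0), c(10, 0, 0))
  expect_equal(spatial_metric(a, a), 0)
  b <- line_pathway(c(0, 1, 0), c(10, 1, 0))
  expect_equal(spatial_metric(a, b), 1)
  expect_error(spatial_metric(pathway(rbind(c(0, 0, 0), c(1, 0, 0))),
                              matrix(1, 1, 3)), "degenerate")
  # translation equivariance for a perpendicular offset
  expect_equal(spatial_metric(a, line_pathway(c(0, 0.37, 0), c(10, 0.37, 0))),
               0.37)
  # randomized curves vs dense brute-force closest-point sampling
  set.seed(31)
  for (rep in 1:5) {
    t1 <- sort(runif(12)); t2 <- sort(runif(15))
    e <- pathway(cbind(10 * t1, sin(4 * t1), cos(3 * t1)))
    t_ <- pathway(cbind(10 * t2 + 0.3, sin(4 * t2 + 0.2), cos(3 * t2)))
    dense_mse <- function(from, to) {
      # sample every target segment extremely densely, take pointwise minima
      seg_pts <- NULL
      for (s in seq_len(nrow(to) - 1)) {
        lam <- seq(0, 1, length.out = 2000)
        seg_pts <- rbind(seg_pts,
                         outer(1 - lam, to[s, ]) + outer(lam, to[s + 1, ]))
      }
      mean(vapply(seq_len(nrow(from)), function(i)
        min(rowSums(sweep(seg_pts, 2, from[i, ])^2)), numeric(1)))
    }
    want <- sqrt((dense_mse(unclass(e), unclass(t_)) +
                  dense_mse(unclass(t_), unclass(e))) / 2)
    expect_equal(spatial_metric(e, t_), want, tolerance = 1e-2)
  }
  expect_equal(spatial_metric(a, b), spatial_metric(b, a))   # symmetry
})

test_that("tangent metric: identity, constant crossing angle, reversal", {
  a <- line_pathway(c(-5, 0, 0), c(5, 0, 0))
  expect_equal(tangent_metric(a, a), 0)
  rot30 <- function(p) {
    R <- matrix(c(cos(pi / 6), sin(pi / 6), 0,
                  -sin(pi / 6), cos(pi / 6), 0, 0, 0, 1), 3, 3)
    pathway(unclass(p) %*% t(R))
  }
  b <- rot30(a)
  expect_equal(tangent_metric(a, b), pi / 6, tolerance = 1e-9)
  rev_a <- pathway(unclass(a)[nrow(a):1, ])
  expect_equal(tangent_metric(a, rev_a), 0)    # axial angles ignore orientation
  expect_equal(tangent_metric(a, b), tangent_metric(b, a))
})

test_that("curve metric: lines, circle-vs-line equals 1/r, identical circles", {
  a <- line_pathway(c(0, 0, 0), c(20, 0, 0), n = 41)
  b <- line_pathway(c(0, 1, 0), c(20, 1, 0), n = 41)
  expect_equal(curve_metric(a, b), 0)
  circ <- circle_pathway(10)
  chord <- line_pathway(c(-10, 0, 0), c(10, 0, 0), n = 41)
  expect_equal(curve_metric(circ, chord), 0.1, tolerance = 1e-3)
  expect_equal(curve_metric(circ, circ), 0)
  expect_equal(curve_metric(circ, chord), curve_metric(chord, circ))
})

toy_truth <- function() {
  g <- voxel_grid(c(12, 12, 4), 1)
  mask <- array(TRUE, g$dims)
  roi <- function(xr, yr) {
    a <- array(FALSE, g$dims); a[xr + 1, yr + 1, ] <- TRUE; a
  }
  # bundle 1 along x, bundle 2 along y
  b1 <- list(roi(0:1, 5:6), roi(10:11, 5:6))
  b2 <- list(roi(5:6, 0:1), roi(5:6, 10:11))
  curves <- list(line_pathway(c(1, 6, 2), c(11, 6, 2)),
                 line_pathway(c(6, 1, 2), c(6, 11, 2)))
  bundle_truth(curves, list(b1, b2), mask, g)
}

test_that("connectivity classifies the three-pathway toy by hand enumeration", {
  truth <- toy_truth()
  p_valid <- line_pathway(c(0.5, 6, 2), c(11.5, 6, 2))       # bundle 1 ends
  p_invalid <- line_pathway(c(0.5, 6, 2), c(6, 11.5, 2))     # cross-bundle
  p_none <- line_pathway(c(4, 4, 2), c(8, 8, 2))             # mid-mask
  rep <- connectivity_metrics(list(p_valid, p_invalid, p_none), truth)
  expect_equal(rep$vc, 100 / 3)
  expect_equal(rep$ic, 100 / 3)
  expect_equal(rep$nc, 100 / 3)
  expect_equal(rep$vb, 1L)
  expect_equal(rep$ib, 1L)
  expect_equal(rep$class, c("vc", "ic", "nc"))
})

test_that("connectivity degenerate and contract cases", {
  truth <- toy_truth()
  rep0 <- connectivity_metrics(list(), truth)
  expect_equal(c(rep0$vc, rep0$ic, rep0$nc, rep0$vb, rep0$ib), c(0, 0, 0, 0, 0))
  all_valid <- list(line_pathway(c(0.5, 6, 2), c(11.5, 6, 2)),
                    line_pathway(c(1.5, 5.5, 2), c(10.5, 5.5, 2)))
  repv <- connectivity_metrics(all_valid, truth)
  expect_equal(c(repv$vc, repv$ic, repv$nc, repv$vb, repv$ib),
               c(100, 0, 0, 1, 0))
  # a same-bundle pathway that leaves the mask is only a "no connection"
  truth_holed <- toy_truth()
  truth_holed$wm_mask[6, 7, 3] <- FALSE
  rep_h <- connectivity_metrics(list(all_valid[[1]]), truth_holed)
  expect_equal(rep_h$class, "nc")
  # overlapping ROIs are rejected
  bad <- toy_truth()
  bad$endpoint_rois[[2]][[1]] <- bad$endpoint_rois[[1]][[1]]
  expect_error(connectivity_metrics(all_valid, bad), "overlap")
})

test_that("connectivity equals an independent per-pathway classification", {
  truth <- toy_truth()
  lut_rois <- list(truth$endpoint_rois[[1]][[1]], truth$endpoint_rois[[1]][[2]],
                   truth$endpoint_rois[[2]][[1]], truth$endpoint_rois[[2]][[2]])
  roi_of <- function(pt, nudge) {
    pt <- pt + 1e-6 * nudge
    v <- floor(pt)
    if (any(v < 0) || any(v >= truth$grid$dims)) return(0L)
    for (r in 1:4) if (lut_rois[[r]][v[1] + 1, v[2] + 1, v[3] + 1]) return(r)
    0L
  }
  set.seed(77)
  paths <- lapply(1:40, function(i) {
    ends <- matrix(runif(6, 0.5, 11.5), 2, 3); ends[, 3] <- 2
    line_pathway(ends[1, ], ends[2, ])
  })
  got <- connectivity_metrics(paths, truth)
  want <- vapply(paths, function(p) {
    p <- unclass(p)
    r1 <- roi_of(p[1, ], p[2, ] - p[1, ])
    r2 <- roi_of(p[nrow(p), ], p[nrow(p) - 1, ] - p[nrow(p), ])
    if (r1 == 0 || r2 == 0 || r1 == r2) return("nc")
    same <- (r1 <= 2) == (r2 <= 2)
    if (same) "vc" else "ic"   # mask is all-TRUE here
  }, character(1))
  expect_equal(got$class, want)
})

test_that("tractogram evaluation pairs pathways with their best bundle", {
  truth <- toy_truth()
  ev <- evaluate_tractogram(list(line_pathway(c(1, 6.2, 2), c(11, 6.2, 2)),
                                 line_pathway(c(6.2, 1, 2), c(6.2, 11, 2))),
                            truth)
  expect_equal(ev$per_pathway$bundle, c(1L, 2L))
  expect_equal(ev$per_pathway$sm, c(0.2, 0.2), tolerance = 1e-6)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_metric_report(ev, jf, cf)
  js <- jsonlite::fromJSON(jf)
  expect_equal(js$vc, 100)
  expect_equal(nrow(utils::read.csv(cf)), 2L)
})
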