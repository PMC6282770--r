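test_that("voxel-line intersections match the six-facet brute-force oracle", {
  g <- voxel_grid(c(1, 1, 1), 1)
  io <- voxel_line_intersections(g, c(0, 0, 0), c(1, 0, 0))
  expect_equal(io$entry, c(0, 0.5, 0.5))
  expect_equal(io$exit, c(1, 0.5, 0.5))
  io <- voxel_line_intersections(g, c(0, 0, 0), c(1, 1, 1) / sqrt(3))
  expect_equal(io$entry, c(0, 0, 0))
  expect_equal(io$exit, c(1, 1, 1))
  io <- voxel_line_intersections(g, c(0, 0, 0), c(2, 1, 0) / sqrt(5))
  expect_equal(io$entry, c(0, 0.25, 0.5))
  expect_equal(io$exit, c(1, 0.75, 0.5))
  set.seed(99)
  for (rep in 1:500) {
    dims <- sample(2:6, 3, replace = TRUE)
    gr <- voxel_grid(dims, runif(3, 0.5, 3), origin = rnorm(3))
    vox <- vapply(dims, function(d) sample(d, 1) - 1L, integer(1))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    got <- voxel_line_intersections(gr, vox, u)
    want <- bruteforce_box_intersections(gr, vox, u)
    expect_equal(got$entry, want$entry, tolerance = 1e-9)
    expect_equal(got$exit, want$exit, tolerance = 1e-9)
  }
})

# a hand-built 2-node collinear chain in adjacent unit voxels
collinear_chain <- function() {
  structure(list(nodes = list(
    chain_node(c(0L, 0L, 0L), c(1, 0, 0), 0.2),
    chain_node(c(1L, 0L, 0L), c(1, 0, 0), 0.6)),
    termination_reason = "no_candidate", length_mm = 1),
    class = "direction_chain")
}

test_that("tangent-mode control points: collinear triples, shared crossings", {
  g <- voxel_grid(c(4, 4, 4), 1)
  ch1 <- structure(list(nodes = list(chain_node(c(1L, 1L, 1L), c(1, 0, 0), 1)),
                        termination_reason = "no_candidate", length_mm = 0),
                   class = "direction_chain")
  cs1 <- control_points_tangent(ch1, g)
  expect_equal(nrow(cs1$points), 3L)
  expect_equal(cs1$provenance, c("entry", "center", "exit"))
  d01 <- diff(cs1$points)
  expect_equal(d01[1, ] / sqrt(sum(d01[1, ]^2)), c(1, 0, 0))

  cs2 <- control_points_tangent(collinear_chain(), g)
  expect_equal(nrow(cs2$points), 5L)   # shared facet point counted once
  expect_equal(cs2$points[3, ], c(1, 0.5, 0.5))

  # bent 3-node chain: each node's (center - entry) x direction = 0
  bend <- structure(list(nodes = list(
    chain_node(c(0L, 0L, 0L), c(1, 0, 0), 1),
    chain_node(c(1L, 0L, 0L), c(1, 1, 0) / sqrt(2), 1),
    chain_node(c(1L, 1L, 0L), c(0, 1, 0), 1)),
    termination_reason = "no_candidate", length_mm = 2),
    class = "direction_chain")
  csb <- control_points_tangent(bend, g)
  for (k in 1:3) {
    nd <- bend$nodes[[k]]
    ctr <- voxel_center(g, nd$voxel)
    ent <- voxel_line_intersections(g, nd$voxel, nd$direction)$entry
    cr <- nurbstrack:::crossprod3(ctr - ent, nd$direction)
    expect_equal(sqrt(sum(cr^2)), 0, tolerance = 1e-12)
  }
  expect_error(control_points_tangent(
    structure(list(nodes = list()), class = "direction_chain"), g), "empty")
})

test_that("general-mode control points are the tangent ones without centers", {
  g <- voxel_grid(c(4, 4, 4), 1)
  ch <- collinear_chain()
  cs_g <- control_points_general(ch, g)
  expect_equal(nrow(cs_g$points), 3L)
  expect_equal(cs_g$provenance, c("entry", "exit", "exit"))
  cs_t <- control_points_tangent(ch, g)
  keep <- cs_t$provenance != "center"
  expect_equal(cs_g$points, cs_t$points[keep, ])
})

test_that("diffusion probabilities convert to max-normalized weights", {
  g <- voxel_grid(c(4, 4, 4), 1)
  ch <- collinear_chain()           # d = (0.2, 0.6)
  cs <- control_points_general(ch, g)
  w <- convert_weights(ch, cs)
  expect_equal(w, c(0.2 / 0.6, 0.4 / 0.6, 1))   # node1, shared, node2
  # equal d -> all weights 1, and the curve equals the non-rational spline
  ch_eq <- collinear_chain()
  ch_eq$nodes[[1]]$probability <- 0.5
  ch_eq$nodes[[2]]$probability <- 0.5
  cs_eq <- control_points_tangent(ch_eq, g)
  w_eq <- convert_weights(ch_eq, cs_eq)
  expect_true(all(w_eq == 1))
  # single node -> weight 1
  ch1 <- structure(list(nodes = list(chain_node(c(0L, 0L, 0L), c(1, 0, 0), 0.3)),
                        termination_reason = "x", length_mm = 0),
                   class = "direction_chain")
  expect_true(all(convert_weights(ch1, control_points_tangent(ch1, g)) == 1))
})

test_that("both modes recover a straight bundle exactly", {
  f <- straight_field(20)
  f$wm_mask <- array(TRUE, f$grid$dims)
  for (m in c("nurbs_t", "nurbs_g")) {
    tr <- track_fibers(matrix(c(10, 10, 10), 1), f, tracking_params(mode = m))
    expect_length(tr$pathways, 1L)
    p <- tr$pathways[[1]]
    expect_lt(max(abs(p[, 2] - 10.5), abs(p[, 3] - 10.5)), 1e-9)
  }
  # empty seed list -> empty tractogram
  expect_length(track_fibers(matrix(integer(0), 0, 3), f,
                             tracking_params())$pathways, 0L)
})

node_tangency_angles <- function(chain, grid) {
  curve <- nurbstrack:::fit_chain_curve(chain, grid, "nurbs_t")
  us <- seq(0, 1, length.out = 2001)
  pts <- nurbs_eval(curve, us)
  vapply(chain$nodes, function(nd) {
    ctr <- voxel_center(grid, nd$voxel)
    i <- which.min(rowSums(sweep(pts, 2, ctr)^2))
    i <- min(max(i, 2L), length(us) - 1L)
    tg <- pts[i + 1L, ] - pts[i - 1L, ]
    tg <- tg / sqrt(sum(tg^2))
    acos(min(1, abs(sum(tg * nd$direction))))
  }, numeric(1))
}

test_that("tangent mode keeps curve tangents near the diffusion directions", {
  # on a straight chain the collinear entry-center-exit triples realize the
  # tangency premise exactly
  fs <- straight_field(16)
  chs <- extract_chain(c(2, 8, 8), c(1, 0, 0), fs, tracking_params())
  expect_lt(max(node_tangency_angles(chs, fs$grid)), 1e-9)

  # on a gently curved chain (r = 20 mm arc, ~3 deg of turn per voxel) the
  # tangency holds on average; isolated staircase corners spike higher
  spec <- phantom_spec("arc", grid = voxel_grid(c(44, 44, 44), 1), radius = 20)
  ph <- generate_field(spec)
  sv <- world_to_voxel(spec$grid, spec$curves[[1]]$point(0.5))
  ch <- bidirectional_chains(sv, ph$field, tracking_params())[[1]]
  angs <- node_tangency_angles(ch, spec$grid)
  expect_lt(mean(angs), 15 * pi / 180)
  expect_lt(max(angs), 30 * pi / 180)

  # both modes stay within a voxel diagonal of the chain's center polyline
  centers <- t(vapply(ch$nodes, function(n) voxel_center(spec$grid, n$voxel),
                      numeric(3)))
  for (m in c("nurbs_t", "nurbs_g")) {
    cv <- nurbstrack:::fit_chain_curve(ch, spec$grid, m)
    smp <- nurbs_eval(cv, seq(0, 1, length.out = 101))
    dmax <- max(vapply(seq_len(nrow(smp)), function(r)
      sqrt(nurbstrack:::closest_on_polyline(smp[r, ], centers)$d2), numeric(1)))
    expect_lt(dmax, sqrt(3))
  }
})

test_that("modes coincide on a perfectly straight chain", {
  f <- straight_field(12)
  ch <- extract_chain(c(2, 6, 6), c(1, 0, 0), f, tracking_params())
  p_t <- sample_pathway(nurbstrack:::fit_chain_curve(ch, f$grid, "nurbs_t"), 0.5)
  p_g <- sample_pathway(nurbstrack:::fit_chain_curve(ch, f$grid, "nurbs_g"), 0.5)
  # geometric coincidence: every sample of one lies on the other's polyline
  expect_lt(max(vapply(seq_len(nrow(p_t)), function(r)
    sqrt(nurbstrack:::closest_on_polyline(unclass(p_t)[r, ],
                                          unclass(p_g))$d2), numeric(1))),
    1e-9)
  expect_equal(unclass(p_t)[1, ], unclass(p_g)[1, ])
  expect_equal(unclass(p_t)[nrow(p_t), ], unclass(p_g)[nrow(p_g), ])
})

test_that("streamline baseline: straight course, bend stop, no branch switch", {
  f <- straight_field(20)
  st <- track_streamline(matrix(c(10, 10, 10), 1), f,
                         tracking_params(mode = "streamline"),
                         integration_step = 0.1)
  expect_length(st$pathways, 1L)
  p <- st$pathways[[1]]
  expect_lt(max(abs(p[, 2] - 10.5), abs(p[, 3] - 10.5)), 1e-9)

  fb <- straight_field(20)
  for (k in 0:19) for (j in 0:19) for (i in 10:19)
    fb$peaks[[nurbstrack:::linear_index(fb$grid, c(i, j, k))]] <-
      direction_set(matrix(c(0, 1, 0), 1), 1)
  stb <- track_streamline(matrix(c(2, 10, 10), 1), fb,
                          tracking_params(mode = "streamline"),
                          integration_step = 0.1)
  reasons <- unlist(lapply(stb$pathways, attr, "termination_reason"))
  expect_true("angle" %in% reasons)
  expect_lt(max(stb$pathways[[1]][, 1]), 10.5)  # stopped at the bend

  spec <- phantom_spec("crossing")
  ph <- generate_field(spec)
  sv <- world_to_voxel(spec$grid, spec$curves[[1]]$point(0.3))
  stc <- track_streamline(matrix(sv, 1), ph$field,
                          tracking_params(mode = "streamline"),
                          integration_step = 0.1)
  p <- stc$pathways[[1]]
  expect_lt(max(abs(p[, 2] - p[1, 2])), 0.6)   # stays on the entering axis
})
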