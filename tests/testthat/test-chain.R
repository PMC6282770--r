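test_that("uniform straight field continues collinearly", {
  f <- straight_field(12)
  cur <- chain_node(c(5, 5, 5), c(1, 0, 0))
  nxt <- select_next(cur, f, tracking_params())
  expect_equal(nxt$node$voxel, c(6L, 5L, 5L))
  expect_equal(nxt$node$direction, c(1, 0, 0))
})

test_that("the neighbor on the direction line beats the FACT-style diagonal", {
  # seed direction slightly off +x: its line passes through the axial
  # neighbor's center region but far from the diagonal neighbor's center.
  g <- voxel_grid(c(5, 5, 1), 1)
  u <- c(1, 0.05, 0) / sqrt(1.0025)
  rot <- function(a) c(cos(a), sin(a), 0)   # 5-degree-off direction for axial
  peaks <- vector("list", prod(g$dims))
  for (i in seq_along(peaks)) peaks[[i]] <- direction_set(matrix(0, 0, 3), numeric(0))
  set_peak <- function(peaks, idx, v) {
    peaks[[idx[1] + g$dims[1] * (idx[2] + g$dims[2] * idx[3]) + 1L]] <-
      direction_set(matrix(v / sqrt(sum(v^2)), 1), 1)
    peaks
  }
  peaks <- set_peak(peaks, c(1, 1, 0), u)        # seed, direction V1
  peaks <- set_peak(peaks, c(2, 1, 0), rot(asin(0.05 / sqrt(1.0025)) + 5 * pi / 180))
  peaks <- set_peak(peaks, c(2, 2, 0), u)        # diagonal: perfectly aligned
  f <- vector_field(g, peaks, fa = array(0.8, g$dims))
  cur <- chain_node(c(1, 1, 0), u)
  # distances: axial center near the line, diagonal center far beyond d_th
  ctr <- voxel_center(g, c(1, 1, 0))
  expect_lt(point_line_distance(voxel_center(g, c(2, 1, 0)), ctr, u), 0.1)
  expect_gt(point_line_distance(voxel_center(g, c(2, 2, 0)), ctr, u),
            0.5 * sqrt(3))
  nxt <- select_next(cur, f, tracking_params())
  expect_equal(nxt$node$voxel, c(2L, 1L, 0L))
  # a FACT-style pure-angle pick would take the perfectly aligned diagonal
  angs <- c(axial = acos(abs(sum(field_peaks_at(f, c(2, 1, 0))$directions[1, ] * u))),
            diag = acos(abs(sum(field_peaks_at(f, c(2, 2, 0))$directions[1, ] * u))))
  expect_lt(angs["diag"], angs["axial"])
})

test_that("angle threshold stops the chain", {
  f <- straight_field(12)
  # overwrite the next voxel with a 75-degree direction
  a <- 75 * pi / 180
  f$peaks[[nurbstrack:::linear_index(f$grid, c(6, 5, 5))]] <-
    direction_set(matrix(c(cos(a), sin(a), 0), 1), 1)
  # remove all other candidates from the forward shell
  for (dy in -1:1) for (dz in -1:1)
    if (dy != 0 || dz != 0)
      f$peaks[[nurbstrack:::linear_index(f$grid, c(6, 5 + dy, 5 + dz))]] <-
        direction_set(matrix(0, 0, 3), numeric(0))
  cur <- chain_node(c(5, 5, 5), c(1, 0, 0))
  nxt <- select_next(cur, f, tracking_params(theta_th = 60))
  expect_null(nxt$node)
  expect_equal(nxt$reason, "angle")
})

test_that("extract_chain traverses, respects length budget, stops at bends", {
  f <- straight_field(20)
  ch <- extract_chain(c(2, 10, 10), c(1, 0, 0), f, tracking_params())
  vx <- t(vapply(ch$nodes, function(n) n$voxel, integer(3)))
  expect_equal(vx[, 1], 2:19)
  expect_true(all(vx[, 2] == 10L & vx[, 3] == 10L))
  expect_equal(ch$termination_reason, "no_candidate")

  ch5 <- extract_chain(c(2, 10, 10), c(1, 0, 0), f, tracking_params(L_th = 5))
  expect_lte(ch5$length_mm, 5)
  expect_equal(ch5$termination_reason, "length")

  # 90-degree bend: +x for x < 10, +y for x >= 10
  fb <- straight_field(20)
  for (k in 0:19) for (j in 0:19) for (i in 10:19)
    fb$peaks[[nurbstrack:::linear_index(fb$grid, c(i, j, k))]] <-
      direction_set(matrix(c(0, 1, 0), 1), 1)
  chb <- extract_chain(c(2, 10, 10), c(1, 0, 0), fb, tracking_params(theta_th = 60))
  expect_equal(chb$termination_reason, "angle")
  last <- chb$nodes[[length(chb$nodes)]]$voxel
  expect_equal(last, c(9L, 10L, 10L))

  expect_error(extract_chain(c(2, 10, 10), c(1, 0, 0), f,
                             tracking_params(FA_th = 0.9)), "FA")
})

test_that("extract_chain agrees with the exhaustive greedy oracle", {
  params <- tracking_params()   # theta 60, L 70, FA 0.15
  for (seed in 1:100) {
    f <- random_tiny_field(seed)
    sv <- first_valid_seed(f, params)
    if (is.null(sv)) next
    v0 <- field_peaks_at(f, sv)$directions[1, ]
    got <- extract_chain(sv, v0, f, params)
    want <- oracle_chain(sv, v0, f, params)
    expect_equal(length(got$nodes), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$nodes[[k]]$voxel, as.integer(want[[k]]$voxel))
      expect_equal(got$nodes[[k]]$direction, want[[k]]$dir)
    }
    # every emitted chain satisfies all four constraints exactly
    vx <- t(vapply(got$nodes, function(n) n$voxel, integer(3)))
    if (nrow(vx) > 1) {
      steps <- abs(diff(vx))
      expect_true(all(steps <= 1L) && all(rowSums(steps) > 0L))
      dirs <- t(vapply(got$nodes, function(n) n$direction, numeric(3)))
      angs <- vapply(seq_len(nrow(dirs) - 1L), function(r)
        acos(min(1, abs(sum(dirs[r, ] * dirs[r + 1L, ])))), numeric(1))
      expect_true(all(angs <= params$theta_th * pi / 180 + 1e-9))
      expect_true(!anyDuplicated(vx))
      expect_lte(got$length_mm, params$L_th)
      fa_vals <- f$fa[vx + 1L]
      expect_true(all(fa_vals >= params$FA_th))
    }
  }
})

test_that("bidirectional chains splice the two sides consistently", {
  f <- straight_field(20)
  chains <- bidirectional_chains(c(10, 10, 10), f, tracking_params())
  expect_length(chains, 1L)
  vx <- t(vapply(chains[[1]]$nodes, function(n) n$voxel, integer(3)))
  expect_equal(vx[, 1], 0:19)     # spans the full bundle both ways
  expect_true(!anyDuplicated(vx))
  dirs <- t(vapply(chains[[1]]$nodes, function(n) n$direction, numeric(3)))
  expect_true(all(dirs[, 1] > 0))  # consistent polarity head -> tail

  # seed voxel with two crossing axes -> two spliced chains, one per axis
  fx <- straight_field(20)
  li <- nurbstrack:::linear_index(fx$grid, c(10, 10, 10))
  fx$peaks[[li]] <- direction_set(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5))
  ch2 <- bidirectional_chains(c(10, 10, 10), fx, tracking_params())
  expect_length(ch2, 2L)

  # seed at the grid edge: the backward side is empty
  che <- bidirectional_chains(c(0, 10, 10), f, tracking_params())
  vx_e <- t(vapply(che[[1]]$nodes, function(n) n$voxel, integer(3)))
  one_sided <- extract_chain(c(0, 10, 10), c(1, 0, 0), f,
                             tracking_params(), L_budget = 35)
  expect_equal(vx_e, t(vapply(one_sided$nodes, function(n) n$voxel, integer(3))))
})

test_that("chains serialize to JSON lines", {
  f <- straight_field(8)
  ch <- extract_chain(c(1, 4, 4), c(1, 0, 0), f, tracking_params())
  path <- tempfile(fileext = ".jsonl")
  write_chains_jsonl(list(ch), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  obj <- jsonlite::fromJSON(lines[1])
  expect_equal(nrow(obj$voxels), length(ch$nodes))
  expect_equal(obj$termination_reason, ch$termination_reason)
})
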