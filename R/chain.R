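#' Chain node
#'
#' One step of a direction chain: a voxel, the chosen diffusion direction
#' (polarity-aligned with the propagation sense) and its probability.
#'
#' @param voxel 0-based integer triple.
#' @param direction unit 3-vector.
#' @param probability the diffusion probability d of the chosen direction.
#' @return object of class \code{chain_node}.
#' @export
chain_node <- function(voxel, direction, probability = 1) {
  direction <- as.numeric(direction)
  if (abs(sum(direction^2) - 1) > 1e-9) stop("chain node direction must be unit")
  if (probability <= 0) stop("chain node probability must be > 0")
  structure(list(voxel = as.integer(voxel), direction = direction,
                 probability = as.numeric(probability)),
            class = "chain_node")
}

#' Select the next (voxel, direction) step of a chain
#'
#' Candidate voxels are the 26-neighbors of the current voxel that are
#' unvisited, lie in the forward hemisphere (strictly positive dot product of
#' the center offset with the current direction), are inside the white-matter
#' mask, have FA >= FA_th, and whose centers lie within \code{d_th} of the
#' line through the current voxel center along the current direction. Among
#' all diffusion directions of the surviving voxels that lie within the
#' axial angle threshold of the current direction, the winner is the voxel
#' whose center the direction line passes nearest (this is what
#' distinguishes the scheme from FACT's facet-crossing jumps); ties go to
#' the smaller axial angle, then the larger probability, then the
#' lexicographic voxel index. The chosen direction is polarity-flipped to
#' continue forward.
#'
#' @param current a \code{\link{chain_node}}.
#' @param field a \code{\link{vector_field}}.
#' @param params a \code{\link{tracking_params}}.
#' @param visited integer matrix of 0-based voxel triples already used
#'   (one per row), or NULL.
#' @return list with \code{node} (a \code{chain_node} or NULL) and
#'   \code{reason} (why no node: "angle", "fa", "mask_exit", "no_candidate";
#'   NULL when a node was found).
#' @export
select_next <- function(current, field, params, visited = NULL) {
  grid <- field$grid
  d_th <- resolve_d_th(params, grid)
  ctr <- voxel_center(grid, current$voxel)
  u <- current$direction
  nb <- neighbors26(grid, current$voxel)

  if (!is.null(visited) && nrow(nb)) {
    key <- function(m) m[, 1] + grid$dims[1] * (m[, 2] + grid$dims[2] * m[, 3])
    nb <- nb[!(key(nb) %in% key(visited)), , drop = FALSE]
  }
  if (!nrow(nb)) return(list(node = NULL, reason = "no_candidate"))

  centers <- sweep(sweep(nb + 0.5, 2L, grid$voxel_size, "*"),
                   2L, grid$origin, "+")
  offs <- sweep(centers, 2L, ctr)
  fwd <- as.numeric(offs %*% u) > 0
  nb <- nb[fwd, , drop = FALSE]; centers <- centers[fwd, , drop = FALSE]
  if (!nrow(nb)) return(list(node = NULL, reason = "no_candidate"))

  if (!is.null(field$wm_mask)) {
    in_mask <- field$wm_mask[nb + 1L]
    if (!any(in_mask)) return(list(node = NULL, reason = "mask_exit"))
    nb <- nb[in_mask, , drop = FALSE]; centers <- centers[in_mask, , drop = FALSE]
  }

  if (!is.null(field$fa)) {
    fa_ok <- field$fa[nb + 1L] >= params$FA_th
    if (!any(fa_ok)) return(list(node = NULL, reason = "fa"))
    nb <- nb[fa_ok, , drop = FALSE]; centers <- centers[fa_ok, , drop = FALSE]
  }

  offs <- sweep(centers, 2L, ctr)
  proj <- as.numeric(offs %*% u)
  line_dist <- sqrt(pmax(0, rowSums(offs^2) - proj^2))
  dist_ok <- line_dist < d_th
  if (!any(dist_ok)) return(list(node = NULL, reason = "no_candidate"))
  nb <- nb[dist_ok, , drop = FALSE]
  line_dist <- line_dist[dist_ok]

  # rank admissible (voxel, direction) pairs: nearest center-to-line voxel
  # first, then smallest axial angle
  theta_max <- params$theta_th * pi / 180
  best <- NULL
  any_direction <- FALSE
  for (r in seq_len(nrow(nb))) {
    ds <- field_peaks_at(field, nb[r, ])
    if (!nrow(ds$directions)) next
    any_direction <- TRUE
    for (q in seq_len(nrow(ds$directions))) {
      v <- ds$directions[q, ]
      ang <- axial_angle(u, v)
      if (ang > theta_max + 1e-12) next
      cand <- list(voxel = nb[r, ], dir = v, d = ds$d[q], ang = ang,
                   ldist = line_dist[r])
      if (is.null(best) || chain_candidate_better(cand, best)) best <- cand
    }
  }
  if (is.null(best))
    return(list(node = NULL,
                reason = if (any_direction) "angle" else "no_candidate"))
  v <- best$dir
  if (sum(v * u) < 0) v <- -v   # keep propagating forward
  list(node = chain_node(best$voxel, v, best$d), reason = NULL)
}

# deterministic candidate ordering: smaller center-to-line distance, then
# smaller axial angle, then larger d, then lexicographic voxel index
chain_candidate_better <- function(a, b, tol = 1e-9) {
  if (a$ldist < b$ldist - tol) return(TRUE)
  if (a$ldist > b$ldist + tol) return(FALSE)
  if (a$ang < b$ang - tol) return(TRUE)
  if (a$ang > b$ang + tol) return(FALSE)
  if (a$d > b$d + tol) return(TRUE)
  if (a$d < b$d - tol) return(FALSE)
  for (i in 1:3) {
    if (a$voxel[i] < b$voxel[i]) return(TRUE)
    if (a$voxel[i] > b$voxel[i]) return(FALSE)
  }
  FALSE
}

#' Extract the chain of consecutive diffusion directions from a seed
#'
#' Starting at the seed voxel with the given direction, repeatedly applies
#' \code{\link{select_next}}, accumulating center-to-center length and
#' stopping when the next step would exceed the length budget, when no
#' candidate survives the constraints, or when anisotropy/mask tests fail.
#' Every accepted voxel is marked visited (loop prevention).
#'
#' @param seed 0-based voxel triple; must hold at least one direction, lie in
#'   the mask and have FA >= FA_th.
#' @param seed_direction unit 3-vector (one of the seed voxel's directions,
#'   or its negation).
#' @param field a \code{\link{vector_field}}.
#' @param params a \code{\link{tracking_params}}.
#' @param L_budget optional length budget, mm (default \code{params$L_th}).
#' @param visited optional matrix of pre-visited voxel triples.
#' @return object of class \code{direction_chain}: list with \code{nodes}
#'   (list of \code{chain_node}) and \code{termination_reason}.
#' @export
extract_chain <- function(seed, seed_direction, field, params,
                          L_budget = NULL, visited = NULL) {
  grid <- field$grid
  seed <- grid_check_index(grid, seed)
  sd <- field_peaks_at(field, seed)
  if (!nrow(sd$directions)) stop("seed voxel has no diffusion direction")
  if (!field_in_mask(field, seed)) stop("seed voxel outside white-matter mask")
  fa0 <- field_fa_at(field, seed)
  if (!is.na(fa0) && fa0 < params$FA_th)
    stop("seed voxel FA below FA_th")
  if (is.null(L_budget)) L_budget <- params$L_th

  # seed probability: the d of the seed direction it matches (axially)
  match <- which.min(vapply(seq_len(nrow(sd$directions)), function(q)
    axial_angle(seed_direction, sd$directions[q, ]), numeric(1)))
  node <- chain_node(seed, normalize(seed_direction), sd$d[match])

  nodes <- list(node)
  visited <- rbind(visited, matrix(seed, 1L, 3L))
  total <- 0
  reason <- "no_candidate"
  repeat {
    nxt <- select_next(nodes[[length(nodes)]], field, params, visited)
    if (is.null(nxt$node)) { reason <- nxt$reason; break }
    step_len <- sqrt(sum((voxel_center(grid, nxt$node$voxel) -
                          voxel_center(grid, nodes[[length(nodes)]]$voxel))^2))
    if (total + step_len > L_budget) { reason <- "length"; break }
    total <- total + step_len
    nodes[[length(nodes) + 1L]] <- nxt$node
    visited <- rbind(visited, matrix(nxt$node$voxel, 1L, 3L))
  }
  structure(list(nodes = nodes, termination_reason = reason,
                 length_mm = total), class = "direction_chain")
}

#' @export
print.direction_chain <- function(x, ...) {
  cat(sprintf("direction_chain: %d node(s), %.2f mm, termination: %s\n",
              length(x$nodes), x$length_mm, x$termination_reason))
  invisible(x)
}

chain_voxels <- function(chain) {
  t(vapply(chain$nodes, function(n) n$voxel, integer(3)))
}

# splice a backward chain (run along -v) and a forward chain (along +v)
# sharing the seed node into one chain; the backward part is reversed and
# its directions flipped so polarity runs head -> tail
splice_chains <- function(back, fwd) {
  bnodes <- rev(back$nodes)
  bnodes <- lapply(bnodes, function(n) {
    n$direction <- -n$direction; n
  })
  nodes <- c(bnodes[-length(bnodes)], fwd$nodes)   # drop duplicate seed
  structure(list(nodes = nodes,
                 termination_reason = c(back$termination_reason,
                                        fwd$termination_reason),
                 length_mm = back$length_mm + fwd$length_mm),
            class = "direction_chain")
}

#' Extract bidirectional chains for every direction of a seed voxel
#'
#' For each diffusion direction held by the seed voxel, one chain is
#' extracted along the direction and one along its negation; the two are
#' spliced (backward part reversed) into a single chain per seed direction.
#' Each side receives half the length budget, so the combined chain obeys
#' the length threshold.
#'
#' @inheritParams extract_chain
#' @return list of \code{direction_chain}, one per seed direction.
#' @export
bidirectional_chains <- function(seed, field, params) {
  sd <- field_peaks_at(field, grid_check_index(field$grid, seed))
  if (!nrow(sd$directions)) stop("seed voxel has no diffusion direction")
  half <- params$L_th / 2
  out <- vector("list", nrow(sd$directions))
  for (q in seq_len(nrow(sd$directions))) {
    v <- sd$directions[q, ]
    fwd <- extract_chain(seed, v, field, params, L_budget = half)
    back <- extract_chain(seed, -v, field, params, L_budget = half,
                          visited = chain_voxels(fwd)[-1L, , drop = FALSE])
    out[[q]] <- splice_chains(back, fwd)
  }
  out
}

#' Serialize chains to JSON-lines for inspection
#'
#' One JSON object per line: voxel indices, directions, probabilities and
#' termination reason of one chain. Debug format, not a tractogram.
#'
#' @param chains list of \code{direction_chain}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_chains_jsonl <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    obj <- list(
      voxels = chain_voxels(ch),
      directions = t(vapply(ch$nodes, function(n) n$direction, numeric(3))),
      probabilities = vapply(ch$nodes, function(n) n$probability, numeric(1)),
      termination_reason = ch$termination_reason)
    writeLines(jsonlite::toJSON(obj, digits = NA), con)
  }
  invisible(path)
}
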