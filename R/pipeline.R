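#' Assemble a run configuration
#'
#' Mirrors the YAML/CLI configuration surface: input volumes (either an ODF
#' field plus direction table, or a prebuilt vector field), optional FA and
#' white-matter mask, seeds, tracking parameters, and output paths.
#'
#' @param odf,directions paths of the 4-D ODF NIfTI and its direction table
#'   (exclusive with \code{vector_field}).
#' @param vector_field path of a 5-D vector-field NIfTI.
#' @param fa,mask optional NIfTI paths.
#' @param seeds seed specification: a path (text table or NIfTI mask) or an
#'   integer matrix of 0-based voxel triples.
#' @param params a \code{\link{tracking_params}} or a named list of its
#'   fields.
#' @param output output tractogram path (.tck or .trk).
#' @param chains_out optional JSON-lines debug path for raw chains.
#' @param log_level "quiet", "info" or "debug".
#' @param seed integer RNG seed (recorded; tracking itself is deterministic).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(odf = NULL, directions = NULL, vector_field = NULL,
                       fa = NULL, mask = NULL, seeds = NULL,
                       params = tracking_params(), output = NULL,
                       chains_out = NULL, log_level = "info", seed = 1L) {
  if (is.null(vector_field) && (is.null(odf) || is.null(directions)))
    stop("config needs either 'vector_field' or both 'odf' and 'directions'")
  if (!is.null(vector_field) && !is.null(odf))
    stop("give either 'vector_field' or 'odf', not both")
  if (is.null(seeds)) stop("config needs 'seeds'")
  if (is.list(params) && !inherits(params, "tracking_params"))
    params <- do.call(tracking_params, params)
  paths <- c(odf, directions, vector_field, fa, mask,
             if (is.character(seeds)) seeds, output, chains_out)
  if (anyDuplicated(paths)) stop("config paths must be distinct")
  structure(list(odf = odf, directions = directions,
                 vector_field = vector_field, fa = fa, mask = mask,
                 seeds = seeds, params = params, output = output,
                 chains_out = chains_out, log_level = log_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}};
#' \code{params} is a nested mapping of \code{\link{tracking_params}}
#' fields.
#'
#' @param path YAML file path.
#' @param overrides named list overriding file values (CLI flags win).
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  do.call(run_config, cfg)
}

pipeline_log <- function(level, cfg_level, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[cfg_level]] >= ranks[[level]])
    message("[nurbstrack] ", ...)
  invisible(NULL)
}

#' Run the full tracking pipeline
#'
#' ODF field (or prebuilt vector field) -> peak extraction -> bidirectional
#' chain extraction -> NURBS (or streamline) tracking -> tractogram output.
#' Logs per-stage counts: voxels with peaks, seeds accepted, termination
#' reasons, pathways written. Deterministic for a fixed configuration.
#'
#' @param config a \code{\link{run_config}} or a YAML path.
#' @return invisibly, the \code{\link{tractogram}}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  lvl <- config$log_level

  field <- tryCatch({
    if (!is.null(config$vector_field)) {
      read_vector_field(config$vector_field, fa_path = config$fa,
                        mask_path = config$mask)
    } else {
      odf <- read_odf_field(config$odf, config$directions)
      fa <- if (!is.null(config$fa)) read_nifti_volume(config$fa)$data
      msk <- if (!is.null(config$mask))
        array(read_nifti_volume(config$mask)$data > 0.5, odf$grid$dims)
      build_vector_field(odf, fa = fa, wm_mask = msk)
    }
  }, error = function(e) stop("pipeline stage 'load field': ",
                              conditionMessage(e), call. = FALSE))
  n_peak_vox <- sum(vapply(field$peaks, function(p)
    !is.null(p) && nrow(p$directions) > 0L, logical(1)))
  pipeline_log("info", lvl, "field loaded: ", n_peak_vox, " voxels with peaks")

  seeds <- tryCatch({
    if (is.character(config$seeds)) read_seeds(config$seeds)
    else seed_matrix(config$seeds)
  }, error = function(e) stop("pipeline stage 'load seeds': ",
                              conditionMessage(e), call. = FALSE))
  pipeline_log("info", lvl, "seeds: ", nrow(seeds))

  tract <- tryCatch(
    withCallingHandlers(
      track_fibers(seeds, field, config$params),
      warning = function(w) {
        pipeline_log("info", lvl, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("pipeline stage 'track': ",
                             conditionMessage(e), call. = FALSE))
  reasons <- table(unlist(lapply(tract$pathways, attr, "termination_reason")))
  pipeline_log("info", lvl, "pathways: ", length(tract$pathways),
               if (length(reasons)) paste0(" (terminations: ",
                 paste(names(reasons), reasons, sep = "=", collapse = ", "), ")"))

  if (!is.null(config$chains_out)) {
    chains <- list()
    for (s in seq_len(nrow(seeds)))
      if (seed_ok(seeds[s, ], field, config$params))
        chains <- c(chains, bidirectional_chains(seeds[s, ], field, config$params))
    write_chains_jsonl(chains, config$chains_out)
    pipeline_log("debug", lvl, "chains written: ", length(chains))
  }
  if (!is.null(config$output)) {
    write_tractogram(tract, config$output)
    pipeline_log("info", lvl, "tractogram written: ", config$output)
  }
  invisible(tract)
}
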