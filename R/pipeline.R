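#' Pipeline orchestration
#'
#' `run_pipeline()` executes the full flow -- register all pairs, build the
#' cost graph, select exemplars, fuse labels, and (when a reference is
#' supplied) evaluate -- persisting auditable artifacts at every stage
#' under the output directory:
#'
#' * `fields/<moving>__to__<fixed>.nii.gz` -- pairwise displacement fields
#'   (reused on re-runs when the cached content hash matches);
#' * `cost_matrix.csv`, `M_raw.csv`, `H_raw.csv`, `M_norm.csv`,
#'   `H_norm.csv` -- graph matrices (`inf` marks absent edges);
#' * `selection.json` -- clusters, exemplars, weights, shortest paths;
#' * `fused.nii.gz`, `confidence.nii.gz` -- fused segmentation and the
#'   per-voxel winning vote score;
#' * `metrics.csv` -- per-structure DSC / MAD / Hausdorff plus a means row.
#'
#' Inputs are assumed bias-corrected, co-aligned to a common space, and
#' skull-stripped; those preprocessing steps belong upstream of this tool.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Construct in code or load from a YAML file with the same field names.
#'
#' @param subject path to the subject NIfTI image.
#' @param atlases named list, each element a list with `image` and `labels`
#'   paths.
#' @param output_dir directory for artifacts (created if needed).
#' @param w1,w2 cost weights; must sum to 1.
#' @param backend registration backend: `"builtin"`, `"external"`
#'   (precomputed fields in `fields_dir`), or `"oracle"` (fields supplied
#'   in memory via `run_pipeline(..., registrations = )`).
#' @param fields_dir directory of `<moving>__to__<fixed>.nii.gz` files for
#'   the external backend.
#' @param mask optional path to a mask label volume.
#' @param reference optional path to a reference segmentation to evaluate
#'   against.
#' @param registration parameters for the builtin registrator.
#' @param seed integer seed recorded in the config (the builtin registrator
#'   is deterministic; the seed matters only for stochastic backends or
#'   simulation).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(subject, atlases, output_dir,
                            w1 = 0.2, w2 = 0.8,
                            backend = c("builtin", "external", "oracle"),
                            fields_dir = NULL, mask = NULL, reference = NULL,
                            registration = list(), seed = 1L,
                            log_level = c("info", "quiet", "debug")) {
  backend <- match.arg(backend)
  log_level <- match.arg(log_level)
  w <- cost_weights(w1, w2)   # validates w1 + w2 = 1
  if (length(atlases) < 2L)
    validation_error("pipeline needs at least 2 atlases, got %d", length(atlases))
  if (is.null(names(atlases)) || anyDuplicated(names(atlases)))
    validation_error("atlases must be a uniquely named list")
  for (id in names(atlases)) {
    a <- atlases[[id]]
    if (is.null(a$image) || is.null(a$labels))
      validation_error("atlas '%s' must have image and labels paths", id)
  }
  structure(list(subject = subject, atlases = atlases,
                 output_dir = output_dir, weights = w, backend = backend,
                 fields_dir = fields_dir, mask = mask, reference = reference,
                 registration = registration, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) io_error("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  for (f in c("subject", "atlases", "output_dir"))
    if (is.null(y[[f]])) validation_error("config is missing required field '%s'", f)
  atl <- y$atlases
  if (!is.null(atl[[1L]]$id)) {           # list-of-records form
    ids <- vapply(atl, function(a) a$id, character(1))
    atl <- stats::setNames(lapply(atl, function(a) a[c("image", "labels")]), ids)
  }
  for (id in names(atl)) {
    for (f in c("image", "labels"))
      if (!file.exists(atl[[id]][[f]]))
        validation_error("atlas '%s': %s file '%s' not found", id, f, atl[[id]][[f]])
  }
  if (!file.exists(y$subject))
    validation_error("subject image '%s' not found", y$subject)
  pipeline_config(subject = y$subject, atlases = atl,
                  output_dir = y$output_dir,
                  w1 = if (is.null(y$w1)) 0.2 else y$w1,
                  w2 = if (is.null(y$w2)) 0.8 else y$w2,
                  backend = if (is.null(y$backend)) "builtin" else y$backend,
                  fields_dir = y$fields_dir, mask = y$mask,
                  reference = y$reference,
                  registration = if (is.null(y$registration)) list() else y$registration,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  log_level = if (is.null(y$log_level)) "info" else y$log_level)
}

pipe_log <- function(cfg, level, fmt, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

# Content hash of an R object (via serialisation to a temp file); keys the
# registration cache on image pair + parameters.
hash_object <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

stage_error <- function(stage, fmt, ...) {
  af_stop("atlasfuse_stage_error", "stage '%s' failed: %s", stage, sprintf(fmt, ...))
}

load_pipeline_inputs <- function(cfg) {
  subject <- read_volume(cfg$subject)
  images <- lapply(cfg$atlases, function(a) read_volume(a$image))
  labels <- lapply(cfg$atlases, function(a) read_volume(a$labels, as_labels = TRUE))
  mask <- if (!is.null(cfg$mask)) read_volume(cfg$mask, as_labels = TRUE)
  list(subject = subject, images = images, labels = labels, mask = mask)
}

#' Register every required pair, with caching
#'
#' Computes (or, for the external backend, loads) the displacement field
#' for every ordered atlas pair and every atlas-to-subject pair, writing
#' each to `fields/` with a content-hash sidecar so identical re-runs skip
#' the work.
#'
#' @param cfg a `pipeline_config`.
#' @param inputs preloaded inputs (optional, from an internal loader).
#' @param registrations in-memory fields for the oracle backend.
#' @return named list of [displacement_field]s keyed `"<moving>__to__<fixed>"`.
#' @export
stage_register_all <- function(cfg, inputs = NULL, registrations = NULL) {
  if (is.null(inputs)) inputs <- load_pipeline_inputs(cfg)
  ids <- names(cfg$atlases)
  fdir <- file.path(cfg$output_dir, "fields")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  pairs <- expand.grid(moving = ids, fixed = c(ids, "subject"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$moving != pairs$fixed, ]
  out <- list()
  n_cached <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$moving[r]; j <- pairs$fixed[r]
    key <- reg_key(i, j)
    fixed_img <- if (j == "subject") inputs$subject else inputs$images[[j]]
    if (cfg$backend == "oracle") {
      if (is.null(registrations[[key]]))
        stage_error("register-all", "oracle backend: no field supplied for %s", key)
      out[[key]] <- registrations[[key]]
      next
    }
    if (cfg$backend == "external") {
      src <- file.path(cfg$fields_dir, paste0(key, ".nii.gz"))
      if (!file.exists(src))
        stage_error("register-all", "missing precomputed field '%s'",
                    paste0(key, ".nii.gz"))
      out[[key]] <- read_field(src)
      next
    }
    path <- file.path(fdir, paste0(key, ".nii.gz"))
    hpath <- file.path(fdir, paste0(key, ".md5"))
    h <- hash_object(list(m = inputs$images[[i]]$data, f = fixed_img$data,
                          p = cfg$registration))
    if (file.exists(path) && file.exists(hpath) &&
        identical(readLines(hpath, warn = FALSE)[1L], h)) {
      pipe_log(cfg, "info", "register-all: cache hit for %s", key)
      out[[key]] <- read_field(path)
      n_cached <- n_cached + 1L
      next
    }
    t0 <- Sys.time()
    res <- register(inputs$images[[i]], fixed_img, backend = "builtin",
                    params = cfg$registration, moving_id = i, fixed_id = j)
    pipe_log(cfg, "debug", "register-all: %s MSD %.5g -> %.5g (%.1fs)", key,
             res$initial_msd, res$residual_msd,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    write_field(res$field, path)
    writeLines(h, hpath)
    out[[key]] <- res$field
  }
  pipe_log(cfg, "info", "register-all: %d pairs (%d cached)", nrow(pairs), n_cached)
  out
}

#' Run the full multi-atlas segmentation pipeline
#'
#' @param cfg a `pipeline_config` (or path to a YAML config file).
#' @param registrations named list of [displacement_field]s for the oracle
#'   backend (ignored otherwise).
#' @return list with `fused` ([label_volume]), `confidence`
#'   ([volume_image]), `selection` (`selection_result`), `graph`
#'   (`atlas_graph`) and `metrics` (data.frame or `NULL`).
#' @export
run_pipeline <- function(cfg, registrations = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!inherits(cfg, "pipeline_config"))
    validation_error("run_pipeline expects a pipeline_config")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_pipeline_inputs(cfg)

  pipe_log(cfg, "info", "stage register-all (%d atlases, backend %s)",
           length(cfg$atlases), cfg$backend)
  regs <- stage_register_all(cfg, inputs, registrations)

  pipe_log(cfg, "info", "stage build-graph")
  g <- tryCatch(
    build_graph(inputs$subject, inputs$images, regs, cfg$weights, inputs$mask),
    atlasfuse_validation_error = function(e)
      stage_error("build-graph", "%s", conditionMessage(e)))
  write_cost_csv(g$cost, file.path(cfg$output_dir, "cost_matrix.csv"))
  write_cost_csv(g$M_raw, file.path(cfg$output_dir, "M_raw.csv"))
  write_cost_csv(g$H_raw, file.path(cfg$output_dir, "H_raw.csv"))
  write_cost_csv(g$M_norm, file.path(cfg$output_dir, "M_norm.csv"))
  write_cost_csv(g$H_norm, file.path(cfg$output_dir, "H_norm.csv"))
  if (cfg$log_level == "debug") {
    pipe_log(cfg, "debug", "cost matrix:\n%s",
             paste(utils::capture.output(print(round(g$cost, 4))), collapse = "\n"))
  }

  pipe_log(cfg, "info", "stage select")
  sel <- select_atlases(g)
  write_selection_json(sel, file.path(cfg$output_dir, "selection.json"))
  pipe_log(cfg, "info", "selected %d exemplar(s): %s", length(sel$exemplars),
           paste(sprintf("%s (w=%.3f)", sel$exemplars, sel$weights), collapse = ", "))

  pipe_log(cfg, "info", "stage fuse")
  stack <- propagate_labels(sel, inputs$labels, regs)
  fused <- weighted_majority_vote(stack, return_confidence = TRUE)
  write_volume(fused$labels, file.path(cfg$output_dir, "fused.nii.gz"))
  write_volume(fused$confidence, file.path(cfg$output_dir, "confidence.nii.gz"))

  metrics <- NULL
  if (!is.null(cfg$reference)) {
    pipe_log(cfg, "info", "stage evaluate")
    ref <- read_volume(cfg$reference, as_labels = TRUE)
    metrics <- evaluate_all(fused$labels, ref)
    utils::write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  list(fused = fused$labels, confidence = fused$confidence,
       selection = sel, graph = g, metrics = metrics)
}

#' Write a phantom population in the layout the pipeline consumes
#'
#' Creates `images/`, `labels/` and `fields/` under `dir`: one image and
#' label file per member plus the subject, and the oracle pairwise fields
#' named `<moving>__to__<fixed>.nii.gz` so the population can be segmented
#' with the external backend.  Also writes a ready-to-run `config.yaml`.
#'
#' @param pspec a `population_spec`.
#' @param dir output directory.
#' @param write_fields if `FALSE`, skip the (many) oracle field files.
#' @return invisibly, the paths list (`config`, `subject`, ids).
#' @export
simulate_population_dir <- function(pspec, dir, write_fields = TRUE) {
  pop <- make_population(pspec)
  for (sub in c("images", "labels", "fields"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  ids <- names(pop$members)
  for (id in ids) {
    write_volume(pop$members[[id]]$image, file.path(dir, "images", paste0(id, ".nii.gz")))
    write_volume(pop$members[[id]]$labels, file.path(dir, "labels", paste0(id, ".nii.gz")))
  }
  write_volume(pop$subject$image, file.path(dir, "images", "subject.nii.gz"))
  write_volume(pop$subject$labels, file.path(dir, "labels", "subject.nii.gz"))
  if (write_fields) {
    regs <- oracle_registrations(pop)
    for (key in names(regs))
      write_field(regs[[key]], file.path(dir, "fields", paste0(key, ".nii.gz")))
  }
  atl <- stats::setNames(lapply(ids, function(id) {
    list(image = file.path(dir, "images", paste0(id, ".nii.gz")),
         labels = file.path(dir, "labels", paste0(id, ".nii.gz")))
  }), ids)
  cfgy <- list(subject = file.path(dir, "images", "subject.nii.gz"),
               atlases = lapply(ids, function(id)
                 c(list(id = id), atl[[id]])),
               output_dir = file.path(dir, "out"),
               backend = if (write_fields) "external" else "builtin",
               fields_dir = file.path(dir, "fields"),
               reference = file.path(dir, "labels", "subject.nii.gz"),
               w1 = 0.2, w2 = 0.8, seed = pspec$seed)
  yaml::write_yaml(cfgy, file.path(dir, "config.yaml"))
  writeLines(jsonlite::toJSON(list(mode_assignment = pop$mode_assignment,
                                   ids = ids), auto_unbox = FALSE),
             file.path(dir, "truth.json"))
  invisible(list(config = file.path(dir, "config.yaml"),
                 subject = file.path(dir, "images", "subject.nii.gz"),
                 ids = ids))
}
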