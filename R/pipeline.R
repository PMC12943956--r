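# Artifact serialization and the end-to-end pipeline. Stage outputs are
# plain JSON/CSV so they can be inspected and re-consumed by the CLI.

#' Write motion segments to JSON
#'
#' Serializes markers, labels, metadata and the per-joint trajectories of a
#' segment tibble.
#'
#' @param segments A segment tibble (see [cut_segments()] /
#'   [segment_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_json <- function(segments, path) {
  meta_cols <- setdiff(names(segments), "trajectory")
  payload <- lapply(seq_len(nrow(segments)), function(i) {
    rec <- as.list(segments[i, meta_cols])
    rec$trajectory <- as.list(segments$trajectory[[i]])
    rec
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read motion segments from JSON
#'
#' @param path A file written by [write_segments_json()].
#' @return A segment tibble with a `trajectory` list column.
#' @export
read_segments_json <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("File does not exist: %s", path))
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- lapply(payload, function(rec) {
    traj <- as_tibble(lapply(rec$trajectory, unlist))
    meta <- rec[setdiff(names(rec), "trajectory")]
    meta <- lapply(meta, function(v) if (is.null(v)) NA else v)
    out <- as_tibble(meta)
    out$trajectory <- list(traj)
    out
  })
  dplyr::bind_rows(rows)
}

#' Write a movement baseline to JSON
#'
#' @param baseline A [build_baseline()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline_json <- function(baseline, path) {
  payload <- list(
    joints = baseline$joints,
    means = as.list(baseline$means),
    l_bar = baseline$l_bar, grid_step = baseline$grid_step,
    mu = baseline$mu, sigma = baseline$sigma,
    n_segments = baseline$n_segments, degenerate = baseline$degenerate
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movement baseline from JSON
#'
#' @param path A file written by [write_baseline_json()].
#' @return A `movement_baseline` object.
#' @export
read_baseline_json <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("File does not exist: %s", path))
  p <- jsonlite::fromJSON(path)
  structure(
    list(
      joints = p$joints, means = as_tibble(p$means),
      l_bar = p$l_bar, grid_step = p$grid_step,
      mu = p$mu, sigma = p$sigma, n_segments = p$n_segments,
      degenerate = p$degenerate, config = dtw_config()
    ),
    class = "movement_baseline"
  )
}

pipeline_stages <- c("simulate", "segment", "baseline", "assess", "evaluate")

#' Derive a stage-specific seed from the run seed
#'
#' Every randomized stage consumes the run seed through this single keyed
#' derivation, so stages are reproducible independently of one another.
#'
#' @param seed Run seed (integer).
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  i <- match(stage, pipeline_stages)
  if (is.na(i)) abort_validation(sprintf("Unknown pipeline stage '%s'.", stage))
  as.integer((as.numeric(seed) * 97 + i * 1009) %% .Machine$integer.max)
}

check_known_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    abort_validation(sprintf("Unknown key(s) in %s: %s.",
                             where, paste(unknown, collapse = ", ")))
  }
}

#' Build and validate a pipeline run configuration
#'
#' A flat configuration with per-stage sections. Unknown keys are rejected
#' and every numeric parameter is validated before any stage runs.
#'
#' @param seed Run seed.
#' @param out_dir Output directory for stage artifacts.
#' @param protocol Named list of [protocol_plan()] arguments.
#' @param movement Named list of [movement_params()] arguments applied to
#'   every exercise (exercise-specific geometry defaults still apply).
#' @param segmentation Named list of [segmentation_params()] arguments, plus
#'   optional `smoothing_window` (odd integer, default 5).
#' @param dtw Named list of [dtw_config()] arguments.
#' @param evaluation Named list: `variants`, `k_closest`, `welch`.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 0L, out_dir = "rehabdtw-output",
                       protocol = list(), movement = list(),
                       segmentation = list(), dtw = list(),
                       evaluation = list(), log_level = c("info", "quiet")) {
  log_level <- rlang::arg_match(log_level)
  check_known_keys(protocol, names(formals(protocol_plan)), "protocol")
  check_known_keys(movement, setdiff(names(formals(movement_params)), "exercise"),
                   "movement")
  check_known_keys(segmentation,
                   c(names(formals(segmentation_params)), "smoothing_window"),
                   "segmentation")
  check_known_keys(dtw, names(formals(dtw_config)), "dtw")
  check_known_keys(evaluation, c("variants", "k_closest", "welch"), "evaluation")

  plan <- do.call(protocol_plan, protocol)
  seg_args <- segmentation
  smoothing_window <- seg_args$smoothing_window %||% 5L
  seg_args$smoothing_window <- NULL
  seg_params <- do.call(segmentation_params, seg_args)
  smoothing_window <- check_count(smoothing_window, "smoothing_window", min = 1L)
  if (smoothing_window %% 2L == 0L) {
    abort_validation("`smoothing_window` must be odd.")
  }
  dtw_cfg <- do.call(dtw_config, dtw)
  params <- lapply(stats::setNames(plan$exercises, plan$exercises), function(ex) {
    do.call(movement_params, c(list(exercise = ex), movement))
  })
  structure(
    list(
      seed = check_count(seed, "seed", min = 0L),
      out_dir = out_dir, log_level = log_level,
      plan = plan, movement = params,
      segmentation = seg_params, smoothing_window = smoothing_window,
      dtw = dtw_cfg,
      variants = evaluation$variants %||%
        c("triple", "dual", "single", "shoulder", "elbow", "wrist"),
      k_closest = evaluation$k_closest %||% 10L,
      welch = evaluation$welch %||% FALSE
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; top-level keys are the arguments of
#'   [run_config()].
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("Config file does not exist: %s", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_known_keys(raw, names(formals(run_config)), "config")
  do.call(run_config, raw)
}

pipeline_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") {
    message(sprintf(paste0("[rehabdtw] ", fmt), ...))
  }
}

#' Run the full pipeline: simulate, segment, baseline, assess, evaluate
#'
#' Generates the synthetic protocol dataset, segments every clip, builds the
#' single-angle subset-B baseline per exercise, assesses all segments and
#' runs the evaluation grid, writing artifacts (JSON/CSV) plus a manifest
#' recording the seed and a hash of the configuration. Re-running with the
#' same configuration reproduces identical numeric outputs.
#'
#' @param config A [run_config()] (or path to a config file).
#' @return Invisibly, a list with the dataset, segments, experiment and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort_validation("`config` must be a run_config or a path to one.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  pipeline_log(config, "simulate: %d participants x %d exercises x %d sides",
               config$plan$n_participants, length(config$plan$exercises),
               length(config$plan$sides))
  dataset <- generate_protocol_dataset(config$plan, config$movement,
                                       seed = stage_seed(config$seed, "simulate"))
  manifest_clips <- dataset[setdiff(names(dataset), "clip")]
  readr::write_csv(manifest_clips, out("clips.csv"), progress = FALSE)

  pipeline_log(config, "segment: %d clips", nrow(dataset))
  segments <- segment_dataset(dataset, config$segmentation,
                              window = config$smoothing_window)
  if (nrow(segments) == 0L) abort_data("Segmentation produced no segments.")
  readr::write_csv(segments[setdiff(names(segments), "trajectory")],
                   out("segments.csv"), progress = FALSE)

  pipeline_log(config, "baseline + assess: single-angle per exercise")
  assigned <- split_subsets(segments, seed = stage_seed(config$seed, "baseline"))
  assessments <- list()
  for (ex in unique(assigned$exercise)) {
    seg_ex <- assigned[assigned$exercise == ex, ]
    joints <- variant_joints(ex, "single")
    seg_sel <- seg_ex
    seg_sel$trajectory <- lapply(seg_sel$trajectory, select_joints, joints = joints)
    baseline <- build_baseline(seg_sel[seg_sel$subset == "B", ], config = config$dtw)
    write_baseline_json(baseline, out(sprintf("baseline_%s.json", ex)))
    if (baseline$degenerate) {
      abort_degenerate(sprintf("Baseline for %s is degenerate (sigma = 0).", ex))
    }
    scored <- assess_segments(seg_sel, baseline, config$dtw)
    assessments[[ex]] <- scored[setdiff(names(scored), "trajectory")]
  }
  assessments <- dplyr::bind_rows(assessments)
  readr::write_csv(assessments, out("assessments.csv"), progress = FALSE)

  pipeline_log(config, "evaluate: %d variants", length(config$variants))
  experiment <- run_experiment(
    segments, config = config$dtw,
    seed = stage_seed(config$seed, "baseline"),
    variants = config$variants, k_closest = config$k_closest,
    welch = config$welch
  )
  readr::write_csv(experiment$comparisons, out("comparisons.csv"), progress = FALSE)
  readr::write_csv(experiment$score_summary, out("score_summary.csv"), progress = FALSE)
  readr::write_csv(experiment$closest_abnormal, out("closest_abnormal.csv"),
                   progress = FALSE)

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    n_clips = nrow(dataset),
    n_segments = nrow(segments),
    segments_per_exercise = as.list(table(segments$exercise)),
    mean_score_by_subset = stats::setNames(
      as.list(tapply(assessments$s_alpha, assessments$subset, mean)),
      sort(unique(assessments$subset))
    )
  )
  jsonlite::write_json(manifest, out("summary.json"), auto_unbox = TRUE, digits = NA)
  pipeline_log(config, "done: artifacts in %s", config$out_dir)
  invisible(list(dataset = dataset, segments = segments,
                 experiment = experiment, manifest = manifest))
}
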