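# End-to-end orchestration: synth -> build -> augment -> split -> train ->
# evaluate -> maps, with a single serializable configuration.

#' Default pipeline configuration
#'
#' A nested list with one section per stage (`cohort`, `template`,
#' `augmentation`, `split`, `network`, `maps`), serializable to a single
#' YAML file. Values mirror the stage defaults: 16 + 16 subjects, 6
#' augmentation variants with a 15-degree yaw limit and 2% noise, an 80/20
#' leakage-safe split, and the default network trained for 200 epochs with
#' batch size 8.
#'
#' @param seed Master seed stamped into every stage.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    template = list(n_vertices = 7859L),
    cohort = list(n_patients = 16L, n_controls = 16L, rater_noise = 0.3,
                  sensor_sd = 0.1),
    augmentation = list(rotation_deg = 15, noise_fraction = 0.02,
                        variants = 6L),
    split = list(train_fraction = 0.8, mode = "stratified"),
    network = list(point_mlp = c(64L, 64L, 128L, 1024L),
                   head = c(512L, 256L), batch_size = 8L, epochs = 200L,
                   learning_rate = 1e-3, points = NULL,
                   loss_mode = "masked"),
    maps = list(enabled = TRUE)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config` (any missing field falls back to the
#'   default).
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the merged `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(default_pipeline_config(seed = user$seed %||% 1))
  merged <- utils::modifyList(base, user)
  structure(merged, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full assessment pipeline
#'
#' Synthesizes a cohort, simulates rater panels and consensus grades, builds
#' and augments the point-cloud samples, splits them without leakage, trains
#' the PointNet regressor, evaluates it on the held-out split, and renders
#' cohort maps. All artifacts (resolved config, manifests, training curve,
#' evaluation report, maps) are written under `out_dir`.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config]).
#' @param out_dir Run directory (created).
#' @param dry_run If `TRUE`, validates the configuration, writes the run
#'   plan, and touches no data.
#' @param verbose Training progress interval in epochs (0 = silent).
#' @return Invisibly, a list with the trained model, the evaluation report,
#'   the split, and the paths written.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         dry_run = FALSE, verbose = 0) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose > 0) message(line)
  }
  write_pipeline_config(config, file.path(out_dir, "config_resolved.yaml"))
  logf("seed %d, config written", config$seed)
  n_orig <- (config$cohort$n_patients + config$cohort$n_controls) * 5L
  plan <- list(
    stages = c("synth", "panels", "build", "augment", "split", "train",
               "evaluate", "maps"),
    n_original_captures = n_orig,
    n_augmented = n_orig * config$augmentation$variants,
    iterations_per_epoch = iterations_per_epoch(
      round(n_orig * config$split$train_fraction) *
        config$augmentation$variants,
      config$network$batch_size))
  jsonlite::write_json(plan, file.path(out_dir, "plan.json"),
                       auto_unbox = TRUE, digits = NA)
  if (dry_run) {
    logf("dry run: plan written, no data touched")
    return(invisible(list(plan = plan, out_dir = out_dir)))
  }

  stage <- function(name, code) {
    ts <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %-8s done in %.1f s", name,
         as.numeric(difftime(Sys.time(), ts, units = "secs")))
    res
  }

  template <- stage("template",
                    make_template(config$template$n_vertices))
  cohort <- stage("synth", synthesize_cohort(
    cohort_spec(config$cohort$n_patients, config$cohort$n_controls,
                rater_noise = config$cohort$rater_noise,
                sensor_sd = config$cohort$sensor_sd,
                seed = config$seed),
    template))
  panels <- stage("panels", simulate_cohort_panels(cohort))
  write_grade_panels(panels, file.path(out_dir, "grade_panels.csv"))
  samples <- stage("build", build_cohort_samples(cohort, panels))
  aug <- stage("augment", augment_samples(
    samples,
    augmentation_config(config$augmentation$rotation_deg,
                        config$augmentation$noise_fraction,
                        config$augmentation$variants),
    seed = config$seed + 10L))
  split <- stage("split", split_samples(
    aug, train_fraction = config$split$train_fraction,
    seed = config$seed + 20L, mode = config$split$mode))
  write_split_manifest(split, file.path(out_dir, "split_manifest.csv"))

  net_args <- config$network[intersect(names(config$network),
                                       names(formals(pointnet_config)))]
  net_args$seed <- config$seed + 30L
  net_cfg <- do.call(pointnet_config, net_args)
  model <- stage("train", train_pointnet(split, net_cfg, verbose = verbose))
  utils::write.csv(model$history, file.path(out_dir, "training_curve.csv"),
                   row.names = FALSE)
  report <- stage("evaluate", evaluate_pointnet(model, split$test))
  jsonlite::write_json(
    list(per_expression = report$per_expression,
         confusion = lapply(report$confusion, function(m)
           if (is.null(m)) NULL else unname(apply(m, 1, as.integer,
                                                  simplify = FALSE))),
         mse = report$mse, r_squared = report$r_squared,
         threshold = report$threshold),
    file.path(out_dir, "evaluation_report.json"),
    auto_unbox = TRUE, digits = NA)

  map_paths <- NULL
  if (isTRUE(config$maps$enabled)) {
    maps <- stage("maps", cohort_map_set(cohort))
    map_paths <- write_cohort_maps(maps, template,
                                   file.path(out_dir, "maps"))
  }
  manifest <- list(
    seed = config$seed,
    config = "config_resolved.yaml",
    artifacts = c("plan.json", "grade_panels.csv", "split_manifest.csv",
                  "training_curve.csv", "evaluation_report.json",
                  if (!is.null(map_paths)) file.path("maps",
                                                     basename(map_paths))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("pipeline complete in %.1f s", manifest$wall_time_s)
  invisible(list(model = model, report = report, split = split,
                 cohort = cohort, out_dir = out_dir))
}

#' Write the meshes and manifest of a synthetic cohort
#'
#' Writes every capture's rest and peak mesh as PLY plus a cohort manifest
#' CSV (subject, expression, laterality, true grade, file paths), the
#' template bundle, and the grade panels.
#'
#' @param cohort A [synthesize_cohort] result.
#' @param out_dir Output directory.
#' @param binary Write binary PLY (default) or ASCII.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, out_dir, binary = TRUE) {
  dir.create(file.path(out_dir, "meshes"), recursive = TRUE,
             showWarnings = FALSE)
  write_template_bundle(cohort$template, out_dir)
  rows <- lapply(cohort$captures, function(cap) {
    id <- paste(cap$subject_id, cap$expression, sep = "_")
    rest_path <- file.path("meshes", paste0(id, "_rest.ply"))
    peak_path <- file.path("meshes", paste0(id, "_peak.ply"))
    write_ply(cap$rest, file.path(out_dir, rest_path), binary = binary)
    write_ply(cap$peak, file.path(out_dir, peak_path), binary = binary)
    data.frame(capture_id = id, subject_id = cap$subject_id,
               cohort = cap$cohort, expression = cap$expression,
               laterality = cap$laterality,
               true_grade = cap$meta$true_grade %||% NA,
               rest_path = rest_path, peak_path = peak_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
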