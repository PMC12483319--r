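# Configuration-driven orchestration: validated YAML/JSON run configs and a
# dispatcher tying simulate -> train -> adapt -> segment -> analyze ->
# evaluate into reproducible runs. The thin shell entry point in
# inst/cli/synrec wraps these functions.

#' Segmentation model presets
#'
#' Working resolutions, patch shapes and postprocessing parameters per
#' segmentation task. The working voxel size is the representative training
#' resolution of the task (inputs are resampled to it before prediction);
#' mitochondria and compartments additionally bin by 2 and 4.
#'
#' @return A tibble, one row per preset.
#' @export
model_presets <- function() {
  tibble::tibble(
    preset = c("vesicles3d", "vesicles2d", "active_zone", "mitochondria",
               "ribbon", "compartments"),
    dimensionality = c(3L, 2L, 3L, 3L, 3L, 3L),
    patch_shape = list(c(48L, 256L, 256L), c(256L, 256L), c(48L, 256L, 256L),
                       c(32L, 256L, 256L), c(64L, 512L, 512L),
                       c(64L, 384L, 384L)),
    voxel_size_nm = c(1.554, 1.554, 1.554, 2 * 1.554, 1.554, 4 * 1.554),
    postprocessing = c("watershed", "watershed", "threshold", "watershed",
                       "threshold", "multicut"),
    boundary_threshold = c(0.5, 0.5, 0.5, 0.25, 0.5, 0.5),
    seed_distance = c(8, 8, NA, 6, NA, 6),
    min_size = c(0, 0, 500, 0, 0, 0)
  )
}

config_schemas <- function() {
  list(
    simulate = list(
      required = c("out_dir"),
      defaults = list(shape = c(64, 64, 64), voxel_size = 1.554,
                      n_vesicles = 20, vesicle_radius_range = c(8, 15),
                      structures = character(0), noise_sd = 0.1, seed = 1)),
    train = list(
      required = c("inputs", "out_checkpoint"),
      defaults = list(dimensionality = 2, iterations = 300,
                      patch_shape = NULL, learning_rate = 1e-4,
                      iters_per_epoch = 50, seed = 1)),
    adapt = list(
      required = c("pretrained", "targets", "out_checkpoint"),
      defaults = list(iterations = 200, t_c = 0.75, alpha = 0.999,
                      patch_shape = NULL, seed = 1)),
    segment = list(
      required = c("input", "output"),
      defaults = list(model = NULL, maps_input = FALSE,
                      boundary_threshold = 0.5, seed_distance = 8,
                      foreground_threshold = 0.5, voxel_size = NULL,
                      postprocessing = "watershed", min_size = 500)),
    analyze = list(
      required = c("vesicles", "output"),
      defaults = list(structures = list(), voxel_size = NULL,
                      pool_criteria = list())),
    evaluate = list(
      required = c("seg", "gt", "output"),
      defaults = list(metric = "f1", iou = 0.5, tolerance = 1,
                      voxel_size = 1)),
    pipeline = list(
      required = c("stages"),
      defaults = list())
  )
}

#' Validate a run configuration
#'
#' Reads a YAML or JSON config (or takes an equivalent named list), checks
#' the command, rejects unknown keys (all offending keys are listed),
#' verifies that referenced input paths exist, and fills defaults.
#'
#' @param cfg A file path or named list with a `command` entry.
#' @return A validated `syn_run_config`.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg)) abort(paste0("config file not found: ", cfg))
    cfg <- if (tolower(tools::file_ext(cfg)) == "json") {
      jsonlite::read_json(cfg, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(cfg)
    }
  }
  if (!is.list(cfg)) abort("config must be a file path or a named list")
  command <- cfg$command
  schemas <- config_schemas()
  if (is.null(command) || !command %in% names(schemas)) {
    abort(paste0("config must name a command, one of: ",
                 paste(names(schemas), collapse = ", ")))
  }
  schema <- schemas[[command]]
  known <- c("command", "seed", "log_level", schema$required,
             names(schema$defaults))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  missing_req <- setdiff(schema$required, names(cfg))
  if (length(missing_req)) {
    abort(paste0("missing required keys: ",
                 paste(missing_req, collapse = ", ")))
  }
  out <- modifyList(schema$defaults, cfg[setdiff(names(cfg), "command")])
  out$command <- command
  # input paths must exist at validation time
  path_keys <- intersect(names(out),
                         c("inputs", "targets", "pretrained", "input",
                           "vesicles", "seg", "gt"))
  for (k in path_keys) {
    paths <- unlist(out[[k]])
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      abort(paste0("missing input path(s) for '", k, "': ",
                   paste(miss, collapse = ", ")))
    }
  }
  structure(out, class = "syn_run_config")
}

#' Execute a validated run configuration
#'
#' Writes the stage artifacts plus a `manifest.json` (command, parameters,
#' seed, package version, artifact list) sufficient to re-run the command.
#' Deterministic commands reproduce identical artifacts for identical
#' config + seed.
#'
#' @param cfg A `syn_run_config` from [validate_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "syn_run_config"))
  artifacts <- switch(cfg$command,
    simulate = run_simulate(cfg),
    train = run_train(cfg),
    adapt = run_adapt(cfg),
    segment = run_segment(cfg),
    analyze = run_analyze(cfg),
    evaluate = run_evaluate(cfg),
    pipeline = {
      res <- lapply(cfg$stages, function(st) run_config(validate_config(st)))
      list(stages = res)
    })
  invisible(artifacts)
}

write_manifest <- function(dir, cfg, artifacts) {
  manifest <- list(
    command = cfg$command,
    parameters = cfg[setdiff(names(cfg), "command")],
    package_version = as.character(utils::packageVersion("synrec")),
    artifacts = artifacts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

run_simulate <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  spec <- phantom_spec(shape = cfg$shape, voxel_size = cfg$voxel_size,
                       n_vesicles = cfg$n_vesicles,
                       vesicle_radius_range = cfg$vesicle_radius_range,
                       structures = cfg$structures, noise_sd = cfg$noise_sd,
                       seed = cfg$seed)
  ph <- generate_phantom(spec)
  arts <- list(raw = file.path(cfg$out_dir, "raw.mrc"))
  write_volume(ph$volume, arts$raw)
  for (nm in names(ph$labels)) {
    p <- file.path(cfg$out_dir, paste0("labels_", nm, ".h5"))
    write_volume(ph$labels[[nm]], p, dataset_key = "labels")
    arts[[paste0("labels_", nm)]] <- p
  }
  maps <- render_oracle_maps(ph$labels$vesicles)
  mp <- file.path(cfg$out_dir, "maps_vesicles.h5")
  write_h5_maps(maps, mp)
  arts$maps_vesicles <- mp
  arts$manifest <- write_manifest(cfg$out_dir, cfg, arts)
  arts
}

write_h5_maps <- function(maps, path) {
  vol <- new_volume(maps$foreground, maps$voxel_size)
  write_volume(vol, path, dataset_key = "foreground")
  write_volume(new_volume(maps$boundary, maps$voxel_size), path,
               dataset_key = "boundary")
  if (!is.null(maps$boundary_distance)) {
    write_volume(new_volume(maps$boundary_distance, maps$voxel_size), path,
                 dataset_key = "boundary_distance")
  }
  path
}

read_h5_maps <- function(path) {
  fg <- read_volume(path, dataset_key = "foreground")
  bd <- read_volume(path, dataset_key = "boundary")
  new_maps(fg$data, bd$data, voxel_size = fg$voxel_size)
}

load_training_item <- function(path) {
  list(volume = read_volume(path, dataset_key = "raw"),
       labels = read_volume(path, dataset_key = "labels", labels = TRUE))
}

run_train <- function(cfg) {
  data <- lapply(cfg$inputs, load_training_item)
  nd <- cfg$dimensionality
  ucfg <- unet_config(dimensionality = nd)
  model <- build_unet(ucfg, seed = cfg$seed)
  patch <- cfg$patch_shape %||% rep(64L, nd)
  tcfg <- train_config(iterations = cfg$iterations,
                       iters_per_epoch = cfg$iters_per_epoch,
                       learning_rate = cfg$learning_rate,
                       patch_shape = patch, seed = cfg$seed)
  trained <- train_supervised(model, data, tcfg)
  trained$voxel_size <- data[[1]]$volume$voxel_size
  save_model(trained, cfg$out_checkpoint)
  arts <- list(checkpoint = cfg$out_checkpoint)
  arts$manifest <- write_manifest(dirname(cfg$out_checkpoint), cfg, arts)
  arts
}

run_adapt <- function(cfg) {
  model <- load_model(cfg$pretrained)
  vols <- lapply(cfg$targets, function(p) read_volume(p, dataset_key = "raw"))
  patch <- cfg$patch_shape %||% rep(64L, model$cfg$dimensionality)
  dcfg <- da_config(t_c = cfg$t_c, alpha = cfg$alpha,
                    iterations = cfg$iterations, patch_shape = patch,
                    seed = cfg$seed)
  res <- adapt_model(model, vols, dcfg)
  save_model(res$model, cfg$out_checkpoint)
  arts <- list(checkpoint = cfg$out_checkpoint)
  arts$manifest <- write_manifest(dirname(cfg$out_checkpoint), cfg, arts)
  arts
}

run_segment <- function(cfg) {
  if (isTRUE(cfg$maps_input)) {
    maps <- read_h5_maps(cfg$input)
  } else {
    if (is.null(cfg$model)) {
      abort("segment needs either maps_input = TRUE or a model checkpoint")
    }
    model <- load_model(cfg$model)
    vol <- read_volume(cfg$input, voxel_size = cfg$voxel_size)
    if (!is.null(model$voxel_size) &&
        any(abs(vol$voxel_size - model$voxel_size) > 1e-6)) {
      vol <- resample_volume(vol, model$voxel_size)
    }
    maps <- predict_tiled(model, vol)
  }
  seg <- switch(cfg$postprocessing,
    watershed = distance_watershed_instances(
      maps, watershed_params(cfg$boundary_threshold, cfg$seed_distance,
                             cfg$foreground_threshold)),
    threshold = segment_active_zone(maps, cfg$foreground_threshold,
                                    cfg$min_size),
    multicut = segment_compartments(maps),
    abort(paste0("unknown postprocessing: ", cfg$postprocessing)))
  write_volume(seg, cfg$output, dataset_key = "labels")
  arts <- list(segmentation = cfg$output)
  arts$manifest <- write_manifest(dirname(cfg$output), cfg, arts)
  arts
}

run_analyze <- function(cfg) {
  ves <- read_volume(cfg$vesicles, dataset_key = "labels", labels = TRUE,
                     voxel_size = cfg$voxel_size)
  structures <- lapply(cfg$structures, function(p)
    read_volume(p, dataset_key = "labels", labels = TRUE,
                voxel_size = cfg$voxel_size))
  crit <- if (length(cfg$pool_criteria)) {
    do.call(pool_criteria, cfg$pool_criteria)
  } else if (all(c("ribbon", "pd", "membrane") %in% names(structures))) {
    pool_criteria()
  } else NULL
  tab <- vesicle_table(ves, structures, criteria = crit)
  utils::write.csv(tab, cfg$output, row.names = FALSE)
  arts <- list(table = cfg$output)
  arts$manifest <- write_manifest(dirname(cfg$output), cfg, arts)
  arts
}

run_evaluate <- function(cfg) {
  seg <- read_volume(cfg$seg, dataset_key = "labels", labels = TRUE,
                     voxel_size = cfg$voxel_size)
  gt <- read_volume(cfg$gt, dataset_key = "labels", labels = TRUE,
                    voxel_size = cfg$voxel_size)
  score <- switch(cfg$metric,
    f1 = glance(matched_f1(seg, gt, cfg$iou)),
    dice = tibble::tibble(dice = dice_score(seg, gt)),
    sbd = tibble::tibble(best_dice = best_dice(seg, gt),
                         symmetric_best_dice = best_dice(seg, gt,
                                                         symmetric = TRUE)),
    surface_dice = tibble::tibble(
      surface_dice = surface_dice(seg, gt, cfg$tolerance)),
    abort(paste0("unknown metric: ", cfg$metric)))
  utils::write.csv(score, cfg$output, row.names = FALSE)
  arts <- list(scores = cfg$output)
  arts$manifest <- write_manifest(dirname(cfg$output), cfg, arts)
  arts
}
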