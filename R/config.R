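#' Default run configuration
#'
#' Nested configuration covering every pipeline stage, with the protocol
#' defaults: learning rate 0.006 with 30% plateau decay, class weights
#' 1/1.5, binarization threshold 0.875, matching gate 50 px, threshold grid
#' 0.500-0.975.  Desk-scale synthetic-data sizes are deliberately small;
#' raise `synth.*` and `train.*` for larger experiments.
#'
#' @return nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_root = "runs/run1",
    synth = list(n_images = 8L, height = 256L, width = 256L,
                 n_cells_range = c(2L, 10L), mean_diameter = 24,
                 diameter_sd = 4, intensity_range = c(120, 255),
                 background_level_range = c(15, 60),
                 background_texture_scale = 60, clump_fraction = 0.3,
                 artifact_rate = 0.5, filament_rate = 0.5, noise_sd = 4),
    split = list(n_test = 2L, val_fraction = 0.3),
    augment = list(factor_manual = 10L, factor_auto = 4L,
                   factor_artifact = 150L, rotation_range = c(-180, 180),
                   noise_sd = 3, brightness_range = c(0.9, 1.1),
                   elastic_alpha = 20, elastic_sigma = 6,
                   manual_fraction = 0.15),
    weightmap = list(w0 = 10, sigma = 25, max_radius = 75),
    model = list(family = "c_resunet", initial_filters = NULL,
                 depth = NULL, batch_norm = TRUE, init_seed = 1L),
    train = list(initial_lr = 0.006, lr_decay_factor = 0.7,
                 lr_patience = 4L, stop_patience = 20L, batch_size = 8L,
                 max_epochs = 10L, crop_size = 128L, augment_data = FALSE,
                 class_weights = list(cell = 1, background = 1.5)),
    postproc = list(threshold = 0.875, min_area = 100, fill_holes = TRUE,
                    avg_cell_diameter = 50),
    eval = list(max_match_dist = 50,
                threshold_grid = seq(0.5, 0.975, by = 0.025))),
    class = "run_config")
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    bv <- base[[key]]
    ov <- override[[key]]
    if (is.list(bv) && !is.null(names(bv)) && length(bv) > 0 &&
        !is.null(names(bv)[1])) {
      if (!is.list(ov))
        stop("configuration key ", full, " must be a section")
      base[[key]] <- merge_config(bv, ov, c(path, key))
    } else {
      base[[key]] <- ov
    }
  }
  base
}

parse_override <- function(s) {
  eq <- regexpr("=", s, fixed = TRUE)
  if (eq < 0) stop("override must be key=value: ", s)
  key <- substr(s, 1, eq - 1)
  val <- yaml::yaml.load(substr(s, eq + 1, nchar(s)))
  keys <- strsplit(key, ".", fixed = TRUE)[[1]]
  out <- val
  for (k in rev(keys)) out <- stats::setNames(list(out), k)
  out
}

validate_run_config <- function(cfg) {
  do.call(synthetic_spec, cfg$synth[setdiff(names(cfg$synth), "n_images")])
  do.call(split_config, c(cfg$split, list(seed = cfg$seed)))
  do.call(augment_config,
          c(cfg$augment, list(seed = cfg$seed)))
  do.call(weight_map_params, cfg$weightmap)
  model_spec_from_config(cfg)
  tr <- cfg$train
  train_config(tr$initial_lr, tr$lr_decay_factor, tr$lr_patience,
               tr$stop_patience, tr$batch_size, tr$max_epochs,
               seed = cfg$seed,
               class_weights = do.call(class_weights, tr$class_weights))
  do.call(postproc_config, cfg$postproc)
  do.call(eval_config, cfg$eval)
  invisible(cfg)
}

model_spec_from_config <- function(cfg) {
  m <- cfg$model
  architecture_spec(m$family,
                    initial_filters = m$initial_filters,
                    depth = m$depth,
                    batch_norm = isTRUE(m$batch_norm))
}

#' Load a run configuration
#'
#' Precedence: package defaults, then the YAML file, then the command-line
#' style `key=value` overrides (dots separate nesting levels, values parsed
#' as YAML).  Unknown keys are rejected by name; the merged configuration
#' is validated section by section.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides character vector of `section.key=value` strings.
#' @return validated `run_config` list.
#' @export
#' @examples
#' cfg <- load_config(NULL, c("postproc.threshold=0.9"))
#' cfg$postproc$threshold
load_config <- function(path = NULL, overrides = character()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    if (length(y)) cfg <- merge_config(cfg, y)
  }
  for (s in overrides) cfg <- merge_config(cfg, parse_override(s))
  validate_run_config(cfg)
  cfg
}

#' Write the resolved configuration next to a run's artifacts
#' @param cfg a `run_config`.
#' @param dir directory to write `config.yaml` into.
#' @return the file path, invisibly.
#' @export
echo_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), p)
  invisible(p)
}
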