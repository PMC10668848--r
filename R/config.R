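#' Default run configuration
#'
#' Nested list mirroring the YAML schema: `seed`, plus blocks `synthetic`
#' (identity count, dispersion, per-session image counts, nuisance levels),
#' `backbone`, `loss`, `train` and `eval`. Unknown keys are rejected by
#' [validate_config()] with an error naming the offending key.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(
      n_ids = 17L, sigma_id = 1.0, per_id_per_session = 8L,
      sessions = c("morning", "noon", "night"), days = c(1L, 2L),
      size = 64L, n_markings = 6L, rgb = FALSE,
      rotation_range = 20, illumination_range = c(0.75, 1.25),
      fog_level = 0.25, partial_crop_prob = 0.08, occlusion_prob = 0.08,
      scale_range = c(0.85, 1.15), noise_sd = 0.02
    ),
    backbone = list(
      input_size = 64L, embed_dim = 128L, architecture = "smallconv",
      channels = c(8L, 16L, 32L, 64L)
    ),
    loss = list(
      s = 10, m = 0.5, lambda_amc = 0.1, lambda_dce = 1, gamma = 3,
      predict_from = "am_head"
    ),
    train = list(
      epochs = 40L, batch_size = 32L, learning_rate = 2e-3,
      optimizer = "adam", augment = "light", train_day = 1L,
      n_known = 10L, n_trials = 5L
    ),
    eval = list(openness_variant = "both", spread = "sd")
  )
}

#' Validate and resolve a run configuration
#'
#' Merges a (possibly partial) configuration over [default_config()],
#' rejecting any key absent from the schema.
#'
#' @param config Named list (e.g. from [load_config()]).
#' @return The resolved configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  merge_block <- function(user, def, path) {
    bad <- setdiff(names(user), names(def))
    if (length(bad) > 0) {
      abort(sprintf("unknown config key: %s%s", path, bad[1]),
            class = "openherd_schema_error")
    }
    for (nm in names(user)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_block(user[[nm]], def[[nm]], paste0(path, nm, "."))
      } else {
        def[[nm]] <- user[[nm]]
      }
    }
    def
  }
  cfg <- merge_block(config, defaults, "")
  stop_if(cfg$train$n_known >= cfg$synthetic$n_ids,
          "train.n_known must be smaller than synthetic.n_ids",
          class = "openherd_schema_error")
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return Resolved configuration (validated against the schema).
#' @export
load_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config '%s' not found", path))
  validate_config(yaml::read_yaml(path))
}

config_nuisance <- function(sc) {
  nuisance_config(
    rotation_range = sc$rotation_range,
    illumination_range = as.numeric(sc$illumination_range),
    fog_level = sc$fog_level,
    partial_crop_prob = sc$partial_crop_prob,
    occlusion_prob = sc$occlusion_prob,
    scale_range = as.numeric(sc$scale_range),
    noise_sd = sc$noise_sd
  )
}

config_backbone <- function(bc) {
  backbone_spec(input_size = bc$input_size, embed_dim = bc$embed_dim,
                architecture = bc$architecture,
                channels = as.integer(bc$channels))
}

config_train <- function(cfg, seed) {
  train_config(
    epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
    learning_rate = cfg$train$learning_rate,
    optimizer = cfg$train$optimizer, augment = cfg$train$augment,
    s = cfg$loss$s, m = cfg$loss$m, lambda_amc = cfg$loss$lambda_amc,
    lambda_dce = cfg$loss$lambda_dce, gamma = cfg$loss$gamma,
    predict_from = cfg$loss$predict_from,
    train_day = cfg$train$train_day, seed = seed
  )
}

#' Reference per-individual image-count table
#'
#' Reads a Table-1-shaped bookkeeping table (one row per individual, one
#' count column per dataset split, plus a `total` row is recomputed rather
#' than trusted). The package ships a reference table for a 17-head herd
#' over one training day and two testing days under
#' `system.file("extdata", "herd_image_counts.csv", package = "openherd")`.
#'
#' @param path CSV with columns `individual`, then one integer column per
#'   split. Defaults to the packaged reference table.
#' @return List: `counts` (tibble without total row) and `totals` (named
#'   numeric, summed over individuals).
#' @export
read_count_table <- function(path = system.file("extdata",
                                                "herd_image_counts.csv",
                                                package = "openherd")) {
  stop_if(!file.exists(path), sprintf("count table '%s' not found", path))
  tab <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stop_if(!"individual" %in% names(tab),
          "count table needs an `individual` column")
  counts <- tab |> filter(.data$individual != "total")
  totals <- vapply(counts[setdiff(names(counts), "individual")], sum,
                   numeric(1))
  list(counts = counts, totals = totals)
}
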