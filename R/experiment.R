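#' Run a full multi-trial open-set experiment
#'
#' Ties everything together: generates (or reuses) the synthetic dataset,
#' draws the random known/unknown splits, trains one model per trial,
#' scores the held-out day, and aggregates the per-trial metrics. Every
#' artifact lands in `out_dir` and is regenerable from the resolved
#' configuration copied there:
#' \itemize{
#'   \item `config.yaml` — resolved configuration (includes the seed)
#'   \item `data/` — images and `manifest.csv`
#'   \item `trial_<t>/` — `checkpoint.rds`, `split.json`, `loss_log.csv`,
#'     `scores.csv`, `metrics.json`
#'   \item `summary.csv` / `summary.json` — per-trial rows and mean/spread
#' }
#'
#' @param config Configuration list (merged over [default_config()]).
#' @param out_dir Run directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return An `osr_metrics` aggregate, invisibly.
#' @export
run_experiment <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }

  manifest <- prepare_data(cfg, file.path(out_dir, "data"), say)
  splits <- make_splits(sort(unique(manifest$individual_id)),
                        n_known = cfg$train$n_known,
                        n_trials = cfg$train$n_trials,
                        seed = derive_seed(cfg$seed, 2))

  reports <- vector("list", nrow(splits))
  for (t in seq_len(nrow(splits))) {
    say("trial %d/%d: training", t, nrow(splits))
    tdir <- file.path(out_dir, sprintf("trial_%d", t))
    dir.create(tdir, showWarnings = FALSE)
    split <- splits[t, ]
    jsonlite::write_json(
      list(trial = t, known_ids = split$known_ids[[1]],
           unknown_ids = split$unknown_ids[[1]], seed = split$seed),
      file.path(tdir, "split.json"), auto_unbox = TRUE)
    model <- train(manifest, split,
                   spec = config_backbone(cfg$backbone),
                   config = config_train(cfg, seed = split$seed))
    save_model(model, file.path(tdir, "checkpoint.rds"))
    utils::write.csv(model$loss_log, file.path(tdir, "loss_log.csv"),
                     row.names = FALSE)
    scores <- score_test_set(model, manifest)
    utils::write.csv(scores, file.path(tdir, "scores.csv"),
                     row.names = FALSE)
    rep <- metric_report(scores)
    jsonlite::write_json(as.list(rep), file.path(tdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    reports[[t]] <- rep |> mutate(trial = t, .before = 1)
  }

  agg <- aggregate_metrics(bind_rows(reports), spread = cfg$eval$spread)
  utils::write.csv(agg$per_trial, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_trial = agg$per_trial, summary = agg$summary),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  say("done: %s", out_dir)
  invisible(agg)
}

prepare_data <- function(cfg, data_dir, say = function(...) NULL) {
  manifest_path <- file.path(data_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    say("reusing dataset in %s", data_dir)
    return(read_manifest(manifest_path))
  }
  sc <- cfg$synthetic
  say("generating %d identities x %d days x %d sessions x %d images",
      sc$n_ids, length(sc$days), length(sc$sessions), sc$per_id_per_session)
  ids <- make_identities(sc$n_ids, sc$sigma_id,
                         seed = derive_seed(cfg$seed, 1),
                         n_markings = sc$n_markings)
  generate_dataset(ids, sc$per_id_per_session, sessions = sc$sessions,
                   nuisance = config_nuisance(sc), out_dir = data_dir,
                   seed = derive_seed(cfg$seed, 3), days = sc$days,
                   size = sc$size, rgb = sc$rgb)
  read_manifest(manifest_path)
}

#' Openness-ladder sweep
#'
#' Holds the unknown set fixed per trial while shrinking the known-class
#' count along `known_counts`, training and evaluating one model per rung
#' and trial; reports per-rung mean metrics together with both openness
#' conventions.
#'
#' @param config Configuration list (merged over [default_config()]).
#' @param out_dir Output directory for the ladder summary.
#' @param known_counts Descending known-class counts (default `10:1`).
#' @param n_unknown_fixed Fixed number of unknown individuals (default 7).
#' @param n_trials Trials per rung (default the config's `train.n_trials`).
#' @param quiet Suppress progress messages.
#' @return Tibble with one row per rung: `known_count`,
#'   `openness_ratio`, `openness_sqrt`, mean `csa`, `auroc`, `oscr`
#'   (also written to `out_dir/ladder.csv`).
#' @export
sweep_openness <- function(config = list(), out_dir,
                           known_counts = 10:1, n_unknown_fixed = 7,
                           n_trials = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  n_trials <- n_trials %||% cfg$train$n_trials
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  manifest <- prepare_data(cfg, file.path(out_dir, "data"), say)
  ladder <- make_openness_ladder(sort(unique(manifest$individual_id)),
                                 n_unknown_fixed = n_unknown_fixed,
                                 known_counts = known_counts,
                                 n_trials = n_trials,
                                 seed = derive_seed(cfg$seed, 4))

  rows <- vector("list", nrow(ladder))
  for (i in seq_len(nrow(ladder))) {
    rung <- ladder[i, ]
    say("rung known=%d trial=%d", rung$known_count, rung$trial)
    model <- train(manifest, rung,
                   spec = config_backbone(cfg$backbone),
                   config = config_train(cfg, seed = rung$seed))
    scores <- score_test_set(model, manifest)
    rows[[i]] <- metric_report(scores) |>
      mutate(trial = rung$trial, known_count = rung$known_count,
             .before = 1)
  }
  per_run <- bind_rows(rows)
  summary <- per_run |>
    group_by(.data$known_count) |>
    summarise(csa = mean(.data$csa), auroc = mean(.data$auroc),
              oscr = mean(.data$oscr), .groups = "drop") |>
    mutate(
      openness_ratio = openness(.data$known_count,
                                .data$known_count + n_unknown_fixed,
                                variant = "ratio"),
      openness_sqrt = openness(.data$known_count,
                               .data$known_count + n_unknown_fixed,
                               variant = "sqrt"),
      .after = "known_count"
    ) |>
    arrange(dplyr::desc(.data$known_count))
  utils::write.csv(summary, file.path(out_dir, "ladder.csv"),
                   row.names = FALSE)
  utils::write.csv(per_run, file.path(out_dir, "ladder_trials.csv"),
                   row.names = FALSE)
  summary
}
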