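# Run configuration, validation, provenance, and the end-to-end pipeline.

default_run_config <- function() {
  list(
    profile = "desk",
    seed = 1L,
    out_dir = "diffage_out",
    n_train = 2000L, n_val = 200L, n_test = 200L,
    grid = 32L,
    percentiles = c(25, 37.5, 50, 62.5, 75),
    min_nonzero_fraction = 0.01,
    noise_sd = 0.02,
    T_steps = 100L,
    learning_rate = 2e-3,
    batch_size = 128L,
    max_epochs = 12L,
    patience = 50L,
    age_bounds = c(3, 30),
    k_rois = 4L,
    dcg_weight = 1,
    n_draws = 4L,
    ensemble_method = "outlier_excluded",
    bias_correction = FALSE
  )
}

#' Documented pipeline defaults
#'
#' One row per configuration key with its default value; this table is the
#' single source the pipeline reads its defaults from, so code and
#' documentation cannot drift apart.
#'
#' @return tibble with `key` and `value` (list-column).
#' @export
diffage_defaults <- function() {
  d <- default_run_config()
  tibble::tibble(key = names(d), value = unname(d))
}

#' Validate a run configuration
#'
#' Fills defaults, rejects unknown keys (strict mode), and checks the
#' profile rules: the `desk` profile forces `T_steps <= 100` and the reduced
#' encoder; `patience >= 1`; `age_bounds` increasing.
#'
#' @param config a named list of overrides, or the path of a YAML file.
#' @return validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  if (!cfg$profile %in% c("desk", "full")) {
    abort("`profile` must be 'desk' or 'full'.")
  }
  if (cfg$profile == "desk" && cfg$T_steps > 100) {
    abort("desk profile requires T_steps <= 100.")
  }
  if (cfg$patience < 1) abort("`patience` must be >= 1.")
  if (!(cfg$age_bounds[1] < cfg$age_bounds[2])) {
    abort("`age_bounds` must be increasing.")
  }
  if (!cfg$ensemble_method %in% c("outlier_excluded", "mean")) {
    abort("`ensemble_method` must be 'outlier_excluded' or 'mean'.")
  }
  structure(cfg, class = "run_config")
}

run_config_training <- function(cfg, seed_offset = 0L) {
  widths <- if (cfg$profile == "desk") c(8L, 16L, 32L) else c(16L, 32L, 64L)
  training_config(
    T_steps = cfg$T_steps, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
    patience = cfg$patience, seed = cfg$seed + seed_offset,
    age_bounds = cfg$age_bounds, encoder_widths = widths,
    k_rois = cfg$k_rois, dcg_weight = cfg$dcg_weight, n_draws = cfg$n_draws)
}

write_provenance <- function(cfg, stage, extra = list()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("diffage")),
                config_hash = rlang::hash(unclass(cfg)),
                seed = cfg$seed, stage = stage,
                external_hooks = list(register = FALSE, skull_strip = FALSE,
                                      n4 = FALSE)),
           extra)
  path <- file.path(cfg$out_dir, "provenance.json")
  existing <- if (file.exists(path)) jsonlite::read_json(path) else list()
  jsonlite::write_json(c(existing, list(log)), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# stage cache: recompute only when the config hash changed
stage_cached <- function(cfg, name, compute) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  key <- rlang::hash(list(unclass(cfg), name))
  path <- file.path(cfg$out_dir, paste0("stage_", name, ".rds"))
  if (file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$key, key)) return(cached$value)
  }
  value <- compute()
  saveRDS(list(key = key, value = value), path)
  value
}

#' Run the full desk-scale pipeline
#'
#' Executes simulate -> preprocess -> train (one model per percentile slice)
#' -> predict -> ensemble -> evaluate on synthetic phantoms, writing
#' artifacts (predictions, consensus, report, provenance) under
#' `config$out_dir`. Stages are cached by config hash: rerunning with an
#' unchanged config skips completed stages.
#'
#' @param config a [validate_config()] result (or a list/YAML path passed to
#'   it).
#' @param through last stage to execute (`"simulate"`, `"preprocess"`,
#'   `"train"`, `"predict"`, or `"evaluate"`); earlier runs' cached stages are
#'   reused.
#' @return For `through = "evaluate"` (default): list with `single_slice`
#'   (per-percentile test MAE), `ensembles` (consensus MAE per method),
#'   `predictions` (per slice x subject), `consensus`, `truth`, and `report`
#'   (one-row summary tibble). Earlier stages return their own artifact.
#' @export
run_pipeline <- function(config = list(),
                         through = c("evaluate", "simulate", "preprocess",
                                     "train", "predict")) {
  through <- match.arg(through)
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  spec <- phantom_spec(grid_shape = rep(cfg$grid, 3), age_range = cfg$age_bounds,
                       noise_sd = cfg$noise_sd)
  sim <- stage_cached(cfg, "simulate", function() {
    list(train = generate_cohort(cfg$n_train, spec, seed = cfg$seed),
         val = generate_cohort(cfg$n_val, spec, seed = cfg$seed + 1000L),
         test = generate_cohort(cfg$n_test, spec, seed = cfg$seed + 2000L))
  })
  if (through == "simulate") {
    write_provenance(cfg, "simulate")
    return(invisible(sim))
  }
  slices <- stage_cached(cfg, "preprocess", function() {
    lapply(sim, cohort_slice_table, percentiles = cfg$percentiles,
           min_nonzero_fraction = cfg$min_nonzero_fraction)
  })
  if (through == "preprocess") {
    write_provenance(cfg, "preprocess")
    return(invisible(slices))
  }
  models <- stage_cached(cfg, "train", function() {
    lapply(seq_along(cfg$percentiles), function(i) {
      p <- cfg$percentiles[i]
      train_diffage(
        dplyr::filter(slices$train, .data$percentile == p),
        run_config_training(cfg, seed_offset = i),
        val_data = dplyr::filter(slices$val, .data$percentile == p))
    })
  })
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cfg$percentiles)) {
    write.csv(models[[i]]$history,
              file.path(cfg$out_dir,
                        sprintf("training_log_p%g.csv", cfg$percentiles[i])),
              row.names = FALSE)
  }
  if (through == "train") {
    write_provenance(cfg, "train")
    return(invisible(models))
  }
  predictions <- stage_cached(cfg, "predict", function() {
    dplyr::bind_rows(lapply(seq_along(cfg$percentiles), function(i) {
      p <- cfg$percentiles[i]
      out <- predict(models[[i]],
                     dplyr::filter(slices$test, .data$percentile == p),
                     seed = cfg$seed + 3000L + i)
      dplyr::select(out, "subject_id", "age", "sex", "percentile",
                    "predicted_age", "prior_global", "prior_local")
    }))
  })
  if (through == "predict") {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(predictions, file.path(cfg$out_dir, "predictions.csv"),
              row.names = FALSE)
    write_provenance(cfg, "predict")
    return(invisible(predictions))
  }
  truth <- sim$test$subjects
  consensus <- ensemble_cohort(predictions, method = cfg$ensemble_method) |>
    dplyr::left_join(truth, by = "subject_id") |>
    dplyr::rename(predicted_age = "final_age")
  single_slice <- predictions |>
    dplyr::group_by(.data$percentile) |>
    dplyr::group_modify(~ mae_iqr(.x)) |>
    dplyr::ungroup()
  ens_mean <- ensemble_cohort(predictions, method = "mean") |>
    dplyr::left_join(truth, by = "subject_id") |>
    dplyr::rename(predicted_age = "final_age")
  ensembles <- dplyr::bind_rows(
    dplyr::mutate(mae_iqr(consensus), method = cfg$ensemble_method),
    dplyr::mutate(mae_iqr(ens_mean), method = "mean"))
  report <- tibble::tibble(
    n_train = cfg$n_train, n_test = cfg$n_test,
    mae_consensus = ensembles$mae[1],
    mae_median_slice = median(single_slice$mae),
    pearson_r = stats::cor(consensus$predicted_age, consensus$age),
    baseline_mae = mean(abs(mean(truth$age) - truth$age)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(predictions, file.path(cfg$out_dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(consensus, file.path(cfg$out_dir, "consensus.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(report), file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, "run")
  list(single_slice = single_slice, ensembles = ensembles,
       predictions = predictions, consensus = consensus, truth = truth,
       report = report, models = models)
}
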