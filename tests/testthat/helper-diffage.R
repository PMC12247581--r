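# shared fixtures: small phantom specs and tiny networks built in code

tiny_spec <- function(noise_sd = 0.02, grid = 16L) {
  phantom_spec(grid_shape = rep(grid, 3), noise_sd = noise_sd)
}

# a deterministic miniature guidance/denoiser stack for unit tests
tiny_nets <- function(hw = c(16L, 16L), seed = 11L, temb_dim = 8L, T_steps = 20L) {
  withr::with_seed(seed, {
    nets <- list(
      rho = diffage:::build_encoder(hw, 1L, c(4L, 8L), c(0L, 0L)),
      tau_g = diffage:::build_saliency_net(hw, 1L, c(4L, 8L)),
      tau_l = diffage:::build_encoder(c(4L, 4L), 1L, c(4L, 8L), c(0L, 0L)),
      schedule = build_schedule(T_steps))
    Fd <- attr(nets$tau_l, "out_dim")
    nets$att <- list(V = diffage:::nn_rnorm_mat(Fd, Fd, 0.3),
                     U = diffage:::nn_rnorm_mat(Fd, Fd, 0.3),
                     w = rnorm(Fd, sd = 0.3))
    nets$head <- list(W = diffage:::nn_rnorm_mat(1, Fd, 0.3), b = 0)
    nets$denoiser <- diffage:::build_mlp(
      attr(nets$rho, "out_dim") + 3L + temb_dim, c(16L, 16L), 1L)
    nets
  })
}

# small slice table for fast training-rule tests
tiny_slice_table <- function(n, seed = 1L, grid = 16L) {
  cohort <- generate_cohort(n, tiny_spec(grid = grid), seed = seed)
  cohort_slice_table(cohort, percentiles = 50)
}

# memoised desk-scale experiment shared by the end-to-end acceptance tests:
# per seed, train one model per percentile slice on 2000 phantoms, predict a
# held-out test set of 200, and return per-slice and ensembled errors
.experiment_cache <- new.env(parent = emptyenv())

phantom_experiment <- function(seed) {
  key <- paste0("seed_", seed)
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  spec <- phantom_spec()
  percentiles <- c(25, 37.5, 50, 62.5, 75)
  train <- cohort_slice_table(generate_cohort(2000, spec, seed = seed),
                              percentiles = percentiles)
  val <- cohort_slice_table(generate_cohort(200, spec, seed = seed + 1000L),
                            percentiles = percentiles)
  test <- cohort_slice_table(generate_cohort(200, spec, seed = seed + 2000L),
                             percentiles = percentiles)
  preds <- dplyr::bind_rows(lapply(seq_along(percentiles), function(i) {
    p <- percentiles[i]
    m <- train_diffage(dplyr::filter(train, percentile == p),
                       training_config(seed = seed + i),
                       val_data = dplyr::filter(val, percentile == p))
    out <- predict(m, dplyr::filter(test, percentile == p),
                   seed = seed + 3000L + i)
    dplyr::select(out, subject_id, age, percentile, predicted_age)
  }))
  slice_mae <- preds |>
    dplyr::group_by(percentile) |>
    dplyr::summarise(mae = mean(abs(predicted_age - age)), .groups = "drop")
  consensus <- ensemble_cohort(preds, method = "outlier_excluded") |>
    dplyr::left_join(dplyr::distinct(preds, subject_id, age), by = "subject_id")
  train_ages <- dplyr::distinct(train, subject_id, age)$age
  test_ages <- dplyr::distinct(test, subject_id, age)$age
  res <- list(
    predictions = preds,
    slice_mae = slice_mae,
    median_slice = preds[preds$percentile == 50, ],
    ensemble_mae = mean(abs(consensus$final_age - consensus$age)),
    median_slice_mae = median(slice_mae$mae),
    baseline_mae = mean(abs(mean(train_ages) - test_ages)))
  .experiment_cache[[key]] <- res
  res
}
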