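#' Linear noise schedule for the diffusion process
#'
#' Per-step noise variances `beta_t` linearly spaced from `beta_start` to
#' `beta_end` (inclusive of both endpoints; defaults 1e-4 and 0.02), with
#' `alpha_t = 1 - beta_t` and the cumulative signal-retention product
#' `alpha_bar_t = prod_{s<=t} alpha_s`.
#'
#' @param T_steps number of diffusion steps (>= 1).
#' @param beta_start,beta_end schedule endpoints, `0 < beta_start <= beta_end < 1`.
#' @return A `diffusion_schedule`: list with `T`, `beta`, `alpha`, `alpha_bar`.
#' @export
build_schedule <- function(T_steps, beta_start = 1e-4, beta_end = 0.02) {
  if (T_steps < 1) abort("`T_steps` must be >= 1.")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    abort("need 0 < beta_start <= beta_end < 1.")
  }
  T_steps <- as.integer(T_steps)
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat("<diffusion_schedule> T =", x$T,
      sprintf("| beta in [%g, %g] | alpha_bar_T = %.4g\n",
              x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

#' Normalise ages to the diffusion response scale
#'
#' Affine map of `[bounds[1], bounds[2]]` onto `[-1, 1]`. Out-of-bounds ages
#' map outside `[-1, 1]` with a warning. `denormalize_age()` is the exact
#' inverse.
#'
#' @param age ages in years.
#' @param bounds numeric(2) age bounds, `bounds[1] < bounds[2]`.
#' @return normalised values.
#' @export
normalize_age <- function(age, bounds = c(3, 30)) {
  if (length(bounds) != 2 || !(bounds[1] < bounds[2])) {
    abort("`bounds` must be increasing numeric(2).")
  }
  y <- 2 * (age - bounds[1]) / (bounds[2] - bounds[1]) - 1
  if (any(abs(y) > 1 + 1e-12)) {
    warn("ages outside `bounds` map outside [-1, 1].")
  }
  y
}

#' @rdname normalize_age
#' @param y normalised values.
#' @export
denormalize_age <- function(y, bounds = c(3, 30)) {
  if (length(bounds) != 2 || !(bounds[1] < bounds[2])) {
    abort("`bounds` must be increasing numeric(2).")
  }
  bounds[1] + (y + 1) * (bounds[2] - bounds[1]) / 2
}

#' Forward noising of a normalised target
#'
#' `y_t = sqrt(alpha_bar_t) * y0 + sqrt(1 - alpha_bar_t) * epsilon`.
#'
#' @param y0 clean normalised target(s).
#' @param t timestep(s) in `[1, T]` (recycled against `y0`).
#' @param epsilon standard-normal draw(s).
#' @param schedule a [build_schedule()] object.
#' @return noised value(s) `y_t`.
#' @export
forward_noise <- function(y0, t, epsilon, schedule) {
  stopifnot(inherits(schedule, "diffusion_schedule"))
  if (any(t < 1 | t > schedule$T)) abort("`t` out of range [1, T].")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * y0 + sqrt(1 - ab) * epsilon
}

# assemble the denoiser input matrix: [rho(x); y_t; y^g; y^l; t-embedding]
denoiser_input <- function(rho_x, yt, y_g, y_l, t, temb_dim, T_max) {
  rho_x <- as.matrix(rho_x)
  n <- ncol(rho_x)
  rbind(rho_x,
        matrix(yt, 1, n), matrix(y_g, 1, n), matrix(y_l, 1, n),
        time_embedding(rep(t, length.out = n), temb_dim, T_max))
}

#' Predict noise with the conditional denoiser
#'
#' Evaluates `epsilon_theta(rho(x), y_t, y^g, y^l, t)`: a multilayer
#' perceptron on the image embedding, the noised target, both guidance
#' priors, and a sinusoidal timestep embedding, ending in a single-output
#' fully connected layer.
#'
#' @param model a fitted `diffage_model` (or a bare denoiser list with
#'   elements `net`, `temb_dim`, `T`).
#' @param rho_x image embedding(s): vector or (dim x n) matrix.
#' @param yt noised target(s).
#' @param y_g,y_l guidance priors.
#' @param t timestep (scalar or length-n).
#' @return numeric vector of predicted noise, one scalar per sample.
#' @export
predict_noise <- function(model, rho_x, yt, y_g, y_l, t) {
  den <- if (inherits(model, "diffage_model")) {
    list(net = model$nets$denoiser, temb_dim = model$config$temb_dim,
         T = model$schedule$T)
  } else model
  if (is.null(dim(rho_x))) rho_x <- matrix(rho_x, ncol = 1)
  Xin <- denoiser_input(rho_x, yt, y_g, y_l, t, den$temb_dim, den$T)
  if (nrow(Xin) != den$net[[1]]$din) {
    abort("denoiser input dimension mismatch.")
  }
  as.numeric(net_forward(den$net, Xin, keep_cache = FALSE)$out)
}

#' Run the reverse (ancestral) diffusion chain
#'
#' Standard DDPM reverse update from `y_T`:
#' `y_{t-1} = (y_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)
#'  + sigma_t z`, with `sigma_t^2 = beta_t` and `z = 0` at `t = 1`.
#'
#' @param eps_fn function `(yt, t) -> eps_hat` (vectorised over `yt`).
#' @param schedule a [build_schedule()] object.
#' @param y_T starting value(s); default standard-normal draws.
#' @param n_chains number of chains when `y_T` is not supplied.
#' @param inject_noise logical; `FALSE` disables the stochastic `sigma_t z`
#'   term (used for closed-form checks).
#' @param rng_seed integer seed; required when the chain is stochastic.
#' @return numeric vector `y_0`, one value per chain (normalised scale).
#' @export
reverse_diffuse <- function(eps_fn, schedule, y_T = NULL, n_chains = 1L,
                            inject_noise = TRUE, rng_seed = NULL) {
  stopifnot(inherits(schedule, "diffusion_schedule"))
  needs_rng <- inject_noise || is.null(y_T)
  if (needs_rng && is.null(rng_seed)) {
    abort("`rng_seed` is required when the reverse chain is stochastic.")
  }
  run <- function() {
    y <- y_T %||% rnorm(n_chains)
    for (t in schedule$T:1) {
      eh <- eps_fn(y, t)
      y <- (y - schedule$beta[t] / sqrt(1 - schedule$alpha_bar[t]) * eh) /
        sqrt(schedule$alpha[t])
      if (inject_noise && t > 1) {
        y <- y + sqrt(schedule$beta[t]) * rnorm(length(y))
      }
    }
    y
  }
  if (needs_rng) with_seed_diffage(rng_seed, run()) else run()
}

#' Sample an age prediction from the reverse diffusion process
#'
#' Runs `n_draws` independent reverse chains conditioned on the image
#' embedding and the dual priors, averages the chain outputs, and maps the
#' result back to years.
#'
#' @param model a fitted `diffage_model`, or a stub list (`net`, `temb_dim`,
#'   `T`, `age_bounds`) for testing.
#' @param rho_x image embedding (vector, one slice).
#' @param y_g,y_l guidance priors (normalised scale).
#' @param schedule optional override of `model$schedule`.
#' @param n_draws chains to average (>= 1).
#' @param rng_seed integer seed (required).
#' @return predicted age in years (scalar).
#' @export
sample_prediction <- function(model, rho_x, y_g, y_l, schedule = NULL,
                              n_draws = 4L, rng_seed = NULL) {
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  schedule <- schedule %||% model$schedule
  bounds <- model$age_bounds %||% model$config$age_bounds
  eps_fn <- function(yt, t) predict_noise(model,
    matrix(rho_x, ncol = 1)[, rep(1L, length(yt)), drop = FALSE], yt,
    rep(y_g, length(yt)), rep(y_l, length(yt)), t)
  y0 <- reverse_diffuse(eps_fn, schedule, n_chains = n_draws,
                        inject_noise = TRUE, rng_seed = rng_seed)
  denormalize_age(mean(y0), bounds)
}
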