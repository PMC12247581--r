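#' Training configuration for the diffusion age model
#'
#' @param T_steps diffusion steps (desk profile uses 100; full fidelity 1000).
#' @param beta_start,beta_end linear noise-schedule endpoints.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs (>= 1): training stops
#'   when the validation loss has not improved for this many consecutive
#'   epochs.
#' @param seed integer seed governing initialisation and the training stream.
#' @param age_bounds years, `[min, max]`, mapped onto the normalised response
#'   scale `[-1, 1]`.
#' @param temb_dim sinusoidal timestep-embedding dimension.
#' @param encoder_widths channels per stage of the image encoder `rho`.
#' @param encoder_res residual blocks per stage of `rho`.
#' @param tau_widths channels per stage of the global/local guidance encoders.
#' @param k_rois ROIs pooled by the local stream.
#' @param patch_size ROI patch side in pixels (default: 1/4 of the slice side).
#' @param dcg_weight weight of the guidance MSE loss in the joint objective.
#' @param mmd_weight weight of each conditional MMD term (0.5 in the total
#'   objective).
#' @param n_draws reverse chains averaged at inference.
#' @param val_fraction fraction split off for validation when no validation
#'   table is supplied.
#' @return a `training_config` list.
#' @export
training_config <- function(T_steps = 100L, beta_start = 1e-4, beta_end = 0.02,
                            learning_rate = 2e-3, batch_size = 128L,
                            max_epochs = 12L, patience = 50L, seed = 1L,
                            age_bounds = c(3, 30), temb_dim = 8L,
                            encoder_widths = c(8L, 16L, 32L),
                            encoder_res = c(0L, 1L, 1L),
                            tau_widths = c(8L, 16L),
                            k_rois = 4L, patch_size = NULL,
                            dcg_weight = 1, mmd_weight = 0.5,
                            n_draws = 4L, val_fraction = 0.1) {
  if (patience < 1) abort("`patience` must be >= 1.")
  if (!(age_bounds[1] < age_bounds[2])) abort("`age_bounds` must be increasing.")
  if (T_steps < 1) abort("`T_steps` must be >= 1.")
  structure(list(T_steps = as.integer(T_steps), beta_start = beta_start,
                 beta_end = beta_end, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 age_bounds = age_bounds, temb_dim = as.integer(temb_dim),
                 encoder_widths = as.integer(encoder_widths),
                 encoder_res = as.integer(encoder_res),
                 tau_widths = as.integer(tau_widths),
                 k_rois = as.integer(k_rois), patch_size = patch_size,
                 dcg_weight = dcg_weight, mmd_weight = mmd_weight,
                 n_draws = as.integer(n_draws), val_fraction = val_fraction),
            class = "training_config")
}

# shared greedy top-k ROI selection with non-maximum suppression;
# returns grid indices and patch top-left coordinates (image space)
roi_select <- function(resp, gh, gw, H, W, k, patch_size) {
  rows <- rep(seq_len(gh), times = gw); cols <- rep(seq_len(gw), each = gh)
  cy <- (rows - 0.5) * (H / gh); cx <- (cols - 0.5) * (W / gw)
  scan_rank <- (rows - 1L) * gw + cols
  ord <- order(-resp, scan_rank)
  radius <- patch_size / 2
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    if (length(sel) > 0 &&
        any(pmax(abs(cy[i] - cy[sel]), abs(cx[i] - cx[sel])) < radius)) next
    sel <- c(sel, i)
  }
  tl_row <- pmin(pmax(round(cy[sel] - patch_size / 2) + 1L, 1L), H - patch_size + 1L)
  tl_col <- pmin(pmax(round(cx[sel] - patch_size / 2) + 1L, 1L), W - patch_size + 1L)
  list(sel = sel, row = as.integer(tl_row), col = as.integer(tl_col))
}

# batched DCG forward pass over a slice matrix X (HW x N)
dcg_forward <- function(nets, X, hw, cfg, keep_cache = TRUE) {
  H <- hw[1]; W <- hw[2]; N <- ncol(X)
  k <- cfg$k_rois
  psz <- cfg$patch_size %||% max(4L, H %/% 4L)
  fg <- net_forward(nets$tau_g, X, keep_cache)
  sal <- fg$out
  grid <- attr(nets$tau_g, "grid_hw")
  y_g <- colMeans(sal)
  # ROI selection + patch index assembly (positions carry no gradient)
  p_off <- as.vector(outer(0:(psz - 1L), H * (0:(psz - 1L)), "+"))
  patch_idx <- matrix(0L, psz * psz, N * k)
  for (n in seq_len(N)) {
    rs <- roi_select(sal[, n], grid[1], grid[2], H, W, k, psz)
    n_sel <- length(rs$sel)
    if (n_sel < k) {  # pad by repeating the strongest ROI
      rs$row <- rep(rs$row, length.out = k); rs$col <- rep(rs$col, length.out = k)
    }
    base <- (rs$col - 1L) * H + rs$row + (n - 1L) * H * W
    patch_idx[, (n - 1L) * k + seq_len(k)] <- outer(p_off, base, "+")
  }
  patches <- matrix(X[patch_idx], psz * psz, N * k)
  fl <- net_forward(nets$tau_l, patches, keep_cache)
  feats <- fl$out                              # F x (N*k)
  Fdim <- nrow(feats)
  tanhv <- tanh(nets$att$V %*% feats)
  sigu <- sigmoid(nets$att$U %*% feats)
  G <- tanhv * sigu
  S <- matrix(colSums(nets$att$w * G), k, N)
  S <- exp(sweep(S, 2, apply(S, 2, max)))
  a <- sweep(S, 2, colSums(S), "/")            # k x N attention weights
  Harr <- array(feats, c(Fdim, k, N))
  z <- matrix(0, Fdim, N)
  for (j in seq_len(k)) z <- z + Harr[, j, ] * rep(a[j, ], each = Fdim)
  y_l <- as.numeric(nets$head$W %*% z) + nets$head$b
  list(y_g = y_g, y_l = y_l, saliency = sal, attention = a,
       cache = if (keep_cache) list(fg = fg$caches, fl = fl$caches,
                                    feats = feats, tanhv = tanhv, sigu = sigu,
                                    G = G, a = a, Harr = Harr, z = z,
                                    grid = grid, k = k, N = N) else NULL)
}

# batched DCG backward pass; returns gradients for tau_g/tau_l/att/head
dcg_backward <- function(nets, fwd, d_yg, d_yl) {
  cc <- fwd$cache
  k <- cc$k; N <- cc$N; Fdim <- nrow(cc$feats)
  # global stream: y_g is the mean of the saliency grid
  n_cells <- prod(cc$grid)
  dsal <- matrix(rep(d_yg, each = n_cells) / n_cells, n_cells, N)
  g_tau_g <- net_backward(nets$tau_g, dsal, cc$fg)$grads
  # local head
  dl <- matrix(d_yl, 1, N)
  dW_head <- tcrossprod(dl, cc$z)
  db_head <- sum(dl)
  dz <- crossprod(nets$head$W, dl)             # F x N
  # attention pooling
  da <- matrix(0, k, N)
  dH1 <- array(0, c(Fdim, k, N))
  for (j in seq_len(k)) {
    da[j, ] <- colSums(cc$Harr[, j, , drop = FALSE][, 1, ] * dz)
    dH1[, j, ] <- dz * rep(cc$a[j, ], each = Fdim)
  }
  ds <- cc$a * (da - rep(colSums(cc$a * da), each = k))
  ds_vec <- as.numeric(ds)
  dG <- outer(as.numeric(nets$att$w), ds_vec)  # A x (N*k)
  dtv <- dG * cc$sigu
  dsu <- dG * cc$tanhv
  dVH <- dtv * (1 - cc$tanhv^2)
  dUH <- dsu * cc$sigu * (1 - cc$sigu)
  g_att <- list(V = tcrossprod(dVH, cc$feats), U = tcrossprod(dUH, cc$feats),
                w = as.numeric(cc$G %*% ds_vec))
  dH <- matrix(dH1, Fdim, k * N) + crossprod(nets$att$V, dVH) +
    crossprod(nets$att$U, dUH)
  g_tau_l <- net_backward(nets$tau_l, dH, cc$fl)$grads
  list(tau_g = g_tau_g, tau_l = g_tau_l, att = g_att,
       head = list(W = dW_head, b = db_head))
}

slice_matrix <- function(slices) {
  X <- vapply(slices, function(s) as.numeric(s), numeric(length(slices[[1]])))
  matrix(X, ncol = length(slices))
}

# one joint training/evaluation pass over a batch; returns losses, and when
# `backward` is TRUE also the full gradient structure
diffage_batch <- function(nets, X, y0, t, eps, ref, hw, cfg, backward = TRUE) {
  n <- length(y0)
  dcg <- dcg_forward(nets, X, hw, cfg, keep_cache = backward)
  loss_dcg <- mean((dcg$y_g - y0)^2 + (dcg$y_l - y0)^2)
  fr <- net_forward(nets$rho, X, keep_cache = backward)
  rho <- fr$out
  ab <- nets$schedule$alpha_bar[t]
  yt <- sqrt(ab) * y0 + sqrt(1 - ab) * eps
  den_fwd <- function(yg, yl) {
    Xin <- denoiser_input(rho, yt, yg, yl, 0, cfg$temb_dim, cfg$T_steps)
    Xin[nrow(Xin) - cfg$temb_dim + seq_len(cfg$temb_dim), ] <-
      time_embedding(t, cfg$temb_dim, cfg$T_steps)
    net_forward(nets$denoiser, Xin, keep_cache = backward)
  }
  f_main <- den_fwd(dcg$y_g, dcg$y_l)
  f_g <- den_fwd(dcg$y_g, dcg$y_g)
  f_l <- den_fwd(dcg$y_l, dcg$y_l)
  eh <- as.numeric(f_main$out); eh_g <- as.numeric(f_g$out)
  eh_l <- as.numeric(f_l$out)
  L_e <- mean((eps - eh)^2)
  h_g <- mmd_bandwidth(eh_g, ref); h_l <- mmd_bandwidth(eh_l, ref)
  L_g <- mmd(eh_g, ref, h_g); L_l <- mmd(eh_l, ref, h_l)
  losses <- list(L_e = L_e, L_mmd_g = L_g, L_mmd_l = L_l, L_dcg = loss_dcg,
                 total = L_e + cfg$mmd_weight * (L_g + L_l) +
                   cfg$dcg_weight * loss_dcg)
  if (!backward) return(list(losses = losses, dcg = dcg))
  rho_dim <- nrow(rho)
  den_bwd <- function(fwd_obj, d_eh) {
    bw <- net_backward(nets$denoiser, matrix(d_eh, 1), fwd_obj$caches)
    list(grads = bw$grads, d_rho = bw$dx[seq_len(rho_dim), , drop = FALSE])
  }
  b_main <- den_bwd(f_main, 2 * (eh - eps) / n)
  b_g <- den_bwd(f_g, cfg$mmd_weight * mmd_grad_a(eh_g, ref, h_g))
  b_l <- den_bwd(f_l, cfg$mmd_weight * mmd_grad_a(eh_l, ref, h_l))
  g_den <- grads_add(grads_add(b_main$grads, b_g$grads), b_l$grads)
  d_rho <- b_main$d_rho + b_g$d_rho + b_l$d_rho
  g_rho <- net_backward(nets$rho, d_rho, fr$caches)$grads
  d_yg <- cfg$dcg_weight * 2 * (dcg$y_g - y0) / n
  d_yl <- cfg$dcg_weight * 2 * (dcg$y_l - y0) / n
  g_dcg <- dcg_backward(nets, dcg, d_yg, d_yl)
  list(losses = losses, dcg = dcg,
       grads = list(rho = g_rho, tau_g = g_dcg$tau_g, tau_l = g_dcg$tau_l,
                    att = g_dcg$att, head = g_dcg$head, denoiser = g_den))
}

nets_get_params <- function(nets) {
  list(rho = net_params(nets$rho), tau_g = net_params(nets$tau_g),
       tau_l = net_params(nets$tau_l), att = nets$att, head = nets$head,
       denoiser = net_params(nets$denoiser))
}

nets_set_params <- function(nets, params) {
  nets$rho <- net_set_params(nets$rho, params$rho)
  nets$tau_g <- net_set_params(nets$tau_g, params$tau_g)
  nets$tau_l <- net_set_params(nets$tau_l, params$tau_l)
  nets$att <- params$att
  nets$head <- params$head
  nets$denoiser <- net_set_params(nets$denoiser, params$denoiser)
  nets
}

#' Train the dual-guidance diffusion age model
#'
#' Joint end-to-end training: per step, a diffusion timestep is drawn
#' uniformly from `[1, T]`, the normalised age is noised by the forward
#' process, and the conditional denoiser, the image encoder, and both
#' guidance streams are updated by Adam on
#' `L_e + 0.5 (L_MMD_g + L_MMD_l) + w_dcg (MSE_g + MSE_l)`. Training stops at
#' `max_epochs` or when the validation loss has not improved for `patience`
#' consecutive epochs; the best-validation parameters are returned.
#'
#' @param data tibble with a `slice` list-column (equal-sized 2D matrices)
#'   and an `age` column in years. Needs >= 2 training rows.
#' @param config a [training_config()].
#' @param val_data optional validation tibble of the same shape (>= 1 row);
#'   when absent, `val_fraction` of `data` is split off.
#' @return A `diffage_model`: fitted networks, schedule, age bounds, config,
#'   and a per-epoch loss history.
#' @export
train_diffage <- function(data, config = training_config(), val_data = NULL) {
  stopifnot(is.data.frame(data), all(c("slice", "age") %in% names(data)))
  cfg <- config
  with_seed_diffage(cfg$seed, {
    if (is.null(val_data)) {
      n_val <- max(1L, round(cfg$val_fraction * nrow(data)))
      idx <- sample.int(nrow(data), n_val)
      val_data <- data[idx, ]; data <- data[-idx, ]
    }
    if (nrow(data) < 2) abort("need >= 2 training examples.")
    hw <- dim(data$slice[[1]])
    X <- slice_matrix(data$slice)
    Xv <- slice_matrix(val_data$slice)
    y0 <- normalize_age(data$age, cfg$age_bounds)
    y0v <- normalize_age(val_data$age, cfg$age_bounds)
    n <- ncol(X); nv <- ncol(Xv)
    schedule <- build_schedule(cfg$T_steps, cfg$beta_start, cfg$beta_end)
    psz <- cfg$patch_size %||% max(4L, hw[1] %/% 4L)
    cfg$patch_size <- psz
    nets <- list(
      rho = build_encoder(hw, 1L, cfg$encoder_widths, cfg$encoder_res),
      tau_g = build_saliency_net(hw, 1L, cfg$tau_widths),
      tau_l = build_encoder(c(psz, psz), 1L, cfg$tau_widths, c(0L, 0L)),
      att = NULL, head = NULL, denoiser = NULL, schedule = schedule)
    Fdim <- attr(nets$tau_l, "out_dim")
    nets$att <- list(V = nn_rnorm_mat(Fdim, Fdim, 1 / sqrt(Fdim)),
                     U = nn_rnorm_mat(Fdim, Fdim, 1 / sqrt(Fdim)),
                     w = rnorm(Fdim, sd = 1 / sqrt(Fdim)))
    nets$head <- list(W = nn_rnorm_mat(1, Fdim, 1 / sqrt(Fdim)), b = 0)
    rho_dim <- attr(nets$rho, "out_dim")
    nets$denoiser <- build_mlp(rho_dim + 3L + cfg$temb_dim, c(64L, 64L), 1L)
    params <- nets_get_params(nets)
    opt <- adam_init(params)
    # fixed validation noising so epoch-to-epoch losses are comparable
    t_val <- sample.int(schedule$T, nv, replace = TRUE)
    eps_val <- rnorm(nv); ref_val <- rnorm(nv)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- vector("list", cfg$max_epochs)
    n_batches <- max(1L, ceiling(n / cfg$batch_size))
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      ep_loss <- c(L_e = 0, L_mmd_g = 0, L_mmd_l = 0, L_dcg = 0, total = 0)
      for (b in seq_len(n_batches)) {
        rows <- perm[(((b - 1L) * cfg$batch_size) + 1L):min(b * cfg$batch_size, n)]
        nb <- length(rows)
        t_b <- sample.int(schedule$T, nb, replace = TRUE)
        eps_b <- rnorm(nb); ref_b <- rnorm(nb)
        out <- diffage_batch(nets, X[, rows, drop = FALSE], y0[rows], t_b,
                             eps_b, ref_b, hw, cfg, backward = TRUE)
        if (!is.finite(out$losses$total)) {
          abort(sprintf("non-finite training loss at epoch %d batch %d.",
                        epoch, b))
        }
        st <- adam_step(params, out$grads, opt, lr = cfg$learning_rate)
        params <- st$params; opt <- st$state
        nets <- nets_set_params(nets, params)
        ep_loss <- ep_loss + unlist(out$losses) * nb / n
      }
      val <- diffage_batch(nets, Xv, y0v, t_val, eps_val, ref_val, hw, cfg,
                           backward = FALSE)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss[["total"]],
        val_loss = val$losses$total, L_e = ep_loss[["L_e"]],
        L_mmd_g = ep_loss[["L_mmd_g"]], L_mmd_l = ep_loss[["L_mmd_l"]],
        L_dcg = ep_loss[["L_dcg"]])
      if (val$losses$total < best$loss - 1e-9) {
        best <- list(loss = val$losses$total, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    nets <- nets_set_params(nets, best$params)
    structure(list(nets = nets, schedule = schedule,
                   age_bounds = cfg$age_bounds, config = cfg,
                   history = dplyr::bind_rows(history),
                   best_epoch = best$epoch, val_loss = best$loss,
                   slice_hw = hw),
              class = "diffage_model")
  })
}

#' @export
print.diffage_model <- function(x, ...) {
  cat("<diffage_model> T =", x$schedule$T,
      "| slices", paste(x$slice_hw, collapse = "x"),
      "| best epoch", x$best_epoch,
      sprintf("| val loss %.4f\n", x$val_loss))
  invisible(x)
}

#' Predict ages for new slices
#'
#' Computes the image embedding and both guidance priors for every slice,
#' then averages `n_draws` reverse-diffusion chains per slice and maps the
#' consensus back to years.
#'
#' @param object a fitted `diffage_model`.
#' @param newdata tibble with a `slice` list-column (any identifier columns
#'   are carried through), or a bare list of matrices.
#' @param n_draws reverse chains averaged per slice (default: training
#'   config).
#' @param seed integer seed for the sampler (required: predictions are
#'   reproducible by construction).
#' @param ... unused.
#' @return the input tibble plus `predicted_age`, `prior_global`,
#'   `prior_local` (all in years).
#' @export
predict.diffage_model <- function(object, newdata, n_draws = NULL,
                                  seed = 1L, ...) {
  if (!is.data.frame(newdata)) newdata <- tibble::tibble(slice = newdata)
  stopifnot("slice" %in% names(newdata))
  n_draws <- as.integer(n_draws %||% object$config$n_draws)
  X <- slice_matrix(newdata$slice)
  N <- ncol(X)
  cfg <- object$config
  sch <- object$schedule
  dcg <- dcg_forward(object$nets, X, object$slice_hw, cfg, keep_cache = FALSE)
  rho <- net_forward(object$nets$rho, X, keep_cache = FALSE)$out
  rep_idx <- rep(seq_len(N), each = n_draws)
  rho_rep <- rho[, rep_idx, drop = FALSE]
  yg_rep <- dcg$y_g[rep_idx]; yl_rep <- dcg$y_l[rep_idx]
  M <- N * n_draws
  y0 <- with_seed_diffage(seed, {
    y <- rnorm(M)
    for (t in sch$T:1) {
      Xin <- rbind(rho_rep, matrix(y, 1), matrix(yg_rep, 1), matrix(yl_rep, 1),
                   time_embedding(rep(t, M), cfg$temb_dim, cfg$T_steps))
      eh <- as.numeric(net_forward(object$nets$denoiser, Xin,
                                   keep_cache = FALSE)$out)
      y <- (y - sch$beta[t] / sqrt(1 - sch$alpha_bar[t]) * eh) / sqrt(sch$alpha[t])
      if (t > 1) y <- y + sqrt(sch$beta[t]) * rnorm(M)
    }
    y
  })
  pred_norm <- colMeans(matrix(y0, n_draws, N))
  out <- tibble::as_tibble(newdata)
  out$predicted_age <- denormalize_age(pred_norm, object$age_bounds)
  out$prior_global <- denormalize_age(dcg$y_g, object$age_bounds)
  out$prior_local <- denormalize_age(dcg$y_l, object$age_bounds)
  out
}

#' @rdname train_diffage
#' @param x a fitted `diffage_model`.
#' @param ... unused.
#' @method tidy diffage_model
#' @export
tidy.diffage_model <- function(x, ...) x$history

#' @rdname train_diffage
#' @method glance diffage_model
#' @export
glance.diffage_model <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 val_loss = x$val_loss, T_steps = x$schedule$T,
                 k_rois = x$config$k_rois, n_draws = x$config$n_draws)
}

#' @rdname train_diffage
#' @param object a fitted `diffage_model`.
#' @method autoplot diffage_model
#' @export
autoplot.diffage_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "joint loss", colour = NULL,
                  title = "Diffusion age model training") +
    ggplot2::theme_minimal()
}

#' Build a slice table from a phantom cohort
#'
#' Preprocesses every volume (intensity normalisation, valid-slice detection,
#' percentile selection) and returns one row per subject x percentile with the
#' extracted slice, ready for [train_diffage()].
#'
#' @param cohort a [generate_cohort()] object.
#' @param percentiles percentile slice positions.
#' @param out_size model input resolution (default: native axial size).
#' @param min_nonzero_fraction valid-slice threshold.
#' @return tibble: subject_id, age, sex, percentile, slice (list-column).
#' @export
cohort_slice_table <- function(cohort, percentiles = c(25, 37.5, 50, 62.5, 75),
                               out_size = NULL, min_nonzero_fraction = 0.01) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  rows <- lapply(seq_along(cohort$volumes), function(i) {
    pp <- preprocess_volume(cohort$volumes[[i]], percentiles,
                            min_nonzero_fraction, out_size)
    tibble::tibble(subject_id = cohort$subjects$subject_id[i],
                   age = cohort$subjects$age[i],
                   sex = cohort$subjects$sex[i],
                   percentile = percentiles,
                   slice = unname(pp$slices))
  })
  dplyr::bind_rows(rows)
}
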