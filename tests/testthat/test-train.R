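test_that("training is reproducible and obeys the early-stopping rule", {
  dat <- tiny_slice_table(24, seed = 30)
  val <- tiny_slice_table(8, seed = 31)
  cfg <- training_config(T_steps = 10, max_epochs = 4, batch_size = 8,
                         seed = 2, patience = 50)
  m1 <- train_diffage(dat, cfg, val_data = val)
  m2 <- train_diffage(dat, cfg, val_data = val)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 4)  # patience > max_epochs: runs to the cap
  p1 <- predict(m1, val, seed = 3)
  p2 <- predict(m2, val, seed = 3)
  expect_identical(p1$predicted_age, p2$predicted_age)
  expect_false(identical(p1$predicted_age,
                         predict(m1, val, seed = 4)$predicted_age))
  # frozen parameters give a constant validation loss: stop at 1 + patience
  cfg0 <- training_config(T_steps = 10, max_epochs = 10, batch_size = 8,
                          seed = 2, patience = 3, learning_rate = 0)
  m0 <- train_diffage(dat, cfg0, val_data = val)
  expect_equal(nrow(m0$history), 4)
  expect_equal(m0$best_epoch, 1)
  expect_error(train_diffage(dat[1, ], cfg, val_data = val), ">= 2")
  expect_error(training_config(patience = 0), "patience")
})

test_that("fitted models expose tidy, glance, autoplot, and loss components", {
  dat <- tiny_slice_table(20, seed = 32)
  val <- tiny_slice_table(6, seed = 33)
  m <- train_diffage(dat, training_config(T_steps = 10, max_epochs = 2,
                                          batch_size = 8, seed = 5),
                     val_data = val)
  td <- tidy(m)
  expect_true(all(c("epoch", "train_loss", "val_loss", "L_e", "L_mmd_g",
                    "L_mmd_l", "L_dcg") %in% names(td)))
  expect_true(all(td$train_loss >= 0))
  expect_true(all(abs(
    m$history$L_e + 0.5 * (m$history$L_mmd_g + m$history$L_mmd_l) +
      m$history$L_dcg - m$history$train_loss) < 1e-9))
  gl <- glance(m)
  expect_equal(gl$epochs_run, 2)
  expect_s3_class(autoplot(m), "ggplot")
  pr <- predict(m, val, seed = 1)
  expect_true(all(c("predicted_age", "prior_global", "prior_local") %in%
                    names(pr)))
  expect_equal(nrow(pr), nrow(val))
})

test_that("cohort slice tables carry one row per subject and percentile", {
  st <- cohort_slice_table(generate_cohort(3, tiny_spec(), seed = 34),
                           percentiles = c(25, 50, 75))
  expect_equal(nrow(st), 9)
  expect_true(all(vapply(st$slice, function(s) all(dim(s) == c(16, 16)),
                         logical(1))))
  st2 <- cohort_slice_table(generate_cohort(2, tiny_spec(), seed = 35),
                            percentiles = 50, out_size = 24)
  expect_identical(dim(st2$slice[[1]]), c(24L, 24L))
})

test_that("hand-written backprop matches finite differences on every stream", {
  set.seed(40)
  n <- 5; hw <- c(16L, 16L)
  X <- matrix(runif(prod(hw) * n), prod(hw), n)
  y0 <- runif(n, -1, 1)
  cfg <- training_config(T_steps = 15, seed = 1)
  cfg$patch_size <- 4L
  nets <- tiny_nets(hw, seed = 41, T_steps = 15L)
  t_b <- sample.int(15, n, TRUE); eps_b <- rnorm(n); ref_b <- rnorm(n)
  out <- diffage:::diffage_batch(nets, X, y0, t_b, eps_b, ref_b, hw, cfg,
                                 backward = TRUE)
  h <- 1e-6
  # pure noise-loss path (guidance and MMD weights zero): image encoder and
  # denoiser gradients
  cfgA <- cfg; cfgA$mmd_weight <- 0; cfgA$dcg_weight <- 0
  outA <- diffage:::diffage_batch(nets, X, y0, t_b, eps_b, ref_b, hw, cfgA,
                                  backward = TRUE)
  fA <- function(nn) diffage:::diffage_batch(nn, X, y0, t_b, eps_b, ref_b,
                                             hw, cfgA, backward = FALSE)$losses$L_e
  numA <- function(set) {
    np <- set(nets, h); nm <- set(nets, -h)
    (fA(np) - fA(nm)) / (2 * h)
  }
  g1 <- outA$grads$rho[[1]]$W[1, 2]
  expect_lt(abs(g1 - numA(function(nn, d) {
    nn$rho[[1]]$params$W[1, 2] <- nn$rho[[1]]$params$W[1, 2] + d; nn
  })), 1e-5 * max(abs(g1), 1e-3))
  g2 <- outA$grads$denoiser[[3]]$b[1]
  expect_lt(abs(g2 - numA(function(nn, d) {
    nn$denoiser[[3]]$params$b[1] <- nn$denoiser[[3]]$params$b[1] + d; nn
  })), 1e-5 * max(abs(g2), 1e-3))
  # guidance path: gradients of the prior MSE through saliency, attention,
  # patch encoder, and head (priors are detached inputs to the denoiser)
  fB <- function(nn) {
    d <- diffage:::dcg_forward(nn, X, hw, cfg, keep_cache = FALSE)
    mean((d$y_g - y0)^2 + (d$y_l - y0)^2)
  }
  numB <- function(set) {
    np <- set(nets, h); nm <- set(nets, -h)
    (fB(np) - fB(nm)) / (2 * h)
  }
  for (probe in list(
    list(g = out$grads$tau_g[[1]]$W[2, 3],
         set = function(nn, d) { nn$tau_g[[1]]$params$W[2, 3] <- nn$tau_g[[1]]$params$W[2, 3] + d; nn }),
    list(g = out$grads$tau_l[[2]]$W[3, 7],
         set = function(nn, d) { nn$tau_l[[2]]$params$W[3, 7] <- nn$tau_l[[2]]$params$W[3, 7] + d; nn }),
    list(g = out$grads$att$V[2, 3],
         set = function(nn, d) { nn$att$V[2, 3] <- nn$att$V[2, 3] + d; nn }),
    list(g = out$grads$att$w[4],
         set = function(nn, d) { nn$att$w[4] <- nn$att$w[4] + d; nn }),
    list(g = out$grads$head$W[1, 2],
         set = function(nn, d) { nn$head$W[1, 2] <- nn$head$W[1, 2] + d; nn }),
    list(g = out$grads$head$b,
         set = function(nn, d) { nn$head$b <- nn$head$b + d; nn })
  )) {
    num <- numB(probe$set)
    expect_lt(abs(probe$g - num), 1e-5 * max(abs(num), 1e-3))
  }
  # MMD gradient with the bandwidth held fixed
  set.seed(42)
  a <- rnorm(8); b <- rnorm(8); bw <- 0.9
  ga <- diffage:::mmd_grad_a(a, b, bw)
  for (i in c(1, 5)) {
    ap <- a; ap[i] <- ap[i] + h; am <- a; am[i] <- am[i] - h
    expect_lt(abs(ga[i] - (mmd(ap, b, bw) - mmd(am, b, bw)) / (2 * h)), 1e-6)
  }
})
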