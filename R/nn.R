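# Minimal batched neural-network core.
#
# Activations are stored as (H*W*C) x N matrices, column-major with h fastest,
# then w, then channel. Convolutions are im2col index gathers followed by BLAS
# GEMM; backward passes are hand-written. This keeps the whole model in plain
# R while remaining fast enough for desk-scale training.

nn_rnorm_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

# ---- layer constructors -----------------------------------------------------

nn_conv <- function(cin, cout, k, stride, pad, in_hw,
                    activation = c("relu", "linear"), residual = FALSE) {
  activation <- match.arg(activation)
  H <- in_hw[1]; W <- in_hw[2]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- (Hp - k) %/% stride + 1L; OW <- (Wp - k) %/% stride + 1L
  if (residual && !(OH == H && OW == W && cin == cout)) {
    abort("residual conv requires matching input/output geometry.")
  }
  # filter offsets (kh fastest, kw, channel) and output-position bases
  off <- as.vector(outer(outer(0:(k - 1L), Hp * (0:(k - 1L)), "+"),
                         Hp * Wp * (0:(cin - 1L)), "+"))
  base <- as.vector(outer(stride * (0:(OH - 1L)), Hp * stride * (0:(OW - 1L)), "+"))
  idx <- as.integer(as.vector(outer(off, base, "+")) + 1L)
  inner_idx <- if (pad > 0) {
    as.integer(as.vector(outer(outer(seq_len(H) + pad, Hp * (seq_len(W) - 1L + pad), "+"),
                               Hp * Wp * (0:(cin - 1L)), "+")))
  } else NULL
  k2cin <- k * k * cin
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
       in_hw = c(H, W), out_hw = c(OH, OW), padded_hw = c(Hp, Wp),
       idx = idx, inner_idx = inner_idx, k2cin = k2cin,
       activation = activation, residual = residual,
       params = list(W = nn_rnorm_mat(cout, k2cin, sqrt(2 / k2cin)),
                     b = rep(0, cout)))
}

nn_dense <- function(din, dout, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "dense", din = din, dout = dout, activation = activation,
       params = list(W = nn_rnorm_mat(dout, din, sqrt(2 / din)),
                     b = rep(0, dout)))
}

nn_gap <- function(in_hw, cin) {
  list(type = "gap", hw = prod(in_hw), cin = cin, params = list())
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, X) {
  switch(layer$type,
    conv = {
      N <- ncol(X)
      if (layer$pad > 0) {
        Xp <- matrix(0, prod(layer$padded_hw) * layer$cin, N)
        Xp[layer$inner_idx, ] <- X
      } else Xp <- X
      C <- Xp[layer$idx, , drop = FALSE]
      dim(C) <- c(layer$k2cin, length(layer$idx) %/% layer$k2cin * N)
      Y <- layer$params$W %*% C + layer$params$b
      n_pos <- prod(layer$out_hw)
      Y <- array(Y, c(layer$cout, n_pos, N))
      Y <- aperm(Y, c(2, 1, 3))
      dim(Y) <- c(n_pos * layer$cout, N)
      if (layer$residual) Y <- Y + X
      mask <- NULL
      if (layer$activation == "relu") {
        mask <- Y > 0
        Y[!mask] <- 0
      }
      list(out = Y, cache = list(C = C, mask = mask, N = N))
    },
    dense = {
      Y <- layer$params$W %*% X + layer$params$b
      mask <- NULL
      if (layer$activation == "relu") {
        mask <- Y > 0
        Y[!mask] <- 0
      }
      list(out = Y, cache = list(X = X, mask = mask))
    },
    gap = {
      N <- ncol(X)
      dim(X) <- c(layer$hw, layer$cin * N)
      M <- colMeans(X)
      dim(M) <- c(layer$cin, N)
      list(out = M, cache = list(N = N))
    })
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      N <- cache$N
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      dres <- if (layer$residual) dout else NULL
      n_pos <- prod(layer$out_hw)
      dY <- array(dout, c(n_pos, layer$cout, N))
      dY <- aperm(dY, c(2, 1, 3))
      dim(dY) <- c(layer$cout, n_pos * N)
      dW <- tcrossprod(dY, cache$C)
      db <- rowSums(dY)
      dC <- crossprod(layer$params$W, dY)
      dim(dC) <- c(layer$k2cin * n_pos, N)
      agg <- rowsum(dC, layer$idx)
      dXp <- matrix(0, prod(layer$padded_hw) * layer$cin, N)
      dXp[as.integer(rownames(agg)), ] <- agg
      dX <- if (layer$pad > 0) dXp[layer$inner_idx, , drop = FALSE] else dXp
      if (!is.null(dres)) dX <- dX + dres
      list(dx = dX, grads = list(W = dW, b = db))
    },
    dense = {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      dW <- tcrossprod(dout, cache$X)
      db <- rowSums(dout)
      dX <- crossprod(layer$params$W, dout)
      list(dx = dX, grads = list(W = dW, b = db))
    },
    gap = {
      N <- cache$N
      dX <- dout[rep(seq_len(layer$cin * N) - 1L, each = layer$hw) + 1L] / layer$hw
      dX <- matrix(dX, layer$hw * layer$cin, N)
      list(dx = dX, grads = list())
    })
}

net_forward <- function(net, X, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net)) else NULL
  for (i in seq_along(net)) {
    fw <- layer_forward(net[[i]], X)
    X <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(net, dout, caches) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    bw <- layer_backward(net[[i]], dout, caches[[i]])
    dout <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dout, grads = grads)
}

net_params <- function(net) lapply(net, function(l) l$params)

net_set_params <- function(net, params) {
  for (i in seq_along(net)) net[[i]]$params <- params[[i]]
  net
}

# ---- network builders -------------------------------------------------------

# small residual convolutional encoder: stride-2 stages with optional
# stride-1 residual blocks, global average pooling to a feature vector
build_encoder <- function(in_hw, cin = 1L, widths = c(8L, 16L, 32L),
                          n_res = c(0L, 1L, 1L)) {
  net <- list()
  hw <- in_hw
  cprev <- cin
  for (s in seq_along(widths)) {
    net[[length(net) + 1L]] <- nn_conv(cprev, widths[s], 3L, 2L, 1L, hw, "relu")
    hw <- net[[length(net)]]$out_hw
    cprev <- widths[s]
    for (r in seq_len(n_res[min(s, length(n_res))])) {
      net[[length(net) + 1L]] <- nn_conv(cprev, cprev, 3L, 1L, 1L, hw, "relu",
                                         residual = TRUE)
    }
  }
  net[[length(net) + 1L]] <- nn_gap(hw, cprev)
  attr(net, "out_dim") <- cprev
  net
}

# global-stream encoder: conv stages then a 1x1 linear conv producing a
# single-channel saliency map over the final feature grid
build_saliency_net <- function(in_hw, cin = 1L, widths = c(8L, 16L)) {
  net <- list()
  hw <- in_hw
  cprev <- cin
  for (s in seq_along(widths)) {
    net[[length(net) + 1L]] <- nn_conv(cprev, widths[s], 3L, 2L, 1L, hw, "relu")
    hw <- net[[length(net)]]$out_hw
    cprev <- widths[s]
  }
  net[[length(net) + 1L]] <- nn_conv(cprev, 1L, 1L, 1L, 0L, hw, "linear")
  attr(net, "grid_hw") <- hw
  net
}

build_mlp <- function(din, hidden = c(64L, 64L), dout = 1L) {
  net <- list()
  dprev <- din
  for (h in hidden) {
    net[[length(net) + 1L]] <- nn_dense(dprev, h, "relu")
    dprev <- h
  }
  net[[length(net) + 1L]] <- nn_dense(dprev, dout, "linear")
  net
}

# ---- sinusoidal timestep embedding ------------------------------------------

time_embedding <- function(t, dim = 8L, T_max = 1000L) {
  half <- dim %/% 2L
  freqs <- exp(-log(T_max * 10) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(freqs, as.numeric(t))
  rbind(sin(ang), cos(ang))
}

# ---- Adam optimiser over nested parameter lists ------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# elementwise sum of two parallel gradient structures
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- grads_add(a[[i]], b[[i]])
    a
  } else a + b
}
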