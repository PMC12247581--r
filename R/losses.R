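#' Noise-estimation loss
#'
#' Squared Euclidean norm of the difference between true and predicted noise,
#' averaged over the batch. Inputs are matrices with one sample per row (a
#' bare numeric vector is treated as a single sample).
#'
#' @param epsilon true noise draws (n x d matrix, or a single vector).
#' @param epsilon_hat predicted noise, same shape.
#' @return scalar loss (>= 0).
#' @export
noise_loss <- function(epsilon, epsilon_hat) {
  if (is.null(dim(epsilon))) epsilon <- matrix(epsilon, nrow = 1)
  if (is.null(dim(epsilon_hat))) epsilon_hat <- matrix(epsilon_hat, nrow = 1)
  if (!all(dim(epsilon) == dim(epsilon_hat))) {
    abort("`epsilon` and `epsilon_hat` must have the same shape.")
  }
  mean(rowSums((epsilon - epsilon_hat)^2))
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
}

# squared Euclidean distance matrix between rows of a and rows of b
sqdist <- function(a, b) {
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Median-heuristic kernel bandwidth
#'
#' Median pairwise Euclidean distance over the pooled sample (off-diagonal
#' pairs); falls back to 1 when all points coincide.
#'
#' @param a,b point sets (rows = observations; vectors = 1-D points).
#' @return scalar bandwidth.
#' @export
mmd_bandwidth <- function(a, b) {
  z <- rbind(as_point_matrix(a), as_point_matrix(b))
  d2 <- sqdist(z, z)
  d <- sqrt(d2[upper.tri(d2)])
  h <- median(d)
  if (!is.finite(h) || h <= 0) 1 else h
}

#' Maximum mean discrepancy (biased V-statistic, Gaussian kernel)
#'
#' `mean_aa + mean_bb - 2 * mean_ab` of Gaussian kernel evaluations
#' `k(x, y) = exp(-||x - y||^2 / (2 h^2))`. The biased estimator is
#' non-negative for any input and zero when the two samples coincide.
#'
#' @param sample_a,sample_b point sets (rows = observations; numeric vectors
#'   are 1-D points). Each needs >= 1 point (>= 2 recommended).
#' @param bandwidth Gaussian kernel bandwidth `h`; default: median heuristic
#'   on the pooled sample.
#' @return scalar MMD^2 estimate (>= 0).
#' @export
mmd <- function(sample_a, sample_b, bandwidth = NULL) {
  a <- as_point_matrix(sample_a); b <- as_point_matrix(sample_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("MMD needs non-empty samples.")
  if (ncol(a) != ncol(b)) abort("samples must have the same dimension.")
  h <- bandwidth %||% mmd_bandwidth(a, b)
  g <- 1 / (2 * h^2)
  kaa <- mean(exp(-g * sqdist(a, a)))
  kbb <- mean(exp(-g * sqdist(b, b)))
  kab <- mean(exp(-g * sqdist(a, b)))
  max(kaa + kbb - 2 * kab, 0)
}

# gradient of mmd(a, b | h) with respect to the points of `a`
# (bandwidth treated as a constant)
mmd_grad_a <- function(a, b, bandwidth) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  m <- nrow(a); n <- nrow(b)
  g <- 1 / (2 * bandwidth^2)
  kaa <- exp(-g * sqdist(a, a))
  kab <- exp(-g * sqdist(a, b))
  # d/da_i of (1/m^2) sum k(a_i, a_j): each pair appears twice
  grad <- matrix(0, m, ncol(a))
  for (d in seq_len(ncol(a))) {
    da <- outer(a[, d], a[, d], "-")
    db <- outer(a[, d], b[, d], "-")
    grad[, d] <- (2 / m^2) * rowSums(kaa * (-2 * g * da)) -
      (2 / (m * n)) * rowSums(kab * (-2 * g * db))
  }
  grad
}

#' Condition-specific MMD regularisers
#'
#' One MMD term per guidance condition: the batch of noise predictions made
#' under global-prior conditioning, and the batch made under local-prior
#' conditioning, are each pulled toward a standard-normal reference sample.
#'
#' @param epsilon_hats_g noise predictions under global-prior conditioning.
#' @param epsilon_hats_l noise predictions under local-prior conditioning.
#' @param reference standard-normal reference draws.
#' @param bandwidth optional shared kernel bandwidth (default: median
#'   heuristic per term).
#' @return named list `L_mmd_g`, `L_mmd_l`. Batches of size 1 contribute 0
#'   with a warning.
#' @export
conditional_mmd_losses <- function(epsilon_hats_g, epsilon_hats_l, reference,
                                   bandwidth = NULL) {
  one <- function(x) {
    if (length(x) < 2) {
      warn("MMD term skipped: batch size < 2 contributes zero.")
      return(0)
    }
    mmd(x, reference, bandwidth)
  }
  list(L_mmd_g = one(epsilon_hats_g), L_mmd_l = one(epsilon_hats_l))
}

#' Total diffusion training objective
#'
#' `L_diff = L_e + 0.5 * (L_mmd_g + L_mmd_l)`.
#'
#' @param L_e noise-estimation loss (>= 0).
#' @param L_mmd_g,L_mmd_l condition-specific MMD terms (>= 0).
#' @return scalar total loss.
#' @export
total_loss <- function(L_e, L_mmd_g, L_mmd_l) {
  if (any(c(L_e, L_mmd_g, L_mmd_l) < 0)) {
    abort("loss components must be non-negative.")
  }
  L_e + 0.5 * (L_mmd_g + L_mmd_l)
}

#' Loss breakdown row
#'
#' @param L_e,L_mmd_g,L_mmd_l loss components.
#' @return one-row tibble with the components and the total.
#' @export
loss_breakdown <- function(L_e, L_mmd_g, L_mmd_l) {
  tibble::tibble(L_e = L_e, L_mmd_g = L_mmd_g, L_mmd_l = L_mmd_l,
                 L_diff = total_loss(L_e, L_mmd_g, L_mmd_l))
}
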