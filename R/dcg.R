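# Dual-Granularity Conditional Guidance: a global prior from a whole-image
# saliency map and a local prior from attention-pooled region-of-interest
# features. Both priors live on the normalised age scale and condition every
# diffusion step.

#' Compute a saliency map for one slice
#'
#' The slice is passed through the global encoder; its final 1x1 linear
#' convolution produces one response per spatial location of the feature grid.
#'
#' @param slice_image 2D numeric matrix.
#' @param global_encoder a saliency network built by the trainer (also found
#'   at `model$nets$tau_g` of a fitted model).
#' @return numeric matrix, the response grid.
#' @export
compute_saliency <- function(slice_image, global_encoder) {
  hw <- global_encoder[[1]]$in_hw
  if (!all(dim(slice_image) == hw)) {
    abort(sprintf("slice must be %dx%d for this encoder.", hw[1], hw[2]))
  }
  X <- matrix(as.numeric(slice_image), ncol = 1)
  out <- net_forward(global_encoder, X, keep_cache = FALSE)$out
  grid <- attr(global_encoder, "grid_hw")
  matrix(out, grid[1], grid[2])
}

#' Global prior from a saliency map
#'
#' The arithmetic mean of all saliency responses.
#'
#' @param saliency numeric matrix (non-empty).
#' @return scalar prior on the normalised age scale.
#' @export
global_prior <- function(saliency) {
  if (length(saliency) == 0) abort("empty saliency map.")
  mean(saliency)
}

#' Extract regions of interest from a saliency map
#'
#' Greedy top-k selection of the highest saliency responses with non-maximum
#' suppression: once a location is chosen, all locations whose corresponding
#' image-space centres lie within `patch_size / 2` (Chebyshev distance) are
#' suppressed. Ties are broken by row-major scan order of the saliency grid.
#' Each selected location is mapped back to a `patch_size` x `patch_size`
#' image patch (clamped to the image borders).
#'
#' @param saliency response grid (matrix).
#' @param slice_image the underlying 2D image.
#' @param k number of ROIs requested (>= 1); fewer are returned with a
#'   warning when suppression exhausts the grid.
#' @param patch_size side of the square image patch (default: 1/4 of the
#'   image side).
#' @return tibble with one row per ROI: `grid_row`, `grid_col`, `response`,
#'   `row`, `col` (patch top-left in image coordinates) and a `patch`
#'   list-column of matrices, ordered by decreasing response.
#' @export
extract_rois <- function(saliency, slice_image, k = 4L,
                         patch_size = max(4L, nrow(slice_image) %/% 4L)) {
  if (k < 1) abort("`k` must be >= 1.")
  gh <- nrow(saliency); gw <- ncol(saliency)
  H <- nrow(slice_image); W <- ncol(slice_image)
  scale_h <- H / gh; scale_w <- W / gw
  # image-space centres of grid cells
  rows <- as.vector(row(saliency)); cols <- as.vector(col(saliency))
  cy <- (rows - 0.5) * scale_h; cx <- (cols - 0.5) * scale_w
  resp <- as.vector(saliency)
  # row-major scan rank for tie-breaking
  scan_rank <- (rows - 1L) * gw + cols
  ord <- order(-resp, scan_rank)
  radius <- patch_size / 2
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    if (length(sel) > 0) {
      d <- pmax(abs(cy[i] - cy[sel]), abs(cx[i] - cx[sel]))
      if (any(d < radius)) next
    }
    sel <- c(sel, i)
  }
  if (length(sel) < k) {
    warn(sprintf("only %d of %d ROIs available after suppression.",
                 length(sel), k))
  }
  tl_row <- pmin(pmax(round(cy[sel] - patch_size / 2) + 1L, 1L), H - patch_size + 1L)
  tl_col <- pmin(pmax(round(cx[sel] - patch_size / 2) + 1L, 1L), W - patch_size + 1L)
  patches <- lapply(seq_along(sel), function(j) {
    slice_image[tl_row[j] + 0:(patch_size - 1L), tl_col[j] + 0:(patch_size - 1L)]
  })
  tibble::tibble(grid_row = rows[sel], grid_col = cols[sel],
                 response = resp[sel],
                 row = as.integer(tl_row), col = as.integer(tl_col),
                 patch = patches)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gated attention weights over instance features
#'
#' `a = softmax_k( w' (tanh(V h_k) * sigmoid(U h_k)) )`: non-negative weights
#' summing to one, used to pool ROI feature vectors into a single slice-level
#' vector.
#'
#' @param features feature vectors: a matrix with one instance per column, or
#'   a list of vectors.
#' @param V,U projection matrices (attention dim x feature dim).
#' @param w scoring vector (attention dim).
#' @return numeric vector of attention weights (one per instance, sums to 1).
#' @export
gated_attention <- function(features, V, U, w) {
  H <- if (is.list(features)) do.call(cbind, features) else as.matrix(features)
  if (ncol(H) < 1) abort("need at least one feature vector.")
  if (ncol(V) != nrow(H) || ncol(U) != nrow(H)) {
    abort("attention parameter dimensions do not match the features.")
  }
  s <- as.numeric(crossprod(w, tanh(V %*% H) * sigmoid(U %*% H)))
  e <- exp(s - max(s))
  e / sum(e)
}

#' Local prior from attention-pooled ROI features
#'
#' Each ROI patch is encoded by the local encoder; gated attention combines
#' the feature vectors into a weighted sum; a linear head maps the pooled
#' vector to the local prior. With an empty ROI list the global prior is
#' returned with a warning.
#'
#' @param rois tibble from [extract_rois()] (needs the `patch` list-column).
#' @param local_encoder the local patch encoder network.
#' @param attention list with elements `V`, `U`, `w` (see [gated_attention()]).
#' @param head list with `W` (1 x feature dim) and `b` (scalar).
#' @param fallback value returned (with a warning) when `rois` is empty,
#'   normally the global prior.
#' @return scalar local prior on the normalised age scale.
#' @export
local_prior <- function(rois, local_encoder, attention, head, fallback = NA_real_) {
  if (nrow(rois) == 0) {
    warn("no ROIs: falling back to the global prior.")
    return(fallback)
  }
  X <- vapply(rois$patch, function(p) as.numeric(p),
              numeric(length(rois$patch[[1]])))
  X <- matrix(X, ncol = nrow(rois))
  feats <- net_forward(local_encoder, X, keep_cache = FALSE)$out
  a <- gated_attention(feats, attention$V, attention$U, attention$w)
  z <- as.numeric(feats %*% a)
  as.numeric(head$W %*% z + head$b)
}

#' Guidance (DCG) training loss
#'
#' Mean over the batch of `(y_g - y)^2 + (y_l - y)^2`: both priors are
#' regressed onto the true (normalised) age.
#'
#' @param y_g,y_l prior vectors.
#' @param y_true_normalized true ages on the normalised scale.
#' @return scalar loss.
#' @export
dcg_loss <- function(y_g, y_l, y_true_normalized) {
  if (!all(is.finite(c(y_g, y_l, y_true_normalized)))) {
    abort("dcg_loss inputs must be finite.")
  }
  mean((y_g - y_true_normalized)^2 + (y_l - y_true_normalized)^2)
}
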