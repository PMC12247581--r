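#' Volume image container
#'
#' A 3D intensity array plus voxel spacing (mm per axis) and an orientation
#' label triple. The axial (inferior-superior) axis is taken as the third
#' array axis unless `orientation` says otherwise.
#'
#' @param intensities 3D numeric array.
#' @param voxel_spacing numeric(3), mm per axis, all > 0.
#' @param orientation character(3) axis labels; default `c("R","A","S")`.
#' @return A `volume_image` object.
#' @export
volume_image <- function(intensities, voxel_spacing = c(1, 1, 1),
                         orientation = c("R", "A", "S")) {
  if (length(dim(intensities)) != 3L) abort("`intensities` must be a 3D array.")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    abort("`voxel_spacing` must be 3 positive values (mm).")
  }
  structure(list(data = intensities, spacing = as.numeric(voxel_spacing),
                 orientation = orientation),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image>", paste(dim(x$data), collapse = "x"), "voxels @",
      paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  invisible(x)
}

as_volume_image <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "volume_image")) x else volume_image(x, spacing)
}

# axial = inferior-superior axis; honoured from orientation labels (S or I)
axial_axis <- function(volume) {
  ax <- which(volume$orientation %in% c("S", "I"))
  if (length(ax) == 1L) ax else 3L
}

#' Rescale a volume to isotropic voxel spacing
#'
#' Trilinear interpolation onto a grid of `target_mm` isotropic voxels. The
#' physical extent of the volume is preserved to within one voxel per axis,
#' so anatomical size differences survive the resampling.
#'
#' @param volume a `volume_image` (or bare 3D array, assumed at 1 mm).
#' @param target_mm target isotropic spacing in mm (> 0).
#' @return A `volume_image` at `target_mm` isotropic spacing.
#' @export
rescale_isotropic <- function(volume, target_mm = 1) {
  volume <- as_volume_image(volume)
  if (!is.numeric(target_mm) || target_mm <= 0) abort("`target_mm` must be > 0.")
  sp <- volume$spacing
  if (all(abs(sp - target_mm) < 1e-12)) {
    volume$spacing <- rep(target_mm, 3)
    return(volume)
  }
  d_in <- dim(volume$data)
  d_out <- pmax(1L, as.integer(round(d_in * sp / target_mm)))
  # voxel-centre coordinates of the output grid expressed on the input grid
  coords <- lapply(1:3, function(a) {
    x <- ((seq_len(d_out[a]) - 0.5) * target_mm) / sp[a] + 0.5
    pmin(pmax(x, 1), d_in[a])
  })
  out <- trilinear_sample(volume$data, coords[[1]], coords[[2]], coords[[3]])
  volume_image(out, rep(target_mm, 3), volume$orientation)
}

# separable trilinear interpolation at a tensor-product grid of coordinates
trilinear_sample <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  interp_axis <- function(coord, axis_len) {
    i0 <- pmin(floor(coord), axis_len - 1L); i0 <- pmax(i0, 1L)
    w <- coord - i0
    list(i0 = as.integer(i0), w = w)
  }
  ix <- interp_axis(cx, d[1]); iy <- interp_axis(cy, d[2])
  iz <- interp_axis(cz, d[3])
  # interpolate one axis at a time (axis 1, then 2, then 3)
  a1 <- arr[ix$i0, , , drop = FALSE] * (1 - ix$w) +
    arr[pmin(ix$i0 + 1L, d[1]), , , drop = FALSE] * ix$w
  a2 <- a1[, iy$i0, , drop = FALSE] * rep(1 - iy$w, each = length(ix$i0)) +
    a1[, pmin(iy$i0 + 1L, d[2]), , drop = FALSE] * rep(iy$w, each = length(ix$i0))
  n12 <- length(ix$i0) * length(iy$i0)
  a3 <- a2[, , iz$i0, drop = FALSE] * rep(1 - iz$w, each = n12) +
    a2[, , pmin(iz$i0 + 1L, d[3]), drop = FALSE] * rep(iz$w, each = n12)
  a3
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximisation of the between-class variance on an `n_bins`-bin
#' histogram; returns the threshold on the intensity scale (upper edge of the
#' background class).
#'
#' @param x numeric vector (or array) of intensities.
#' @param n_bins histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  edges[k + 1L]
}

#' Median-filter a 3D volume (3x3x3 neighbourhood)
#'
#' Borders are handled by clamping (replication). Implemented in C++ for
#' throughput; used inside [normalize_intensities()].
#'
#' @param arr 3D numeric array.
#' @return filtered array of the same shape.
#' @export
median_filter3 <- function(arr) {
  d <- dim(arr)
  if (length(d) != 3L) abort("`arr` must be a 3D array.")
  .median_filter3_cpp(as.numeric(arr), as.integer(d))
}

#' Normalise volume intensities
#'
#' The standard intensity pipeline applied after registration and skull
#' stripping: background voxels (below an Otsu threshold of the volume
#' histogram) are set to zero, the volume is median-filtered (3x3x3), and
#' foreground intensities are mapped to a fixed `[0, 1]` scale. The scale is
#' anchored at the zero background and divided by the foreground maximum, so
#' re-normalising an already normalised volume leaves the intensity scale
#' unchanged; z-scoring is available as an alternative.
#'
#' @param volume `volume_image` or 3D array.
#' @param scale `"minmax"` (default) or `"zscore"`.
#' @param n_bins histogram bins for the Otsu threshold.
#' @return `volume_image` with normalised intensities; attribute
#'   `"otsu_threshold"` records the threshold used. An all-zero volume is
#'   returned unchanged with a warning.
#' @export
normalize_intensities <- function(volume, scale = c("minmax", "zscore"),
                                  n_bins = 256L) {
  scale <- match.arg(scale)
  volume <- as_volume_image(volume)
  x <- volume$data
  if (all(x == 0)) {
    warn("all-zero volume: returned unchanged.")
    return(volume)
  }
  if (diff(range(x)) == 0) {
    # constant positive volume: all foreground, maps to the top of the scale
    out <- array(1, dim = dim(x))
    volume$data <- out
    attr(volume$data, "otsu_threshold") <- 0
    return(volume)
  }
  thr <- otsu_threshold(x, n_bins)
  x[x <= thr] <- 0
  x <- median_filter3(x)
  fg <- x > 0
  if (!any(fg)) {
    warn("Otsu threshold removed every voxel; returning zeroed volume.")
    volume$data <- x
    return(volume)
  }
  if (scale == "minmax") {
    x[fg] <- x[fg] / max(x[fg])
  } else {
    mu <- mean(x[fg]); s <- sd(x[fg])
    x[fg] <- if (s > 0) (x[fg] - mu) / s else 0
  }
  volume$data <- x
  attr(volume$data, "otsu_threshold") <- thr
  volume
}

#' Find axial slices with enough non-zero voxels
#'
#' A slice is valid when its fraction of non-zero voxels is at least
#' `min_nonzero_fraction` (inclusive); applied after background removal.
#'
#' @param volume `volume_image` or 3D array.
#' @param min_nonzero_fraction minimum non-zero fraction (default 0.01).
#' @return sorted integer vector of valid axial slice indices (possibly empty).
#' @export
find_valid_slices <- function(volume, min_nonzero_fraction = 0.01) {
  volume <- as_volume_image(volume)
  ax <- axial_axis(volume)
  frac <- apply(volume$data != 0, ax, mean)
  which(frac >= min_nonzero_fraction)
}

round_half_up <- function(x) floor(x + 0.5)

#' Select percentile slices from the valid range
#'
#' Nearest-rank selection on list positions: for percentile `p` the chosen
#' index is `valid_indices[round(p/100 * (n - 1)) + 1]` with round-half-up.
#'
#' @param valid_indices sorted valid slice indices (non-empty).
#' @param percentiles percentile values in `[0, 100]`; default
#'   `c(25, 37.5, 50, 62.5, 75)`.
#' @return A `slice_plan`: list with `valid_indices`, `percentiles`,
#'   `selected_indices` (one per percentile, non-decreasing in p).
#' @export
select_percentile_slices <- function(valid_indices,
                                     percentiles = c(25, 37.5, 50, 62.5, 75)) {
  if (length(valid_indices) == 0) abort("`valid_indices` is empty.")
  if (any(percentiles < 0 | percentiles > 100)) {
    abort("`percentiles` must lie in [0, 100].")
  }
  valid_indices <- sort(as.integer(valid_indices))
  n <- length(valid_indices)
  pos <- round_half_up(percentiles / 100 * (n - 1)) + 1L
  structure(list(valid_indices = valid_indices,
                 percentiles = percentiles,
                 selected_indices = valid_indices[pos]),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat("<slice_plan>", length(x$valid_indices), "valid slices; selected",
      paste(sprintf("p%g=%d", x$percentiles, x$selected_indices),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract one axial slice, optionally padded/cropped to a model resolution
#'
#' @param volume `volume_image` or 3D array.
#' @param index axial slice index (within bounds).
#' @param out_size optional integer(1 or 2): output height/width; the slice is
#'   centre-padded with zeros or centre-cropped to this size.
#' @return 2D numeric matrix.
#' @export
extract_slice <- function(volume, index, out_size = NULL) {
  volume <- as_volume_image(volume)
  ax <- axial_axis(volume)
  n_ax <- dim(volume$data)[ax]
  if (index < 1 || index > n_ax) {
    abort(sprintf("slice index %d out of bounds [1, %d]", index, n_ax))
  }
  sl <- switch(ax,
               volume$data[index, , ],
               volume$data[, index, ],
               volume$data[, , index])
  sl <- as.matrix(sl)
  if (!is.null(out_size)) {
    out_size <- as.integer(rep(out_size, length.out = 2L))
    sl <- pad_crop_center(sl, out_size)
  }
  sl
}

pad_crop_center <- function(m, out_size) {
  d <- dim(m)
  out <- matrix(0, out_size[1], out_size[2])
  src_h <- min(d[1], out_size[1]); src_w <- min(d[2], out_size[2])
  so_h <- (d[1] - src_h) %/% 2L; so_w <- (d[2] - src_w) %/% 2L
  do_h <- (out_size[1] - src_h) %/% 2L; do_w <- (out_size[2] - src_w) %/% 2L
  out[do_h + seq_len(src_h), do_w + seq_len(src_w)] <-
    m[so_h + seq_len(src_h), so_w + seq_len(src_w)]
  out
}

#' Pass-through hook for external preprocessing tools
#'
#' Rigid registration to an age-appropriate atlas, skull stripping, and N4
#' bias-field correction are external tools in this pipeline; the hook either
#' applies a user-supplied function or passes the volume through unchanged,
#' recording in the provenance whether the step ran.
#'
#' @param volume `volume_image`.
#' @param tool one of `"register"`, `"skull_strip"`, `"n4"`.
#' @param fn optional function `volume -> volume` implementing the tool.
#' @return the (possibly transformed) volume, with a `"provenance"` attribute
#'   accumulating `tool = ran?` flags.
#' @export
external_tool_hook <- function(volume, tool = c("register", "skull_strip", "n4"),
                               fn = NULL) {
  tool <- match.arg(tool)
  volume <- as_volume_image(volume)
  prov <- attr(volume, "provenance") %||% list()
  if (is.null(fn)) {
    prov[[tool]] <- FALSE
  } else {
    volume <- as_volume_image(fn(volume))
    prov[[tool]] <- TRUE
  }
  attr(volume, "provenance") <- prov
  volume
}

#' Preprocess one volume into model-ready axial slices
#'
#' Composes the intensity pipeline: optional external hooks, isotropic
#' rescale, intensity normalisation, valid-slice detection (>= 1% non-zero
#' voxels by default), percentile slice selection, and slice extraction.
#'
#' @param volume `volume_image` or 3D array.
#' @param percentiles percentile slice positions.
#' @param min_nonzero_fraction valid-slice threshold.
#' @param out_size model input resolution (default: native slice size).
#' @param target_mm isotropic spacing (default 1 mm).
#' @param hooks optional named list of functions for `register`,
#'   `skull_strip`, `n4`.
#' @return list with `slices` (named list of 2D matrices, one per percentile),
#'   `plan` (the `slice_plan`), `volume` (the normalised volume), and
#'   `provenance`.
#' @export
preprocess_volume <- function(volume,
                              percentiles = c(25, 37.5, 50, 62.5, 75),
                              min_nonzero_fraction = 0.01,
                              out_size = NULL, target_mm = 1,
                              hooks = list()) {
  volume <- as_volume_image(volume)
  for (tool in c("register", "skull_strip", "n4")) {
    volume <- external_tool_hook(volume, tool, hooks[[tool]])
  }
  prov <- attr(volume, "provenance")
  volume <- rescale_isotropic(volume, target_mm)
  volume <- normalize_intensities(volume)
  valid <- find_valid_slices(volume, min_nonzero_fraction)
  if (length(valid) == 0) abort("no valid axial slices after preprocessing.")
  plan <- select_percentile_slices(valid, percentiles)
  slices <- lapply(plan$selected_indices, function(i) {
    extract_slice(volume, i, out_size)
  })
  names(slices) <- sprintf("p%g", percentiles)
  list(slices = slices, plan = plan, volume = volume,
       provenance = c(prov, list(min_nonzero_fraction = min_nonzero_fraction,
                                 target_mm = target_mm)))
}
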