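test_that("isotropic rescaling preserves extent and constants", {
  v <- volume_image(array(runif(32^3), rep(32, 3)), c(1, 1, 1))
  expect_identical(dim(rescale_isotropic(v)$data), dim(v$data))
  v2 <- volume_image(array(runif(32^3), rep(32, 3)), c(2, 2, 2))
  out <- rescale_isotropic(v2, 1)
  expect_identical(dim(out$data), rep(64L, 3))
  expect_equal(out$spacing, c(1, 1, 1))
  vc <- volume_image(array(3.5, rep(20, 3)), c(1.7, 0.9, 2.3))
  outc <- rescale_isotropic(vc, 1)
  expect_true(all(abs(outc$data - 3.5) < 1e-12))
  # physical extent preserved within one voxel per axis
  expect_true(all(abs(dim(outc$data) * 1 - dim(vc$data) * vc$spacing) <= 1))
  expect_error(volume_image(array(0, rep(16, 3)), c(0, 1, 1)), "positive")
})

# independent exhaustive Otsu: scan every candidate split of the sorted data
oracle_otsu <- function(x, n_bins = 256L) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  best <- -Inf; thr <- edges[2]
  for (k in seq_len(n_bins - 1L)) {
    t_cand <- edges[k + 1L]
    w0 <- mean(x <= t_cand)
    if (w0 == 0 || w0 == 1) next
    sb <- w0 * (1 - w0) * (mean(x[x <= t_cand]) - mean(x[x > t_cand]))^2
    if (sb > best) { best <- sb; thr <- t_cand }
  }
  thr
}

test_that("Otsu threshold separates a bimodal volume at the analytic midpoint", {
  set.seed(7)
  x <- array(abs(rnorm(24^3, sd = 0.5)), rep(24, 3))
  x[5:20, 5:20, 5:20] <- 100 + rnorm(16^3, sd = 0.5)
  thr <- otsu_threshold(x)
  # mask at the Otsu threshold vs mask at the analytic midpoint (50)
  expect_lt(mean((x <= thr) != (x <= 50)), 0.01)
  # agreement with an independent exhaustive scan
  set.seed(8)
  y <- c(rnorm(3000, 10, 2), rnorm(2000, 60, 5))
  expect_lt(abs(otsu_threshold(y) - oracle_otsu(y)),
            diff(range(y)) / 256 + 1e-9)
  # background of the normalised volume is zero, foreground scaled to [0, 1]
  out <- normalize_intensities(volume_image(x))$data
  expect_equal(max(out), 1)
  expect_true(all(out >= 0))
  expect_true(all(out[x <= thr] == 0))
})

test_that("normalisation contracts: constants, all-zero, idempotence", {
  const <- volume_image(array(7, rep(16, 3)))
  out <- normalize_intensities(const)$data
  expect_true(all(out == 1))
  zero <- volume_image(array(0, rep(16, 3)))
  expect_warning(z <- normalize_intensities(zero), "all-zero")
  expect_identical(z$data, zero$data)
  # idempotent on filter-stable (flat-interface) input: a layered slab volume
  slab <- array(0, rep(16, 3))
  slab[, , 6:10] <- 0.5
  slab[, , 11:14] <- 1
  v1 <- normalize_intensities(volume_image(slab))
  v2 <- normalize_intensities(v1)
  expect_lt(max(abs(v1$data - v2$data)), 1e-6)
  # random input still respects the output contract
  r <- normalize_intensities(volume_image(array(runif(16^3, 1, 9), rep(16, 3))))
  expect_equal(max(r$data), 1)
})

test_that("valid-slice detection uses an inclusive threshold and honours geometry", {
  z <- array(0, c(20, 20, 5))
  expect_length(find_valid_slices(volume_image(z)), 0)
  z[1:4, 1, 2] <- 1  # exactly 1% of 400 voxels
  z[1:3, 1, 3] <- 1  # just below 1%
  got <- find_valid_slices(volume_image(z), 0.01)
  expect_identical(got, 2L)
  # monotone in the threshold: raising it never adds indices
  v <- volume_image(generate_phantom(10, tiny_spec(noise_sd = 0)))
  lo <- find_valid_slices(v, 0.01)
  hi <- find_valid_slices(v, 0.10)
  expect_true(all(hi %in% lo))
  # noise-free phantom: valid range equals the analytic axial extent
  spec <- tiny_spec(noise_sd = 0)
  vol <- generate_phantom(10, spec)
  d <- spec$grid_shape; ctr <- (d + 1) / 2; rt <- spec$ellipsoid_ratios
  frac <- vapply(seq_len(d[3]), function(k) {
    inside <- outer(seq_len(d[1]), seq_len(d[2]), function(i, j) {
      sqrt(((i - ctr[1]) / rt[1])^2 + ((j - ctr[2]) / rt[2])^2 +
             ((k - ctr[3]) / rt[3])^2) <= spec$brain_radius
    })
    mean(inside)
  }, numeric(1))
  expect_identical(find_valid_slices(volume_image(vol), 0.01),
                   which(frac >= 0.01))
})

test_that("percentile slice selection follows the nearest-rank convention", {
  plan <- select_percentile_slices(c(10, 20, 30, 40, 50), 50)
  expect_identical(plan$selected_indices, 30L)
  plan2 <- select_percentile_slices(0:99, c(25, 37.5, 50, 62.5, 75))
  expect_identical(plan2$selected_indices, c(25L, 37L, 50L, 62L, 74L))
  one <- select_percentile_slices(17, c(25, 50, 75))
  expect_identical(one$selected_indices, rep(17L, 3))
  # non-decreasing in p
  set.seed(1)
  for (i in 1:20) {
    valid <- sort(sample(100, sample(2:40, 1)))
    p <- sort(runif(5, 0, 100))
    expect_true(!is.unsorted(select_percentile_slices(valid, p)$selected_indices))
  }
  expect_error(select_percentile_slices(integer(0)), "empty")
})

test_that("slice extraction pads, crops, and respects bounds", {
  v <- volume_image(array(as.numeric(seq_len(16^3)), rep(16, 3)))
  sl <- extract_slice(v, 5)
  expect_identical(sl, as.matrix(v$data[, , 5]))
  expect_error(extract_slice(v, 17), "out of bounds")
  padded <- extract_slice(v, 5, out_size = 24)
  expect_identical(dim(padded), c(24L, 24L))
  expect_identical(padded[5:20, 5:20], as.matrix(v$data[, , 5]))
  expect_true(all(padded[1:4, ] == 0))
  cropped <- extract_slice(v, 5, out_size = 8)
  expect_identical(dim(cropped), c(8L, 8L))
  # round-trip over all valid indices
  vv <- volume_image(generate_phantom(10, tiny_spec()))
  valid <- find_valid_slices(vv)
  slices <- lapply(valid, extract_slice, volume = vv)
  expect_length(slices, length(valid))
})

test_that("external tool hooks pass through and record provenance", {
  v <- volume_image(array(runif(16^3), rep(16, 3)))
  out <- external_tool_hook(v, "register")
  expect_false(attr(out, "provenance")$register)
  out2 <- external_tool_hook(out, "n4", fn = function(x) {
    x$data <- x$data * 2; x
  })
  expect_true(attr(out2, "provenance")$n4)
  expect_equal(out2$data, v$data * 2)
})

test_that("preprocess_volume composes the pipeline end to end", {
  pp <- preprocess_volume(generate_phantom(20, tiny_spec()))
  expect_named(pp$slices, c("p25", "p37.5", "p50", "p62.5", "p75"))
  expect_true(all(pp$plan$selected_indices %in% pp$plan$valid_indices))
  expect_equal(max(pp$volume$data), 1)
  expect_error(suppressWarnings(preprocess_volume(array(0, rep(16, 3)))),
               "no valid")
})
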