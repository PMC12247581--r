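# analytic voxel-count oracle: count voxels by the nested radius inequalities
oracle_compartment_counts <- function(spec, age) {
  d <- spec$grid_shape; ctr <- (d + 1) / 2; rt <- spec$ellipsoid_ratios
  counts <- c(csf = 0, wm = 0, gm = 0, background = 0)
  rv <- spec$ventricle_radius_fn(age)
  th <- spec$cortical_thickness_fn(age)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    r <- sqrt(((i - ctr[1]) / rt[1])^2 + ((j - ctr[2]) / rt[2])^2 +
                ((k - ctr[3]) / rt[3])^2)
    lab <- if (r <= rv) "csf" else if (r <= spec$brain_radius - th) "wm"
      else if (r <= spec$brain_radius) "gm" else "background"
    counts[lab] <- counts[lab] + 1
  }
  counts
}

test_that("phantom generation is bit-reproducible and rejects out-of-range ages", {
  spec <- tiny_spec()
  expect_identical(generate_phantom(10, spec, 42), generate_phantom(10, spec, 42))
  expect_false(identical(generate_phantom(10, spec, 42),
                         generate_phantom(10, spec, 43)))
  expect_error(generate_phantom(40, spec), "outside")
  expect_true(all(generate_phantom(5, spec, 1) >= 0))
})

test_that("noise-free compartment counts match the analytic oracle and grow monotonely", {
  spec <- tiny_spec(noise_sd = 0)
  ti <- spec$tissue_intensities
  for (age in c(4, 15, 28)) {
    vol <- generate_phantom(age, spec)
    got <- c(csf = sum(vol == ti[["csf"]]), wm = sum(vol == ti[["wm"]]),
             gm = sum(vol == ti[["gm"]]),
             background = sum(vol == ti[["background"]]))
    expect_equal(got, oracle_compartment_counts(spec, age))
  }
  v_young <- sum(generate_phantom(5, spec) == ti[["csf"]])
  v_old <- sum(generate_phantom(25, spec) == ti[["csf"]])
  expect_lt(v_young, v_old)
})

test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(grid_shape = c(8, 32, 32)), ">= 16")
  expect_error(phantom_spec(age_range = c(30, 3)), "increasing")
  expect_error(phantom_spec(ventricle_radius_fn = function(a) 5 - a / 100,
                            age_range = c(3, 30)), "increasing")
  expect_error(phantom_spec(cortical_thickness_fn = function(a) 1 + a / 100),
               "decreasing")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
})

test_that("cohorts are reproducible, seed-sensitive, and uniformly aged", {
  spec <- tiny_spec()
  c1 <- generate_cohort(1, spec, seed = 5)
  expect_equal(nrow(c1$subjects), 1)
  expect_length(c1$volumes, 1)
  expect_identical(attr(c1$volumes[[1]], "age"), c1$subjects$age[1])
  c2 <- generate_cohort(4, spec, seed = 5)
  c3 <- generate_cohort(4, spec, seed = 6)
  expect_identical(c2$subjects, generate_cohort(4, spec, seed = 5)$subjects)
  expect_false(identical(c2$subjects$age, c3$subjects$age))
  expect_error(generate_cohort(0, spec), ">= 1")
  # uniformity of the age distribution (KS against Uniform(age_range))
  ages <- withr::with_seed(1, {
    generate_cohort(1000, phantom_spec(grid_shape = rep(16, 3)), seed = 99)
  })$subjects$age
  ks <- suppressWarnings(
    stats::ks.test(ages, "punif", spec$age_range[1], spec$age_range[2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("volumetric tables plant recoverable effect sizes", {
  null_tab <- generate_volumetric_table(500, effect = list(), seed = 2)
  expect_identical(null_tab, generate_volumetric_table(500, effect = list(), seed = 2))
  expect_equal(nrow(null_tab), 1500)
  expect_false(any(is.na(null_tab)))
  d_hat <- function(tab, measure, grp) {
    x <- tab[tab$planted_group == grp, ][[measure]]
    y <- tab[tab$planted_group == "Average", ][[measure]]
    (mean(x) - mean(y)) / sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                                 (length(x) + length(y) - 2))
  }
  for (m in c("WMV", "GMV", "sGMV", "VV")) {
    expect_lt(abs(d_hat(null_tab, m, "Older")), 0.15)
  }
  planted <- generate_volumetric_table(500, effect = list(Older = c(VV = 0.5)),
                                       seed = 3)
  d_vv <- d_hat(planted, "VV", "Older")
  expect_gt(d_vv, 0.35); expect_lt(d_vv, 0.65)
  expect_error(generate_volumetric_table(5), ">= 10")
  # age trends follow development in the simulated range
  fit <- lm(GMV ~ age, data = null_tab)
  expect_lt(coef(fit)[2], 0)
  expect_gt(coef(lm(VV ~ age, data = null_tab))[2], 0)
})

test_that("longitudinal cohorts have increasing visit ages and controllable slopes", {
  lc <- generate_longitudinal_cohort(50, n_visits = 3, interval = 2, seed = 4)
  expect_equal(nrow(lc), 150)
  diffs <- lc |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(d = list(diff(age)), .groups = "drop")
  dd <- unlist(diffs$d)
  expect_true(all(dd > 0))
  expect_true(all(abs(dd - 2) < 0.6))  # interval 2 +/- jitter
  # zero slope variance and zero noise: identical volumetric rates everywhere
  flat <- generate_longitudinal_cohort(20, seed = 5, rate_sd = 0,
                                       accelerated_fraction = 0,
                                       decelerated_fraction = 0,
                                       vol_slope_sd = 0, vol_noise_sd = 0,
                                       jitter_sd = 0)
  rates <- flat |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(r = mean(diff(WMV) / diff(age)), .groups = "drop")
  expect_lt(diff(range(rates$r)), 1e-8)
  expect_error(generate_longitudinal_cohort(10, n_visits = 1), ">= 2")
  expect_error(generate_longitudinal_cohort(10, interval = 0), "> 0")
})
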