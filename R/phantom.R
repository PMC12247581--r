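#' Specification of a synthetic brain phantom
#'
#' A phantom encodes a scalar age geometrically in a 3D volume: a central
#' CSF-filled "ventricle" sphere whose radius grows with age, a cortical
#' "grey-matter" band that thins with age, and a "white-matter" compartment in
#' between, all nested inside an ellipsoidal brain. The mapping age -> geometry
#' is strictly monotone, so the image -> age regression problem has a known
#' ground truth and the compartment voxel counts have a closed analytic form.
#'
#' @param grid_shape integer(3), voxels per axis (each >= 16).
#' @param age_range numeric(2), years; ages outside are rejected.
#' @param ventricle_radius_fn monotone increasing function age -> radius (voxels).
#' @param cortical_thickness_fn monotone decreasing function age -> band
#'   thickness (voxels).
#' @param brain_radius outer brain radius in voxels (first-axis radius).
#' @param ellipsoid_ratios numeric(3), per-axis semi-axis ratios of the brain
#'   and its nested compartments (1 = spherical on that axis).
#' @param tissue_intensities named numeric: `background`, `csf`, `gm`, `wm`,
#'   all >= 0.
#' @param noise_sd additive Gaussian intensity noise (standard deviation).
#' @param seed integer seed stored with the spec (generators take their own).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         age_range = c(3, 30),
                         ventricle_radius_fn = NULL,
                         cortical_thickness_fn = NULL,
                         brain_radius = 0.82 * min(grid_shape) / 2,
                         ellipsoid_ratios = c(1, 0.95, 0.88),
                         tissue_intensities = c(background = 0, csf = 0.25,
                                                gm = 0.55, wm = 0.9),
                         noise_sd = 0.02,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    abort("`grid_shape` must be 3 integers, each >= 16.")
  }
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    abort("`age_range` must be increasing numeric(2).")
  }
  if (is.null(ventricle_radius_fn)) {
    # linear increasing map; kept linear so the analytic oracle stays trivial
    lo <- age_range[1]; span <- diff(age_range)
    r_min <- 0.08 * min(grid_shape); r_max <- 0.20 * min(grid_shape)
    ventricle_radius_fn <- function(age) r_min + (r_max - r_min) * (age - lo) / span
  }
  if (is.null(cortical_thickness_fn)) {
    lo <- age_range[1]; span <- diff(age_range)
    th_max <- 0.14 * min(grid_shape); th_min <- 0.05 * min(grid_shape)
    cortical_thickness_fn <- function(age) th_max - (th_max - th_min) * (age - lo) / span
  }
  need <- c("background", "csf", "gm", "wm")
  if (!all(need %in% names(tissue_intensities)) || any(tissue_intensities < 0)) {
    abort("`tissue_intensities` needs non-negative background/csf/gm/wm.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  spec <- structure(
    list(grid_shape = grid_shape, age_range = as.numeric(age_range),
         ventricle_radius_fn = ventricle_radius_fn,
         cortical_thickness_fn = cortical_thickness_fn,
         brain_radius = brain_radius,
         ellipsoid_ratios = as.numeric(ellipsoid_ratios),
         tissue_intensities = tissue_intensities[need],
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  ages <- seq(age_range[1], age_range[2], length.out = 25)
  rv <- vapply(ages, spec$ventricle_radius_fn, numeric(1))
  th <- vapply(ages, spec$cortical_thickness_fn, numeric(1))
  if (any(diff(rv) <= 0)) abort("`ventricle_radius_fn` must be strictly increasing on age_range.")
  if (any(diff(th) >= 0)) abort("`cortical_thickness_fn` must be strictly decreasing on age_range.")
  if (max(rv) >= brain_radius - max(th)) {
    abort("ventricle radius must stay inside the white-matter compartment.")
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid", paste(x$grid_shape, collapse = "x"),
      "| ages", paste(x$age_range, collapse = "-"),
      "| noise_sd", x$noise_sd, "\n")
  invisible(x)
}

# normalised ellipsoidal radius field (voxels, first-axis scale)
phantom_radius_field <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  r <- spec$ellipsoid_ratios
  gx <- (seq_len(d[1]) - ctr[1]) / r[1]
  gy <- (seq_len(d[2]) - ctr[2]) / r[2]
  gz <- (seq_len(d[3]) - ctr[3]) / r[3]
  sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+"))
}

#' Generate one synthetic brain phantom
#'
#' @param age age in years, inside `spec$age_range`.
#' @param spec a [phantom_spec()].
#' @param rng_seed integer seed for the additive noise; the output is
#'   bit-reproducible for fixed `(age, spec, rng_seed)`.
#' @return 3D numeric array of intensities (all >= 0) with attribute
#'   `"age"`.
#' @export
generate_phantom <- function(age, spec, rng_seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (age < spec$age_range[1] || age > spec$age_range[2]) {
    abort(sprintf("age %.2f outside spec age_range [%g, %g]",
                  age, spec$age_range[1], spec$age_range[2]))
  }
  rad <- phantom_radius_field(spec)
  rv <- spec$ventricle_radius_fn(age)
  th <- spec$cortical_thickness_fn(age)
  rb <- spec$brain_radius
  ti <- spec$tissue_intensities
  vol <- array(ti[["background"]], dim = spec$grid_shape)
  vol[rad <= rb] <- ti[["gm"]]
  vol[rad <= rb - th] <- ti[["wm"]]
  vol[rad <= rv] <- ti[["csf"]]
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(as.integer(rng_seed))
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim = dim(vol))
    .Random.seed_restore(old)
    vol[vol < 0] <- 0
  }
  attr(vol, "age") <- age
  vol
}

# save/restore the global RNG so generators are self-seeding without
# disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed_diffage <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a cohort of phantoms with uniformly sampled ages
#'
#' Ages are drawn uniformly over `spec$age_range` (mirroring age-flattened
#' training stratification), sex labels are balanced Bernoulli draws.
#'
#' @param n number of subjects (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the cohort is reproducible given `(n, spec, seed)`.
#' @return A `phantom_cohort`: list with `volumes` (list of 3D arrays) and
#'   `subjects` (tibble: subject_id, age, sex).
#' @export
generate_cohort <- function(n, spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  dat <- with_seed_diffage(seed, {
    list(ages = runif(n, spec$age_range[1], spec$age_range[2]),
         sex = sample(c("F", "M"), n, replace = TRUE),
         vol_seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  volumes <- lapply(seq_len(n), function(i) {
    generate_phantom(dat$ages[i], spec, rng_seed = dat$vol_seeds[i])
  })
  structure(
    list(volumes = volumes,
         subjects = tibble::tibble(
           subject_id = sprintf("S%04d", seq_len(n)),
           age = dat$ages, sex = dat$sex),
         spec = spec, seed = as.integer(seed)),
    class = "phantom_cohort"
  )
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort>", nrow(x$subjects), "subjects, grid",
      paste(x$spec$grid_shape, collapse = "x"), "\n")
  invisible(x)
}

# baseline age trends for the four volumetric measures; linear so the
# marginal SD (noise + age trend) has a closed form
.vol_measures <- function() {
  tibble::tribble(
    ~measure, ~intercept, ~slope, ~noise_sd,
    "WMV",  430,  6.0, 40,
    "GMV",  780, -5.0, 50,
    "sGMV",  62, -0.3,  5,
    "VV",    14,  0.6,  4
  )
}

#' Generate a synthetic volumetric table with planted group effects
#'
#' Emulates per-subject records of the four key volumetric measures (WMV,
#' GMV, sGMV, VV) for three brain-age-gap groups (Younger / Average / Older).
#' Effects are planted as standardized mean differences (Cohen's d) against
#' the Average group: the shift applied is `d * SD_total` where `SD_total`
#' includes both measurement noise and the age-trend variance, so the planted
#' d is recovered (up to sampling error) by a pooled-SD Cohen's d.
#'
#' @param n subjects per group (>= 10).
#' @param effect named list of named numeric vectors: planted d per measure for
#'   groups `"Older"` and/or `"Younger"`, e.g.
#'   `list(Older = c(VV = 0.5, GMV = -0.3))`. Empty means no planted effect.
#' @param seed integer seed.
#' @param age_range age sampling range (uniform, identical across groups).
#' @return tibble: subject_id, age, sex, WMV, GMV, sGMV, VV, planted_group.
#' @export
generate_volumetric_table <- function(n, effect = list(), seed = 1L,
                                      age_range = c(5, 25)) {
  if (!is.numeric(n) || n < 10) abort("`n` (per group) must be >= 10.")
  n <- as.integer(n)
  meas <- .vol_measures()
  groups <- c("Younger", "Average", "Older")
  with_seed_diffage(seed, {
    rows <- lapply(groups, function(g) {
      age <- runif(n, age_range[1], age_range[2])
      sex <- sample(c("F", "M"), n, replace = TRUE)
      out <- tibble::tibble(
        subject_id = sprintf("%s%04d", substr(g, 1, 1), seq_len(n)),
        age = age, sex = sex)
      for (i in seq_len(nrow(meas))) {
        m <- meas$measure[i]
        sd_total <- sqrt(meas$noise_sd[i]^2 +
                           meas$slope[i]^2 * diff(age_range)^2 / 12)
        shift <- 0
        if (!is.null(effect[[g]]) && !is.na(effect[[g]][m]) &&
            m %in% names(effect[[g]])) {
          shift <- effect[[g]][[m]] * sd_total
        }
        out[[m]] <- meas$intercept[i] + meas$slope[i] * age +
          rnorm(n, sd = meas$noise_sd[i]) + shift
      }
      out$planted_group <- g
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic longitudinal cohort with planted rate subgroups
#'
#' Each subject has `n_visits` visits at (jittered) fixed intervals. The
#' predicted brain age follows a per-subject linear trajectory whose rate is
#' `1 + N(0, rate_sd)` years/year for unplanted subjects. Planted
#' "Accelerated" ("Decelerated") subjects have their rate pinned to
#' `1 + shift_sd_mult * rate_sd` (`1 - shift_sd_mult * rate_sd`) exactly: the
#' plant replaces the subject-level rate deviation rather than adding to it,
#' so a mean + 1 SD cohort threshold can recover the planted label with high
#' sensitivity. Volumetric trajectories follow developmental trends (VV growth
#' up, GMV/WMV/sGMV growth down for Accelerated; opposite sign for
#' Decelerated) with per-subject random slopes.
#'
#' @param n_subjects number of subjects.
#' @param n_visits visits per subject (>= 2).
#' @param interval nominal years between visits (> 0).
#' @param seed integer seed.
#' @param accelerated_fraction,decelerated_fraction planted fractions.
#' @param shift_sd_mult planted rate shift in units of `rate_sd`.
#' @param rate_sd SD of the brain-age rate across unplanted subjects (yr/yr).
#' @param pred_noise_sd per-visit measurement noise on predicted age (years).
#' @param vol_slope_sd per-subject random-slope SD, as a fraction of each
#'   measure's mean annual change.
#' @param vol_noise_sd per-visit volumetric measurement noise, as a fraction
#'   of each measure's annual change.
#' @param jitter_sd SD of visit-interval jitter (years).
#' @param baseline_age_range uniform range of first-visit ages.
#' @return tibble: subject_id, visit, age, predicted_age, WMV, GMV, sGMV, VV,
#'   planted_group ("Accelerated" / "Decelerated" / "Stable").
#' @export
generate_longitudinal_cohort <- function(n_subjects, n_visits = 3, interval = 2,
                                         seed = 1L,
                                         accelerated_fraction = 0.1,
                                         decelerated_fraction = 0.1,
                                         shift_sd_mult = 2,
                                         rate_sd = 0.15,
                                         pred_noise_sd = 0.1,
                                         vol_slope_sd = 0.15,
                                         vol_noise_sd = 0.25,
                                         jitter_sd = 0.1,
                                         baseline_age_range = c(8, 12)) {
  if (n_visits < 2) abort("`n_visits` must be >= 2.")
  if (interval <= 0) abort("`interval` must be > 0.")
  n_subjects <- as.integer(n_subjects)
  meas <- .vol_measures()
  n_acc <- round(accelerated_fraction * n_subjects)
  n_dec <- round(decelerated_fraction * n_subjects)
  with_seed_diffage(seed, {
    grp <- rep("Stable", n_subjects)
    planted <- sample.int(n_subjects, n_acc + n_dec)
    grp[planted[seq_len(n_acc)]] <- "Accelerated"
    if (n_dec > 0) grp[planted[n_acc + seq_len(n_dec)]] <- "Decelerated"
    rate <- 1 + rnorm(n_subjects, sd = rate_sd)
    rate[grp == "Accelerated"] <- 1 + shift_sd_mult * rate_sd
    rate[grp == "Decelerated"] <- 1 - shift_sd_mult * rate_sd
    age0 <- runif(n_subjects, baseline_age_range[1], baseline_age_range[2])
    gap0 <- rnorm(n_subjects, sd = 1)
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      dt <- c(0, cumsum(pmax(interval + rnorm(n_visits - 1, sd = jitter_sd),
                             interval / 4)))
      ages <- age0[i] + dt
      pred <- age0[i] + gap0[i] + rate[i] * dt +
        rnorm(n_visits, sd = pred_noise_sd)
      out <- tibble::tibble(
        subject_id = sprintf("L%04d", i),
        visit = seq_len(n_visits), age = ages, predicted_age = pred,
        planted_group = grp[i])
      # volumetric growth rates coupled to the brain-age rate deviation:
      # VV grows faster, the rest slower, when aging is accelerated
      rate_dev <- rate[i] - 1
      for (j in seq_len(nrow(meas))) {
        m <- meas$measure[j]
        annual <- abs(meas$slope[j])
        coupling <- if (m == "VV") 1 else -1
        slope_i <- meas$slope[j] + coupling * rate_dev * annual * 2 +
          rnorm(1, sd = vol_slope_sd * annual)
        out[[m]] <- meas$intercept[j] + meas$slope[j] * age0[i] +
          slope_i * dt + rnorm(n_visits, sd = vol_noise_sd * annual)
      }
      rows[[i]] <- out
    }
    dplyr::bind_rows(rows)[, c("subject_id", "visit", "age", "predicted_age",
                               "WMV", "GMV", "sGMV", "VV", "planted_group")]
  })
}
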