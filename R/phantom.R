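#' Lesion, phantom and noise specifications
#'
#' `lesion_spec()` describes one lesion: an ellipsoid (a sphere is the
#' equal-axes case) with a target volume, a tumor-to-background
#' activity-concentration ratio (TBR), and optional incomplete uptake —
#' either a perfused fraction below one (a planar cut leaves part of the
#' lesion without activity) or a necrotic core (a central scaled copy of
#' the ellipsoid with zero uptake, giving a rim lesion).  The
#' *morphologic* truth mask is always the full ellipsoid; activity is
#' restricted to the perfused region.
#'
#' @param target_volume_cm3 Lesion volume in cm^3.
#' @param center Center in mm (grid coordinates).
#' @param tbr Lesion-to-background activity-concentration ratio (>= 0).
#'   In a cold-background phantom the background concentration is zero
#'   and `tbr` only sets the relative weight between lesions.
#' @param semi_axes Optional semi-axes `(a, b, c)` in mm.  If omitted, a
#'   sphere with the target volume is used.  If given, they must be
#'   consistent with `target_volume_cm3` within 0.5%.
#' @param perfused_fraction Fraction of the lesion volume with uptake,
#'   in (0, 1]; values below 1 cut the lesion by a plane.
#' @param core_fraction Fraction of each semi-axis occupied by a
#'   zero-uptake necrotic core, in [0, 1).
#' @param perfusion_axis Unit direction of the perfusion cut (default
#'   +x); only used when `perfused_fraction < 1`.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(target_volume_cm3, center, tbr = 5,
                        semi_axes = NULL, perfused_fraction = 1,
                        core_fraction = 0, perfusion_axis = c(1, 0, 0)) {
  stopifnot(target_volume_cm3 > 0, tbr >= 0,
            perfused_fraction > 0, perfused_fraction <= 1,
            core_fraction >= 0, core_fraction < 1)
  if (is.null(semi_axes)) {
    r <- (3 * target_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
    semi_axes <- c(r, r, r)
    shape <- "sphere"
  } else {
    semi_axes <- as.numeric(semi_axes)
    stopifnot(length(semi_axes) == 3L, all(semi_axes > 0))
    v <- 4 / 3 * pi * prod(semi_axes) / 1000
    if (abs(v - target_volume_cm3) / target_volume_cm3 > 0.005)
      stop(sprintf(
        "semi_axes give %.2f cm^3, inconsistent with target_volume %.2f cm^3",
        v, target_volume_cm3), call. = FALSE)
    shape <- if (max(semi_axes) - min(semi_axes) < 1e-9) "sphere" else "ellipsoid"
  }
  u <- as.numeric(perfusion_axis)
  u <- u / sqrt(sum(u^2))
  structure(list(shape = shape, center = as.numeric(center),
                 semi_axes = semi_axes,
                 target_volume_cm3 = target_volume_cm3, tbr = tbr,
                 perfused_fraction = perfused_fraction,
                 core_fraction = core_fraction, perfusion_axis = u),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @param model Noise model; only `"gaussian_correlated"` is provided.
#' @param background_cov Target coefficient of variation realized in the
#'   warm background (unitless).
#' @param correlation_sigma Spatial correlation length of the noise
#'   field, in voxels.
#' @param floor_fraction Signal floor, as a fraction of the mean nonzero
#'   signal, added under the square root of the signal-dependent
#'   standard deviation.
#' @export
noise_spec <- function(model = "gaussian_correlated", background_cov = 0.25,
                       correlation_sigma = 1, floor_fraction = 0.05) {
  stopifnot(identical(model, "gaussian_correlated"), background_cov >= 0,
            correlation_sigma >= 0, floor_fraction >= 0)
  structure(list(model = model, background_cov = background_cov,
                 correlation_sigma = correlation_sigma,
                 floor_fraction = floor_fraction),
            class = "noise_spec")
}

#' @rdname lesion_spec
#' @param grid_dim Grid shape (3 integers); if `NULL`, sized to the
#'   liver bounding box plus a margin.
#' @param spacing Voxel spacing in mm; default the PET grid
#'   `(4.07, 4.07, 3)`.
#' @param liver_volume_cm3 Liver volume; `NA` for a cold (no-background)
#'   phantom in which activity is confined to the lesions.
#' @param liver_semi_axes Optional liver ellipsoid semi-axes in mm.
#' @param lesions List of [lesion_spec()]s.
#' @param total_activity_gbq Total activity in the liver (or, for a cold
#'   phantom, in the lesions), GBq.
#' @param psf_fwhm_mm Gaussian post-filter FWHM, mm.
#' @param noise A [noise_spec()].
#' @param seed Integer seed used when simulating this phantom.
#' @export
phantom_spec <- function(lesions, total_activity_gbq = 3.0,
                         liver_volume_cm3 = 1200,
                         liver_semi_axes = NULL,
                         spacing = c(4.07, 4.07, 3), grid_dim = NULL,
                         psf_fwhm_mm = 5, noise = noise_spec(),
                         seed = 1L) {
  stopifnot(total_activity_gbq > 0, psf_fwhm_mm >= 0)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  cold <- is.na(liver_volume_cm3)
  if (!cold && is.null(liver_semi_axes)) {
    # mildly flattened liver-like ellipsoid with the requested volume
    ab <- c(1.55, 1.35)                      # a:c and b:c aspect ratios
    c3 <- liver_volume_cm3 * 1000 * 3 / (4 * pi * prod(ab))
    cc <- c3^(1 / 3)
    liver_semi_axes <- c(ab * cc, cc)
  }
  structure(list(lesions = lesions, total_activity_gbq = total_activity_gbq,
                 liver_volume_cm3 = liver_volume_cm3,
                 liver_semi_axes = liver_semi_axes,
                 spacing = as.numeric(spacing), grid_dim = grid_dim,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## rasterization --------------------------------------------------------

# logical array of voxels whose centers fall inside an ellipsoid
rasterize_ellipsoid <- function(dims, spacing, origin, center, semi_axes) {
  cx <- (origin[1] + (seq_len(dims[1]) - 1) * spacing[1] - center[1]) / semi_axes[1]
  cy <- (origin[2] + (seq_len(dims[2]) - 1) * spacing[2] - center[2]) / semi_axes[2]
  cz <- (origin[3] + (seq_len(dims[3]) - 1) * spacing[3] - center[3]) / semi_axes[3]
  q <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  q <= 1
}

# perfused sub-region of a rasterized lesion (planar cut and/or cored rim)
perfused_region <- function(les, lesion_vox, dims, spacing, origin) {
  perf <- lesion_vox
  if (les$core_fraction > 0) {
    core <- rasterize_ellipsoid(dims, spacing, origin, les$center,
                                les$semi_axes * les$core_fraction)
    perf <- perf & !core
  }
  if (les$perfused_fraction < 1) {
    idx <- which(perf)
    if (length(idx)) {
      ijk <- arrayInd(idx, dims)
      xyz <- sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
      proj <- as.numeric((xyz - matrix(les$center, nrow(xyz), 3,
                                       byrow = TRUE)) %*% les$perfusion_axis)
      keep <- proj <= stats::quantile(proj, les$perfused_fraction,
                                      type = 1, names = FALSE)
      drop <- idx[!keep]
      perf[drop] <- FALSE
    }
  }
  perf
}

#' Rasterize a phantom specification into ground-truth volumes
#'
#' Builds the piecewise-constant activity-concentration image (Bq/mL)
#' with the background concentration inside the liver, `tbr` times that
#' inside each lesion's perfused region and zero elsewhere, scaled so
#' the total activity over the voxelized grid equals the specified total
#' exactly.  Truth masks are the analytic shapes rasterized by
#' voxel-center inclusion.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `activity` ([voxel_image], Bq/mL),
#'   `truth_masks` (list of [voi_mask], one per lesion), `liver_mask`
#'   ([voi_mask]; all-false for a cold phantom) and `background_mask`
#'   (liver minus lesions; for a cold phantom, the perfused lesion
#'   voxels — the only region with signal against which noise can be
#'   calibrated).
#' @export
build_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cold <- is.na(spec$liver_volume_cm3)
  spacing <- spec$spacing
  margin_mm <- 6 * spacing                 # room for PSF tails
  if (cold) {
    ctr <- vapply(spec$lesions, `[[`, numeric(3), "center")
    sa <- vapply(spec$lesions, `[[`, numeric(3), "semi_axes")
    lo <- apply(ctr - sa, 1, min) - margin_mm
    hi <- apply(ctr + sa, 1, max) + margin_mm
  } else {
    lo <- -spec$liver_semi_axes - margin_mm
    hi <- spec$liver_semi_axes + margin_mm
  }
  dims <- if (is.null(spec$grid_dim))
    as.integer(ceiling((hi - lo) / spacing) + 1L) else as.integer(spec$grid_dim)
  origin <- lo
  vol_mL <- prod(spacing) / 1000           # voxel volume, mL (= cm^3)

  liver_vox <- if (cold) array(FALSE, dims)
  else rasterize_ellipsoid(dims, spacing, origin, c(0, 0, 0),
                           spec$liver_semi_axes)
  lesion_vox <- vector("list", length(spec$lesions))
  perf_vox <- vector("list", length(spec$lesions))
  occupied <- array(FALSE, dims)
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    lv <- rasterize_ellipsoid(dims, spacing, origin, les$center,
                              les$semi_axes)
    if (!any(lv))
      stop("geometry error: lesion ", i, " rasterizes to zero voxels",
           call. = FALSE)
    if (!cold && any(lv & !liver_vox))
      stop("geometry error: lesion ", i, " extends outside the liver",
           call. = FALSE)
    if (any(lv & occupied))
      stop("geometry error: lesion ", i, " overlaps another lesion",
           call. = FALSE)
    occupied <- occupied | lv
    lesion_vox[[i]] <- lv
    perf_vox[[i]] <- perfused_region(les, lv, dims, spacing, origin)
  }

  act <- array(0, dims)
  tbrs <- vapply(spec$lesions, `[[`, numeric(1), "tbr")
  perf_mL <- vapply(perf_vox, sum, numeric(1)) * vol_mL
  total_bq <- spec$total_activity_gbq * 1e9
  if (cold) {
    c0 <- total_bq / sum(tbrs * perf_mL)
    for (i in seq_along(spec$lesions))
      act[perf_vox[[i]]] <- c0 * tbrs[i]
  } else {
    bg_vox <- liver_vox & !occupied
    c_b <- total_bq / (sum(bg_vox) * vol_mL + sum(tbrs * perf_mL))
    act[bg_vox] <- c_b
    for (i in seq_along(spec$lesions))
      act[perf_vox[[i]]] <- c_b * tbrs[i]
  }

  bg_mask <- if (cold) Reduce(`|`, perf_vox) else liver_vox & !occupied
  list(activity = voxel_image(act, spacing, origin, unit = "Bq/mL"),
       truth_masks = lapply(lesion_vox, voi_mask, spacing = spacing,
                            origin = origin),
       liver_mask = voi_mask(liver_vox, spacing, origin),
       background_mask = voi_mask(bg_mask, spacing, origin))
}

#' Add correlated, signal-dependent Gaussian noise
#'
#' Adds zero-mean Gaussian noise with standard deviation proportional to
#' `sqrt(signal + floor)`, spatially correlated by a Gaussian of
#' `correlation_sigma` voxels, scaled so the realized coefficient of
#' variation inside `reference` matches `noise$background_cov`.
#' Negative results are clipped to zero.  Deterministic given `seed`.
#'
#' @param img A [voxel_image].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param reference A [voi_mask] marking the region (normally the warm
#'   liver background) whose coefficient of variation is calibrated; if
#'   `NULL`, all voxels with positive signal are used.
#' @return A noisy [voxel_image] on the same grid.
#' @export
add_noise <- function(img, noise, seed, reference = NULL) {
  stopifnot(inherits(img, "voxel_image"), inherits(noise, "noise_spec"))
  if (noise$background_cov == 0) return(img)
  v <- img$values
  ref <- if (is.null(reference)) v > 0 else reference$values
  if (!any(ref)) stop("noise reference region is empty", call. = FALSE)
  field <- with_seed(seed, array(stats::rnorm(length(v)), dim(v)))
  if (noise$correlation_sigma > 0)
    field <- gaussian_blur_vox(field, rep(noise$correlation_sigma, 3))
  field <- field / stats::sd(field)
  floor_abs <- noise$floor_fraction * mean(v[v > 0])
  raw <- field * sqrt(pmax(v, 0) + floor_abs)
  # calibrate to the *realized* CoV in the reference region: the blurred
  # background already varies, so the added-noise variance is the target
  # variance minus the baseline variance (zero if already above target)
  target_var <- (noise$background_cov * mean(v[ref]))^2
  base_var <- stats::var(v[ref])
  k <- sqrt(max(target_var - base_var, 0)) / stats::sd(raw[ref])
  out <- pmax(v + k * raw, 0)
  voxel_image(array(out, dim(v)), img$spacing, img$origin, unit = img$unit)
}

# simulate one phantom case end to end: truth -> PSF -> noise
simulate_case <- function(spec, id = "case", patient_id = id) {
  truth <- build_truth(spec)
  blurred <- apply_psf(truth$activity, spec$psf_fwhm_mm)
  pet <- add_noise(blurred, spec$noise, seed = spec$seed,
                   reference = truth$background_mask)
  list(id = id, patient_id = patient_id, spec = spec,
       activity = truth$activity, pet = pet,
       truth_masks = truth$truth_masks, liver_mask = truth$liver_mask,
       background_mask = truth$background_mask)
}

#' The three-phantom validation suite
#'
#' Builds the three liver phantom studies on the PET grid
#' (4.07 x 4.07 x 3 mm): (a) a 60 cm^3 hot sphere in a cold background,
#' (b) a 60 cm^3 hot sphere in a warm 1200 cm^3 liver at TBR 5:1 with
#' 3.0 GBq total, and (c) 8, 16 and 29 cm^3 lesions (two spheres and an
#' ovoid) at TBRs 5.1, 6.2 and 5.5 in the warm liver.  Each case carries
#' the piecewise-constant truth activity, the 5-mm-FWHM blurred and
#' noisy PET-like image, and the rasterized truth masks, which double as
#' the morphologic segmentation for phantom analyses.
#'
#' @param seed Integer master seed (fixes the noise realizations).
#' @param noise A [noise_spec()]; the default emulates the high noise of
#'   post-therapy yttrium-90 PET.
#' @param psf_fwhm_mm Gaussian post-filter FWHM, mm.
#' @return List of three case objects as returned by the simulator; case
#'   element `lesion_labels` names the lesions.
#' @export
make_phantom_suite <- function(seed = 1L, noise = noise_spec(),
                               psf_fwhm_mm = 5) {
  seed <- as.integer(seed)
  # cold-case activity chosen to match the warm case's lesion
  # concentration: c_b = 3 GBq / (1140 + 5 * 60) mL, lesion = 5 c_b
  c_les <- 3e9 / 1440 * 5                  # Bq/mL
  cold_act_gbq <- c_les * 60 / 1e9
  # scale the cold calibration so the sphere plateau carries the same
  # relative noise as a TBR-5 lesion in the warm phantom
  cold_noise <- noise
  cold_noise$background_cov <- noise$background_cov / sqrt(5)

  case_a <- simulate_case(phantom_spec(
    lesions = list(lesion_spec(60, c(0, 0, 0), tbr = 1)),
    total_activity_gbq = cold_act_gbq, liver_volume_cm3 = NA,
    psf_fwhm_mm = psf_fwhm_mm, noise = cold_noise,
    seed = child_seed(seed, "cold60")), id = "sphere60_cold")
  case_b <- simulate_case(phantom_spec(
    lesions = list(lesion_spec(60, c(0, 0, 0), tbr = 5)),
    total_activity_gbq = 3.0, psf_fwhm_mm = psf_fwhm_mm, noise = noise,
    seed = child_seed(seed, "warm60")), id = "sphere60_warm")
  case_c <- simulate_case(phantom_spec(
    lesions = list(
      lesion_spec(8, c(-45, 10, 0), tbr = 5.1),
      lesion_spec(16, c(15, -38, 5), tbr = 6.2),
      lesion_spec(29, c(28, 38, -6), tbr = 5.5,
                  semi_axes = c(24, 17, 17.004))),
    total_activity_gbq = 3.0, psf_fwhm_mm = psf_fwhm_mm, noise = noise,
    seed = child_seed(seed, "multi")), id = "multi_lesion")
  case_a$lesion_labels <- "sphere60_cold"
  case_b$lesion_labels <- "sphere60_warm"
  case_c$lesion_labels <- c("sphere8", "sphere16", "ovoid29")
  list(case_a, case_b, case_c)
}

#' Simulate a patient-like cohort
#'
#' Generates `n_patients` cases, each a warm 1200 cm^3 liver carrying
#' 1 to 9 lesions with log-uniform volumes in 2 to 818 cm^3.  Each
#' lesion is randomly fully perfused, partially perfused (perfused
#' fraction in \[0.3, 1)) or a rim lesion (necrotic core fraction in
#' \[0.3, 0.7\]).  The morphologic segmentation (MS) mask is the true
#' shape displaced by a per-axis Gaussian translation of
#' `registration_sigma_mm`, emulating residual rigid mis-registration of
#' the anatomy-derived contour; the truth mask is undisplaced.  Patient
#' identity is carried per lesion for clustered statistics.
#'
#' @param n_patients Number of patients (>= 1).
#' @param lesions_per_patient_range Integer range, lesions per patient.
#' @param seed Integer master seed.
#' @param registration_sigma_mm Per-axis standard deviation of the MS
#'   displacement, mm.
#' @param volume_range_cm3 Lesion-volume range (log-uniform), cm^3.
#' @param tbr_range Lesion TBR range (log-uniform).
#' @param activity_range_gbq Per-patient total liver activity range
#'   (uniform), GBq.
#' @param noise,psf_fwhm_mm As in [make_phantom_suite()].
#' @return List of case objects; each has `ms_masks` (displaced
#'   morphologic masks) alongside `truth_masks`.
#' @export
make_patient_cohort <- function(n_patients, lesions_per_patient_range = c(1, 9),
                                seed = 1L, registration_sigma_mm = 2,
                                volume_range_cm3 = c(2, 818),
                                tbr_range = c(1.5, 6),
                                activity_range_gbq = c(0.6, 4),
                                noise = noise_spec(), psf_fwhm_mm = 5) {
  stopifnot(n_patients >= 1)
  seed <- as.integer(seed)
  lapply(seq_len(n_patients), function(p) {
    s <- child_seed(seed, paste0("patient", p))
    with_seed(s, simulate_patient(p, lesions_per_patient_range,
                                  registration_sigma_mm, volume_range_cm3,
                                  tbr_range, activity_range_gbq, noise,
                                  psf_fwhm_mm, noise_seed = child_seed(s, "nz")))
  })
}

simulate_patient <- function(p, nles_range, reg_sigma, vol_range, tbr_range,
                             act_range, noise, psf_fwhm_mm, noise_seed) {
  liver_sa <- phantom_spec(list(lesion_spec(10, c(0, 0, 0))))$liver_semi_axes
  spacing <- c(4.07, 4.07, 3)
  n_les <- sample(seq(nles_range[1], nles_range[2]), 1)
  vols <- sort(exp(stats::runif(n_les, log(vol_range[1]), log(vol_range[2]))),
               decreasing = TRUE)
  lesions <- list()
  shifts <- list()
  placed <- NULL                            # occupied voxels on a probe grid
  probe <- NULL
  for (v in vols) {
    res <- place_lesion(v, liver_sa, spacing, placed, probe, vol_range,
                        tbr_range)
    if (is.null(res)) next
    lesions[[length(lesions) + 1L]] <- res$les
    shifts[[length(shifts) + 1L]] <- stats::rnorm(3, 0, reg_sigma)
    placed <- res$placed
    probe <- res$probe
  }
  if (!length(lesions))                     # always give the patient a lesion
    lesions <- list(lesion_spec(vol_range[1] * 2, c(0, 0, 0),
                                tbr = mean(tbr_range)))
  spec <- phantom_spec(lesions,
                       total_activity_gbq = stats::runif(1, act_range[1],
                                                         act_range[2]),
                       psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                       seed = noise_seed)
  case <- simulate_case(spec, id = sprintf("patient%02d", p),
                        patient_id = sprintf("P%02d", p))
  # MS = shape displaced by residual registration error, rasterized on
  # the case grid
  dims <- dim(case$pet$values)
  case$ms_masks <- lapply(seq_along(lesions), function(i) {
    les <- lesions[[i]]
    voi_mask(rasterize_ellipsoid(dims, spacing, case$pet$origin,
                                 les$center + shifts[[i]], les$semi_axes),
             spacing, case$pet$origin)
  })
  case$lesion_labels <- sprintf("%s_L%d", case$patient_id,
                                seq_along(lesions))
  case
}

# rejection placement of one lesion inside the liver with a >= 1 voxel
# gap to previously placed lesions; shrinks the volume when it cannot fit
place_lesion <- function(v, liver_sa, spacing, placed, probe, vol_range,
                         tbr_range) {
  for (shrink in 1:6) {
    if (v > 200) {
      sa <- liver_sa * (v * 1000 * 3 / (4 * pi * prod(liver_sa)))^(1 / 3)
    } else {
      ecc <- exp(stats::runif(3, log(0.8), log(1.25)))
      sa <- (3 * v * 1000 / (4 * pi))^(1 / 3) * ecc / prod(ecc)^(1 / 3)
    }
    if (is.null(probe)) {
      lo <- -liver_sa - 2 * spacing
      dims <- as.integer(ceiling((liver_sa * 2 + 4 * spacing) / spacing) + 1L)
      probe <- list(dims = dims, origin = lo,
                    liver = rasterize_ellipsoid(dims, spacing, lo, c(0, 0, 0),
                                                liver_sa))
      placed <- array(FALSE, dims)
    }
    for (try in 1:60) {
      ctr <- stats::runif(3, -1, 1) * pmax(liver_sa - sa, 0)
      lv <- rasterize_ellipsoid(probe$dims, spacing, probe$origin, ctr, sa)
      if (!any(lv)) next
      if (any(lv & !probe$liver)) next
      if (any(dilate6(lv) & placed)) next
      tbr <- exp(stats::runif(1, log(tbr_range[1]), log(tbr_range[2])))
      perf_mode <- sample(c("full", "partial", "rim"), 1,
                          prob = c(0.5, 0.25, 0.25))
      les <- lesion_spec(4 / 3 * pi * prod(sa) / 1000, ctr, tbr = tbr,
                         semi_axes = sa,
                         perfused_fraction = if (perf_mode == "partial")
                           stats::runif(1, 0.3, 0.999) else 1,
                         core_fraction = if (perf_mode == "rim")
                           stats::runif(1, 0.3, 0.7) else 0,
                         perfusion_axis = stats::rnorm(3))
      return(list(les = les, placed = placed | lv, probe = probe))
    }
    v <- max(vol_range[1], v / 2)           # could not fit: try smaller
  }
  NULL
}
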