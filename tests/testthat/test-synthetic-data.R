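test_that("uniform liver activity equals total / volume (2.5 MBq/mL)", {
  # 3 GBq over a 1200 cm^3 liver with no lesions -> 3e9 / 1.2e6 Bq/mL
  spec <- phantom_spec(lesions = list(), total_activity_gbq = 3.0,
                       liver_volume_cm3 = 1200)
  tr <- build_truth(spec)
  inside <- tr$liver_mask$values
  expect_equal(unique(round(tr$activity$values[inside], 6)),
               3e9 / (sum(inside) * prod(spec$spacing) / 1000),
               tolerance = 1e-9)
  # voxelized liver volume is close to nominal, so concentration is
  # close to the analytic 2.5e6 Bq/mL
  expect_equal(mean(tr$activity$values[inside]), 2.5e6, tolerance = 0.02)
  tot <- sum(tr$activity$values) * prod(spec$spacing) / 1000
  expect_equal(tot, 3e9, tolerance = 1e-9)
})

test_that("lesion-to-background concentration ratio equals the TBR pre-blur", {
  spec <- phantom_spec(list(lesion_spec(16, c(0, 0, 0), tbr = 6.2)))
  tr <- build_truth(spec)
  les <- tr$truth_masks[[1]]$values
  bg <- tr$background_mask$values
  expect_equal(mean(tr$activity$values[les]) / mean(tr$activity$values[bg]),
               6.2, tolerance = 1e-12)
})

test_that("cold phantom confines activity to the sphere", {
  b <- blurred_sphere(60, warm = FALSE, fwhm = 0)
  act <- b$truth$activity
  expect_true(all(act$values[!b$ms$values] == 0))
  expect_true(all(act$values[b$ms$values] > 0))
  expect_equal(volume_cm3(b$ms), 60, tolerance = 0.05)  # one voxel shell
})

test_that("geometry violations are rejected", {
  expect_error(build_truth(phantom_spec(list(
    lesion_spec(8, c(0, 0, 0)), lesion_spec(8, c(5, 0, 0))))),
    "overlap")
  expect_error(build_truth(phantom_spec(list(
    lesion_spec(8, c(90, 0, 0))))), "outside the liver")
})

test_that("apply_psf preserves total activity and has the right width", {
  # total conservation on an interior source
  b <- blurred_sphere(16, warm = TRUE, fwhm = 0)
  blurred <- apply_psf(b$truth$activity, 5)
  expect_equal(sum(blurred$values), sum(b$truth$activity$values),
               tolerance = 1e-3)
  # identity at fwhm 0, uniform interior unchanged
  expect_identical(apply_psf(b$truth$activity, 0), b$truth$activity)
  u <- tiny_image(2, c(15, 15, 15), spacing = c(2, 2, 2))
  expect_equal(apply_psf(u, 5)$values[8, 8, 8], 2, tolerance = 1e-6)
  # delta function: fitted FWHM along each axis within 2%
  d <- array(0, c(41, 41, 41))
  d[21, 21, 21] <- 1
  img <- voxel_image(d, spacing = c(1, 1, 1))
  bl <- apply_psf(img, 5)$values
  for (prof in list(bl[, 21, 21], bl[21, , 21], bl[21, 21, ])) {
    sigma <- sqrt(sum(prof * (seq_along(prof) - 21)^2) / sum(prof))
    expect_equal(sigma * 2 * sqrt(2 * log(2)), 5, tolerance = 0.02)
  }
  expect_error(apply_psf(u, -1), "non-negative")
})

test_that("add_noise calibrates the realized background CoV", {
  u <- tiny_image(1, c(30, 30, 30), spacing = c(2, 2, 2))
  ns <- noise_spec(background_cov = 0.25)
  noisy <- add_noise(u, ns, seed = 5)
  interior <- array(FALSE, dim(u$values))
  interior[5:26, 5:26, 5:26] <- TRUE
  cov <- sd(noisy$values[interior]) / mean(noisy$values[interior])
  expect_equal(cov, 0.25, tolerance = 0.1)
  # identity at zero CoV; determinism at fixed seed
  expect_identical(add_noise(u, noise_spec(background_cov = 0), seed = 1), u)
  expect_identical(add_noise(u, ns, seed = 5)$values, noisy$values)
  expect_false(identical(add_noise(u, ns, seed = 6)$values, noisy$values))
})

test_that("realized background CoV increases with the noise knob", {
  b <- blurred_sphere(60, warm = TRUE, fwhm = 5)
  ref <- b$truth$background_mask
  covs <- vapply(c(0.1, 0.2, 0.3), function(target) {
    n <- add_noise(b$pet, noise_spec(background_cov = target), seed = 2,
                   reference = ref)
    sd(n$values[ref$values]) / mean(n$values[ref$values])
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
  expect_equal(covs, c(0.1, 0.2, 0.3), tolerance = 0.1)
})

test_that("blur strictly reduces lesion contrast (partial-volume effect)", {
  for (v in c(8, 60)) {
    b <- blurred_sphere(v, warm = TRUE, tbr = 5, fwhm = 5)
    les <- b$ms$values
    bg <- b$truth$background_mask$values
    contrast <- mean(b$pet$values[les]) / mean(b$pet$values[bg])
    expect_lt(contrast, 5)
    expect_gt(contrast, 1)
  }
})

test_that("the phantom suite reproduces the printed study geometry", {
  suite <- cached("suite_seed2", make_phantom_suite(seed = 2))
  expect_length(suite, 3)
  expect_equal(vapply(suite, function(cs) length(cs$truth_masks), integer(1)),
               c(1L, 1L, 3L))
  multi <- suite[[3]]
  tbrs <- vapply(multi$spec$lesions, `[[`, numeric(1), "tbr")
  expect_equal(tbrs, c(5.1, 6.2, 5.5))
  vols <- vapply(multi$truth_masks, volume_cm3, numeric(1))
  expect_equal(vols, c(8, 16, 29), tolerance = 0.06)
  expect_equal(volume_cm3(multi$liver_mask), 1200, tolerance = 0.02)
  expect_equal(multi$pet$spacing, c(4.07, 4.07, 3))
  # determinism: same master seed -> bit-identical images
  suite2 <- make_phantom_suite(seed = 2)
  expect_identical(suite2[[3]]$pet$values, multi$pet$values)
})

test_that("patient cohort: volumes in range, MS displaced, reproducible", {
  coh <- cached("cohort_small",
                make_patient_cohort(3, lesions_per_patient_range = c(1, 3),
                                    seed = 5))
  expect_length(coh, 3)
  vols <- unlist(lapply(coh, function(cs)
    vapply(cs$truth_masks, volume_cm3, numeric(1))))
  expect_true(all(vols >= 2 * 0.8 & vols <= 818 * 1.2))
  pid <- unlist(lapply(coh, function(cs)
    rep(cs$patient_id, length(cs$truth_masks))))
  expect_length(unique(pid), 3)
  coh2 <- make_patient_cohort(3, lesions_per_patient_range = c(1, 3),
                              seed = 5)
  expect_identical(coh2[[2]]$pet$values, coh[[2]]$pet$values)
  expect_identical(coh2[[2]]$ms_masks[[1]]$values,
                   coh[[2]]$ms_masks[[1]]$values)
})

test_that("zero registration error makes MS equal the truth mask", {
  coh <- make_patient_cohort(2, lesions_per_patient_range = c(1, 2),
                             seed = 9, registration_sigma_mm = 0)
  for (cs in coh)
    for (i in seq_along(cs$truth_masks))
      expect_identical(cs$ms_masks[[i]]$values, cs$truth_masks[[i]]$values)
})
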