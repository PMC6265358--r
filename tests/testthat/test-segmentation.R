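test_that("init_from_mask recovers the analytic rays of simple shapes", {
  # grid-centered sphere: all six rays equal the radius within half a
  # voxel
  dims0 <- c(31, 31, 41)
  sp0 <- c(2, 2, 1.5)
  org0 <- -(dims0 - 1) / 2 * sp0
  sph <- voi_mask(ysegdose:::rasterize_ellipsoid(dims0, sp0, org0,
                                                 c(0, 0, 0),
                                                 rep(24.3, 3)),
                  sp0, org0)
  init <- init_from_mask(sph)
  expect_true(all(abs(init$ray_lengths - 24.3) <=
                    sp0[c(1, 1, 2, 2, 3, 3)] / 2 + 1e-9))
  # axis-aligned ellipsoid: rays (a, a, b, b, c, c)
  dims <- c(31, 31, 41)
  sp <- c(2, 2, 1.5)
  org <- -(dims - 1) / 2 * sp
  ell <- voi_mask(ysegdose:::rasterize_ellipsoid(dims, sp, org, c(0, 0, 0),
                                                 c(20, 14, 10)),
                  sp, org)
  init2 <- init_from_mask(ell)
  expect_equal(init2$ray_lengths, c(20, 20, 14, 14, 10, 10),
               tolerance = 0.08)
})

test_that("hollow rim lesion relocates the seed into the rim", {
  dims <- c(25, 25, 25)
  sp <- c(2, 2, 2)
  org <- -(dims - 1) / 2 * sp
  outer_m <- ysegdose:::rasterize_ellipsoid(dims, sp, org, c(0, 0, 0),
                                            c(18, 18, 18))
  inner <- ysegdose:::rasterize_ellipsoid(dims, sp, org, c(0, 0, 0),
                                          c(12, 12, 12))
  rim <- voi_mask(outer_m & !inner, sp, org)
  init <- init_from_mask(rim)
  idx <- round((init$seed - org) / sp) + 1
  expect_true(rim$values[idx[1], idx[2], idx[3]])
})

test_that("sharp-edged sphere is recovered within one voxel shell", {
  b <- blurred_sphere(60, warm = FALSE, fwhm = 0)
  ps <- gradient_segment(b$pet, init_from_mask(b$ms),
                         gradient_params(smooth_sigma = 1))
  oracle <- sum(b$ms$values)            # voxel-center count in the sphere
  shell <- sum(boundary_voxels(b$ms)$values)
  expect_lt(abs(sum(ps$values) - oracle), shell)
  expect_gt(dice(b$ms, ps), 0.9)
})

test_that("blurred warm sphere edge is found at the true radius", {
  # 1D erf-profile argument: the outward-derivative minimum of a blurred
  # step sits at the step location, so the recovered equivalent radius
  # is within 1 mm of truth
  b <- blurred_sphere(60, warm = TRUE, fwhm = 5)
  ps <- gradient_segment(b$pet, init_from_mask(b$ms))
  r_true <- (3 * volume_cm3(b$ms) * 1000 / (4 * pi))^(1 / 3)
  r_ps <- (3 * volume_cm3(ps) * 1000 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_ps - r_true), 1)
})

test_that("gradient segmentation is scale-invariant and deterministic", {
  b <- blurred_sphere(16, warm = TRUE, fwhm = 5, noise_cov = 0.25)
  init <- init_from_mask(b$ms)
  ps <- gradient_segment(b$pet, init)
  scaled <- voxel_image(b$pet$values * 37.5, b$pet$spacing, b$pet$origin,
                        unit = b$pet$unit)
  expect_identical(gradient_segment(scaled, init)$values, ps$values)
  expect_identical(gradient_segment(b$pet, init)$values, ps$values)
  # jittered runs are deterministic given the seed
  pj <- gradient_params(jitter_sigma = 2)
  expect_identical(gradient_segment(b$pet, init, pj, seed = 4)$values,
                   gradient_segment(b$pet, init, pj, seed = 4)$values)
})

test_that("gradient mask is connected, contains the seed, stays in bound", {
  b <- blurred_sphere(29, warm = TRUE, fwhm = 5, noise_cov = 0.25)
  init <- init_from_mask(b$ms)
  ps <- gradient_segment(b$pet, init)
  idx <- round((init$seed - ps$origin) / ps$spacing) + 1
  expect_true(ps$values[idx[1], idx[2], idx[3]])
  comp <- ysegdose:::flood_fill26(ps$values,
                                  which(ps$values)[1])
  expect_identical(comp, ps$values)     # one 26-connected component
})

test_that("flat image raises a degenerate-input error", {
  u <- tiny_image(1, c(20, 20, 20), spacing = c(2, 2, 2))
  init <- gradient_init(c(19, 19, 19), rep(8, 6))
  expect_error(gradient_segment(u, init), "degenerate")
  expect_error(gradient_segment(u, gradient_init(c(500, 0, 0), rep(8, 6))),
               "outside")
})

test_that("threshold segmentation recovers binary objects exactly", {
  b <- blurred_sphere(29, warm = FALSE, fwhm = 0)
  bound <- threshold_bound(b$ms)
  for (pct in c(10, 50, 90))
    expect_identical(threshold_segment(b$pet, bound, pct)$values,
                     b$ms$values)
  # pct near 100 keeps only the maximum voxel
  noisy <- add_noise(b$pet, noise_spec(background_cov = 0.1), seed = 3,
                     reference = b$ms)
  expect_equal(sum(threshold_segment(noisy, bound, 99.9)$values), 1L)
})

test_that("threshold is taken as percent of the in-bound maximum", {
  b <- blurred_sphere(16, warm = TRUE, fwhm = 5)
  bound <- threshold_bound(b$ms)
  m1 <- threshold_segment(b$pet, bound, 60)
  scaled <- voxel_image(b$pet$values * 5, b$pet$spacing, b$pet$origin)
  expect_identical(threshold_segment(scaled, bound, 60)$values, m1$values)
})

test_that("volume-optimal threshold is higher in warm than cold background", {
  # erf edge profile: half-rise sits at (plateau + background) / 2, so
  # the optimal percent grows with the background level, and the
  # cold-optimal percent overestimates the warm-background volume
  cold <- cached("thr_cold", blurred_sphere(60, warm = FALSE, fwhm = 5))
  warm <- cached("thr_warm", blurred_sphere(60, warm = TRUE, fwhm = 5))
  grid <- seq(5, 95, by = 1)
  p_cold <- optimal_threshold(cold$pet, threshold_bound(cold$ms),
                              volume_cm3(cold$ms), pct_grid = grid)
  p_warm <- optimal_threshold(warm$pet, threshold_bound(warm$ms),
                              volume_cm3(warm$ms), pct_grid = grid)
  expect_gt(p_warm, p_cold)
  v_over <- volume_cm3(threshold_segment(warm$pet, threshold_bound(warm$ms),
                                         p_cold))
  expect_gt(v_over, volume_cm3(warm$ms))
  assign("thr_pcts", list(cold = p_cold, warm = p_warm, v_over = v_over),
         envir = .fixture_cache)
})

test_that("optimal_threshold breaks ties toward the lower percent", {
  b <- blurred_sphere(16, warm = FALSE, fwhm = 0)
  bound <- threshold_bound(b$ms)
  # binary object: every pct recovers it exactly, so ties everywhere
  expect_equal(optimal_threshold(b$pet, bound, volume_cm3(b$ms),
                                 pct_grid = seq(10, 90, 10)), 10)
})
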