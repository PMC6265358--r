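make_dvh <- function(doses, vol = 0.05) {
  structure(list(doses = sort(doses), voxel_volume_cm3 = vol),
            class = "dvh")
}

test_that("compute_dvh collects the masked voxel doses sorted", {
  d <- voxel_image(array(c(3, 1, 2, 9, 9, 9, 9, 9), c(2, 2, 2)),
                   c(1, 1, 1), unit = "Gy")
  m <- box_mask(c(2, 2, 2), 1:2, 1:2, 1)
  m$values[2, 2, 1] <- FALSE
  dvh <- compute_dvh(d, m)
  expect_equal(dvh$doses, c(1, 2, 3))
  expect_equal(length(dvh$doses), sum(m$values))
  empty <- voi_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_error(compute_dvh(d, empty), "empty")
  off <- voi_mask(m$values, c(2, 2, 2))
  expect_error(compute_dvh(d, off), "grid")
})

test_that("Dq follows the (i-1)/(n-1) interpolation rule", {
  dvh <- make_dvh(seq(10, 100, by = 10))
  # q = 90: quantile at p = 0.1 -> between 10 and 20 at 19.0
  expect_equal(dvh_percentile(dvh, 90), 19)
  expect_equal(dvh_percentile(dvh, 50), median(dvh$doses))
  u <- make_dvh(rep(42, 17))
  for (q in c(10, 50, 90)) expect_equal(dvh_percentile(u, q), 42)
  one <- make_dvh(7)
  expect_equal(dvh_percentile(one, 90), 7)
  # non-increasing in q, and D90 <= D70
  set.seed(1)
  r <- make_dvh(rexp(101, 1 / 100))
  qs <- vapply(seq(5, 95, 5), dvh_percentile, numeric(1), dvh = r)
  expect_true(all(diff(qs) <= 0))
  expect_lte(dvh_percentile(r, 90), dvh_percentile(r, 70))
})

test_that("BED transform matches the hand-computed value", {
  p <- radiobiology_params()
  expect_equal(p$alpha_beta, 10)
  expect_equal(p$lambda_phys, 0.0108)
  expect_equal(p$mu_repair, 0.462)
  expect_equal(bed_transform(0, p), 0)
  # 100 + 100^2/10 * 0.0108/(0.0108 + 0.462) = 122.84 Gy
  expect_equal(bed_transform(100, p), 122.8426, tolerance = 1e-4)
  big <- radiobiology_params(alpha_beta = 1e12)
  expect_equal(bed_transform(100, big), 100, tolerance = 1e-6)
  d <- seq(0, 650, by = 10)
  expect_true(all(bed_transform(d, p) >= d))
  expect_true(all(diff(bed_transform(d, p)) > 0))
})

test_that("dose_metrics summarizes mean, quantiles, BED and EUD coherently", {
  u <- make_dvh(rep(100, 50))
  m <- dose_metrics(u)
  expect_equal(m$mean_Gy, 100)
  expect_equal(m$d70_Gy, 100)
  expect_equal(m$d90_Gy, 100)
  expect_equal(m$eud_Gy, 100, tolerance = 1e-9)
  expect_equal(m$volume_cm3, 50 * 0.05)
  set.seed(6)
  r <- make_dvh(runif(201, 10, 600))
  mr <- dose_metrics(r)
  p <- radiobiology_params()
  # monotone-transform quantile equivariance
  expect_equal(mr$bed90_Gy, bed_transform(mr$d90_Gy, p), tolerance = 1e-9)
  expect_equal(mr$bed70_Gy, bed_transform(mr$d70_Gy, p), tolerance = 1e-9)
  # Jensen: EUD below the mean for alpha > 0, equality iff uniform
  expect_lt(mr$eud_Gy, mr$mean_Gy)
  expect_gte(mr$bed_mean_Gy, mr$mean_Gy)
})

test_that("Dice matches hand values and conventions", {
  a <- box_mask(c(8, 8, 8), 2:3, 2:3, 2:3)   # 8 voxels
  b <- box_mask(c(8, 8, 8), 2:3, 2:3, 2:5)   # 16 voxels, contains a
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(dice(b, a), 2 / 3)            # symmetry
  expect_equal(dice(a, a), 1)
  c_ <- box_mask(c(8, 8, 8), 6:7, 6:7, 6:7)
  expect_equal(dice(a, c_), 0)
  e <- voi_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
  expect_warning(val <- dice(e, e), "empty")
  expect_equal(val, 1)
  expect_error(dice(a, voi_mask(a$values, c(2, 2, 2))), "grid")
})

test_that("MDA matches hand values and the brute-force oracle", {
  sp <- c(4.07, 4.07, 3)
  a <- box_mask(c(12, 12, 12), 2, 5, 5, spacing = sp)
  b <- box_mask(c(12, 12, 12), 5, 5, 5, spacing = sp)
  expect_equal(mda(a, b), 3 * 4.07)
  expect_equal(mda(a, a), 0)
  expect_equal(mda(a, b), mda(b, a))
  # translated solid cube vs oracle (exact agreement)
  cu1 <- box_mask(c(14, 14, 14), 3:7, 3:7, 3:7, spacing = c(2, 3, 2.5))
  cu2 <- box_mask(c(14, 14, 14), 5:9, 4:8, 6:10, spacing = c(2, 3, 2.5))
  expect_equal(mda(cu1, cu2), mda_bruteforce(cu1, cu2), tolerance = 1e-9)
  # random blobs vs oracle
  set.seed(21)
  v1 <- array(runif(10^3) > 0.7, c(10, 10, 10))
  v2 <- array(runif(10^3) > 0.7, c(10, 10, 10))
  m1 <- voi_mask(v1, sp); m2 <- voi_mask(v2, sp)
  expect_equal(mda(m1, m2), mda_bruteforce(m1, m2), tolerance = 1e-8)
  expect_error(mda(a, voi_mask(array(FALSE, c(12, 12, 12)), sp)),
               "non-empty")
})

test_that("EUD correlates strongly with mean dose at alpha = 0.004", {
  # lesion-like skewed dose samples up to ~650 Gy
  set.seed(14)
  p <- radiobiology_params()
  stats_ <- t(vapply(1:40, function(i) {
    mu <- runif(1, 15, 600)
    d <- pmin(pmax(rnorm(300, mu, 0.3 * mu), 0), 900)
    m <- dose_metrics(make_dvh(d), p)
    c(m$eud_Gy, m$mean_Gy)
  }, numeric(2)))
  expect_gt(cor(stats_[, 1], stats_[, 2]), 0.95)
})

test_that("dvh_curve is a non-increasing cumulative curve from 1", {
  d <- make_dvh(c(10, 20, 30, 40))
  cur <- dvh_curve(d, n = 50)
  expect_equal(cur$volume_fraction[1], 1)
  expect_true(all(diff(cur$volume_fraction) <= 0))
})
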