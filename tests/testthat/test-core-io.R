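test_that("NIfTI round-trip preserves values and geometry", {
  set.seed(3)
  img <- voxel_image(array(runif(1000), c(10, 10, 10)),
                     spacing = c(4.07, 4.07, 3.0), origin = c(-20, 5, 1.5),
                     unit = "Bq/mL")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(img, f)
  back <- read_image(f, unit = "Bq/mL")
  expect_identical(dim(back$values), dim(img$values))
  expect_equal(back$values, img$values, tolerance = 0)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
  expect_equal(back$origin, img$origin, tolerance = 1e-6)
})

test_that("mask round-trip stores uint8 0/1 and re-reads as logical", {
  m <- box_mask(c(6, 6, 6), 2:4, 2:5, 3, spacing = c(4.07, 4.07, 3))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  back <- read_mask(f)
  expect_identical(back$values, m$values)
  expect_equal(back$spacing, m$spacing, tolerance = 1e-6)
})

test_that("reading a 4D payload is a format error", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 2))), f)
  expect_error(read_image(f), "3D")
})

test_that("ASCII NRRD with spacings and origin is read correctly", {
  vals <- array(seq_len(24) / 10, c(2, 3, 4))
  f <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               "sizes: 2 3 4", "spacings: 4.07 4.07 3",
               "space origin: (1.5,-2,0)", "encoding: ascii", ""),
             con)
  writeLines(paste(as.vector(vals), collapse = " "), con)
  close(con)
  g <- read_image(f)
  expect_equal(g$values, vals)
  expect_equal(g$spacing, c(4.07, 4.07, 3))
  expect_equal(g$origin, c(1.5, -2, 0))
})

test_that("NRRD header errors name the missing or bad field", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 4",
               "sizes: 2 2 2 2", "encoding: ascii", "", "0"), f)
  expect_error(read_image(f), "dimension")
})

test_that("volume_cm3 equals voxel count times voxel volume", {
  m <- box_mask(c(10, 10, 10), 1:10, 1:10, 1:10,
                spacing = c(4.07, 4.07, 3.0))
  expect_equal(volume_cm3(m), 1000 * 4.07 * 4.07 * 3 / 1000,
               tolerance = 1e-12)
  expect_equal(volume_cm3(m), 49.6947, tolerance = 1e-3)
  iso <- box_mask(c(10, 10, 10), 1:10, 1:10, 1:10)
  expect_equal(volume_cm3(iso), 1)
  empty <- box_mask(c(5, 5, 5), 1, 1, 1)
  empty$values[] <- FALSE
  expect_equal(volume_cm3(empty), 0)
})

test_that("volume is additive over disjoint masks and translation-invariant", {
  a <- box_mask(c(8, 8, 8), 1:2, 1:3, 1:4, spacing = c(2, 3, 1))
  b <- box_mask(c(8, 8, 8), 5:6, 5:6, 5:6, spacing = c(2, 3, 1))
  ab <- voi_mask(a$values | b$values, a$spacing, a$origin)
  expect_equal(volume_cm3(ab), volume_cm3(a) + volume_cm3(b))
  shifted <- voi_mask(a$values, a$spacing, origin = c(100, -50, 7))
  expect_equal(volume_cm3(shifted), volume_cm3(a))
})

test_that("boundary_voxels matches combinatorial counts and conventions", {
  cube <- box_mask(c(9, 9, 9), 3:7, 3:7, 3:7)
  expect_equal(sum(boundary_voxels(cube)$values), 5^3 - 3^3)
  single <- box_mask(c(5, 5, 5), 3, 3, 3)
  expect_identical(boundary_voxels(single)$values, single$values)
  # full grid: the border counts as outside, so faces remain
  full <- box_mask(c(4, 4, 4), 1:4, 1:4, 1:4)
  expect_equal(sum(boundary_voxels(full)$values), 4^3 - 2^3)
  expect_error(boundary_voxels(voi_mask(array(FALSE, c(3, 3, 3)),
                                        c(1, 1, 1))), "empty")
})

test_that("boundary is a subset of the mask and idempotent-contained", {
  set.seed(11)
  v <- array(runif(12^3) > 0.4, c(12, 12, 12))
  m <- voi_mask(v, c(1, 2, 3))
  b <- boundary_voxels(m)
  expect_true(all(m$values[b$values]))
  b2 <- boundary_voxels(b)
  expect_true(all(b$values[b2$values]))
})

test_that("constructors validate geometry and finiteness", {
  expect_error(voxel_image(array(1, c(3, 3)), c(1, 1, 1)), "3D")
  expect_error(voxel_image(array(1, c(3, 3, 3)), c(1, -1, 1)), "positive")
  bad <- array(1, c(3, 3, 3)); bad[2, 2, 2] <- NA
  expect_error(voxel_image(bad, c(1, 1, 1)), "finite")
  expect_error(voi_mask(array(2, c(3, 3, 3)), c(1, 1, 1)), "0/1")
})
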