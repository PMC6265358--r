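# Shared fixture builders.  Everything is generated in code; the heavier
# phantom-suite pipeline report is memoized so several test files can
# share one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# uniform image on a small grid
tiny_image <- function(value = 1, dim = c(10, 10, 10),
                       spacing = c(1, 1, 1), unit = "1") {
  voxel_image(array(value, dim), spacing = spacing, unit = unit)
}

# cuboid mask given 1-based index ranges
box_mask <- function(dim, i, j, k, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
  v <- array(FALSE, dim)
  v[i, j, k] <- TRUE
  voi_mask(v, spacing = spacing, origin = origin)
}

# noiseless blurred single-sphere phantom (warm or cold background)
blurred_sphere <- function(volume_cm3, warm = TRUE, tbr = 5, fwhm = 5,
                           noise_cov = 0) {
  spec <- phantom_spec(
    list(lesion_spec(volume_cm3, c(0, 0, 0), tbr = if (warm) tbr else 1)),
    liver_volume_cm3 = if (warm) 1200 else NA,
    total_activity_gbq = if (warm) 3 else 0.625,
    noise = noise_spec(background_cov = noise_cov), seed = 1)
  tr <- build_truth(spec)
  pet <- apply_psf(tr$activity, fwhm)
  if (noise_cov > 0)
    pet <- add_noise(pet, spec$noise, seed = 1,
                     reference = tr$background_mask)
  list(pet = pet, ms = tr$truth_masks[[1]], truth = tr)
}

phantom_report_seed1 <- function() {
  cached("phantom_report_seed1", run_phantom_acceptance(seed = 1))
}

# O(n^2) brute-force symmetric mean surface distance oracle
mda_bruteforce <- function(a, b) {
  pa <- ysegdose:::voxel_centers_mm(a, which(boundary_voxels(a)$values))
  pb <- ysegdose:::voxel_centers_mm(b, which(boundary_voxels(b)$values))
  d_ab <- mean(apply(pa, 1, function(p)
    sqrt(min(colSums((t(pb) - p)^2)))))
  d_ba <- mean(apply(pb, 1, function(p)
    sqrt(min(colSums((t(pa) - p)^2)))))
  (d_ab + d_ba) / 2
}
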