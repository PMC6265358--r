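#' Physical constants for yttrium-90 dosimetry
#'
#' Yttrium-90 decays with a 64.1-h half-life (physical decay constant
#' `ln 2 / 64.1 = 0.0108` per hour) emitting beta particles with mean
#' energy 0.9267 MeV.  Microspheres are permanently trapped, so the
#' time-integrated activity is the imaged activity divided by the decay
#' constant.
#'
#' @param half_life_h Half-life, hours.
#' @param mean_energy_mev Mean beta energy per decay, MeV.
#' @param density_g_ml Tissue density, g/mL (1.0 water phantom, 1.06
#'   soft tissue).
#' @return A `physics_constants` list with the derived decay constant
#'   `lambda_phys_per_h`.
#' @export
physics_constants <- function(half_life_h = 64.1, mean_energy_mev = 0.9267,
                              density_g_ml = 1.0) {
  stopifnot(half_life_h > 0, mean_energy_mev > 0, density_g_ml > 0)
  structure(list(half_life_h = half_life_h,
                 lambda_phys_per_h = lambda_from_half_life(half_life_h),
                 mean_energy_mev = mean_energy_mev,
                 density_g_ml = density_g_ml),
            class = "physics_constants")
}

#' @rdname physics_constants
#' @export
lambda_from_half_life <- function(half_life_h) {
  if (!is.numeric(half_life_h) || any(half_life_h <= 0))
    stop("`half_life_h` must be positive", call. = FALSE)
  log(2) / half_life_h
}

MEV_TO_J <- 1.602176634e-13

#' Local-deposition absorbed-dose map
#'
#' Converts an activity-concentration image (Bq/mL) to an absorbed-dose
#' map (Gy) for permanently trapped microspheres under the
#' local-deposition approximation: each voxel's decays deposit all their
#' energy in that voxel, so `D = (C / rho) * Delta / lambda` with
#' `Delta` the mean energy per decay (J) and `lambda` the physical decay
#' constant (1/s).  Total absorbed energy is conserved exactly.
#'
#' @param act A non-negative [voxel_image] in Bq/mL.
#' @param consts A [physics_constants()].
#' @return A [voxel_image] in Gy with attribute `provenance =
#'   "local_deposition"`.
#' @export
activity_to_dose_local <- function(act, consts = physics_constants()) {
  stopifnot(inherits(act, "voxel_image"), inherits(consts, "physics_constants"))
  if (any(act$values < 0))
    stop("activity image contains negative voxels", call. = FALSE)
  lambda_s <- consts$lambda_phys_per_h / 3600
  delta_j <- consts$mean_energy_mev * MEV_TO_J
  rho_kg_ml <- consts$density_g_ml * 1e-3
  dose <- act$values / rho_kg_ml * delta_j / lambda_s
  out <- voxel_image(dose, act$spacing, act$origin, unit = "Gy")
  attr(out, "provenance") <- "local_deposition"
  out
}

#' Dose-kernel convolution refinement
#'
#' Spreads the local-deposition dose with a radially symmetric
#' deposited-energy kernel, bounding the effect of beta transport across
#' voxels.  The kernel is given as a table of `radius_mm` and
#' `energy_fraction_per_mm` (density of deposited-energy fraction per
#' radial mm) that must integrate to 1; it is resampled onto the voxel
#' grid, renormalized to unit sum, and applied by FFT convolution, so
#' total energy is conserved up to the stated tolerance.
#'
#' @param act A [voxel_image] in Bq/mL.
#' @param kernel Data frame with columns `radius_mm` and
#'   `energy_fraction_per_mm`, or a path to such a CSV file.
#' @param consts A [physics_constants()].
#' @return A [voxel_image] in Gy with attribute `provenance = "kernel"`.
#' @export
dose_kernel_convolve <- function(act, kernel, consts = physics_constants()) {
  if (is.character(kernel)) kernel <- utils::read.csv(kernel)
  stopifnot(all(c("radius_mm", "energy_fraction_per_mm") %in% names(kernel)))
  r <- kernel$radius_mm
  f <- kernel$energy_fraction_per_mm
  if (any(f < 0) || any(diff(r) <= 0))
    stop("validation error: kernel radii must increase and fractions be >= 0",
         call. = FALSE)
  total <- sum(diff(r) * (f[-1] + f[-length(f)]) / 2)
  if (abs(total - 1) > 0.02)
    stop(sprintf(
      "validation error: kernel integrates to %.4f, expected 1 (unit deposited-energy fraction)",
      total), call. = FALSE)
  local <- activity_to_dose_local(act, consts)
  rmax <- max(r)
  h <- pmax(ceiling(rmax / act$spacing), 0)
  off <- list(-h[1]:h[1], -h[2]:h[2], -h[3]:h[3])
  dk <- lengths(off)
  rx <- off[[1]] * act$spacing[1]
  ry <- off[[2]] * act$spacing[2]
  rz <- off[[3]] * act$spacing[3]
  rr <- sqrt(outer(outer(rx^2, ry^2, `+`), rz^2, `+`))
  # energy fraction per unit volume at radius rr: f(r) / (4 pi r^2)
  dens <- array(0, dk)
  okr <- rr <= rmax
  fr <- stats::approx(r, f, xout = rr[okr], rule = 2)$y
  dens[okr] <- fr / pmax(4 * pi * rr[okr]^2, 1e-9)
  ctr <- h + 1L
  dens[ctr[1], ctr[2], ctr[3]] <- 0
  # keep a point-deposition share for the sub-voxel radii the table
  # resolves below the grid, then normalize to unit sum
  short <- r <= min(act$spacing) / 2
  w_self <- if (any(short))
    sum(diff(r[short]) * (f[short][-1] + f[short][-sum(short)]) / 2) else 0
  s <- sum(dens) * prod(act$spacing)
  if (s > 0) dens <- dens * (1 - w_self) / s * prod(act$spacing)
  dens[ctr[1], ctr[2], ctr[3]] <- 1 - sum(dens[-((ctr[3] - 1) * dk[1] * dk[2] +
                                                 (ctr[2] - 1) * dk[1] + ctr[1])])
  out <- fft_convolve3(local$values, dens, ctr)
  out <- pmax(out, 0)
  res <- voxel_image(array(out, dim(local$values)), act$spacing, act$origin,
                     unit = "Gy")
  attr(res, "provenance") <- "kernel"
  res
}
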