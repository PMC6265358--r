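#' Dose-volume histogram of a masked dose map
#'
#' @param dose A [voxel_image] in Gy.
#' @param mask A non-empty [voi_mask] on the same grid.
#' @return An object of class `dvh`: the ascending voxel-dose sample and
#'   the (uniform) voxel volume in cm^3.
#' @export
compute_dvh <- function(dose, mask) {
  stopifnot(inherits(dose, "voxel_image"), inherits(mask, "voi_mask"))
  stop_if_grid_mismatch(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("compute_dvh: mask is empty", call. = FALSE)
  structure(list(doses = sort(dose$values[mask$values]),
                 voxel_volume_cm3 = voxel_volume_cm3(mask)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels (%.4g cm^3), dose %.4g-%.4g Gy, mean %.4g Gy\n",
              length(x$doses), length(x$doses) * x$voxel_volume_cm3,
              min(x$doses), max(x$doses), mean(x$doses)))
  invisible(x)
}

#' Dose-volume percentile Dq
#'
#' `Dq` is the minimum dose received by the hottest `q` percent of the
#' volume, i.e. the empirical quantile of the voxel-dose sample at
#' probability `1 - q/100`, with linear interpolation between order
#' statistics at plotting positions `(i - 1)/(n - 1)`.
#'
#' @param dvh A [compute_dvh()] result.
#' @param q Volume percentage in (0, 100); `q = 90` gives D90.
#' @return Dose in Gy.
#' @export
dvh_percentile <- function(dvh, q) {
  stopifnot(inherits(dvh, "dvh"), q > 0, q < 100)
  unname(stats::quantile(dvh$doses, probs = 1 - q / 100, type = 7))
}

#' Radiobiology parameters for BED and EUD
#'
#' Defaults: tumor radiosensitivity ratio alpha/beta 10 Gy, yttrium-90
#' physical decay constant 0.0108 per hour, cell repair constant 0.462
#' per hour, and alpha 0.004 per Gy for the equivalent-uniform-dose
#' summaries.
#'
#' @param alpha_beta alpha/beta ratio, Gy.
#' @param lambda_phys Physical decay constant, 1/h.
#' @param mu_repair Sublethal-damage repair constant, 1/h.
#' @param alpha Radiosensitivity for EUD/EUBED, 1/Gy.
#' @export
radiobiology_params <- function(alpha_beta = 10, lambda_phys = 0.0108,
                                mu_repair = 0.462, alpha = 0.004) {
  stopifnot(alpha_beta > 0, lambda_phys > 0, mu_repair > 0, alpha > 0)
  structure(list(alpha_beta = alpha_beta, lambda_phys = lambda_phys,
                 mu_repair = mu_repair, alpha = alpha),
            class = "radiobiology_params")
}

#' Biological effective dose of a permanently trapped emitter
#'
#' Linear-quadratic BED for an exponentially decaying dose rate with no
#' retreatment: `BED = D + D^2 / (alpha/beta) * lambda / (lambda + mu)`.
#' The transform is monotone increasing, so BED quantiles equal the
#' transform of the dose quantiles.
#'
#' @param d Absorbed dose, Gy (vectorized, non-negative).
#' @param p A [radiobiology_params()].
#' @return BED in Gy.
#' @export
bed_transform <- function(d, p = radiobiology_params()) {
  stopifnot(inherits(p, "radiobiology_params"))
  if (any(d < 0)) stop("dose must be non-negative", call. = FALSE)
  d + d^2 / p$alpha_beta * p$lambda_phys / (p$lambda_phys + p$mu_repair)
}

# equivalent uniform dose of a voxel sample
eud_of <- function(d, alpha) -log(mean(exp(-alpha * d))) / alpha

#' Summary dose metrics of a DVH
#'
#' Mean, D70 and D90 of the absorbed dose; the same three metrics of the
#' per-voxel BED-transformed sample; equivalent uniform dose
#' `EUD = -(1/alpha) log mean exp(-alpha D)` and its BED counterpart
#' (EUBED); and the VOI volume.
#'
#' @param dvh A [compute_dvh()] result.
#' @param p A [radiobiology_params()].
#' @return An object of class `dose_metrics` (a named list).
#' @export
dose_metrics <- function(dvh, p = radiobiology_params()) {
  stopifnot(inherits(dvh, "dvh"))
  d <- dvh$doses
  bed <- bed_transform(d, p)
  bdvh <- structure(list(doses = sort(bed),
                         voxel_volume_cm3 = dvh$voxel_volume_cm3),
                    class = "dvh")
  structure(list(
    mean_Gy = mean(d),
    d70_Gy = dvh_percentile(dvh, 70),
    d90_Gy = dvh_percentile(dvh, 90),
    bed_mean_Gy = mean(bed),
    bed70_Gy = dvh_percentile(bdvh, 70),
    bed90_Gy = dvh_percentile(bdvh, 90),
    eud_Gy = eud_of(d, p$alpha),
    eubed_Gy = eud_of(bed, p$alpha),
    volume_cm3 = length(d) * dvh$voxel_volume_cm3),
    class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("<dose_metrics> %.4g cm^3 | mean %.4g, D70 %.4g, D90 %.4g Gy | BED mean %.4g, BED70 %.4g, BED90 %.4g Gy\n",
              x$volume_cm3, x$mean_Gy, x$d70_Gy, x$d90_Gy,
              x$bed_mean_Gy, x$bed70_Gy, x$bed90_Gy))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: 1 is perfect agreement, 0 no
#' spatial overlap.  Two empty masks are defined to agree perfectly
#' (with a warning) so batch runs stay total.
#'
#' @param a,b [voi_mask]s on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Mean distance to agreement (symmetric mean surface distance)
#'
#' Extracts the boundary voxels of both masks ([boundary_voxels()]),
#' averages over each surface the Euclidean distance (mm, anisotropic
#' spacing, between voxel centers) to the nearest voxel of the other
#' surface, and returns the mean of the two directed averages.
#'
#' @param a,b Non-empty [voi_mask]s on the same grid.
#' @return MDA in mm; 0 for identical masks.
#' @export
mda <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"))
  stop_if_grid_mismatch(a, b, "masks")
  if (!any(a$values) || !any(b$values))
    stop("mda: masks must be non-empty", call. = FALSE)
  pa <- voxel_centers_mm(a, which(boundary_voxels(a)$values))
  pb <- voxel_centers_mm(b, which(boundary_voxels(b)$values))
  (mean(nearest_dists(pa, pb)) + mean(nearest_dists(pb, pa))) / 2
}

# for each row of `from`, distance to the nearest row of `to` (mm)
nearest_dists <- function(from, to, chunk = 2000L) {
  n2 <- rowSums(to^2)
  out <- numeric(nrow(from))
  for (s in seq(1, nrow(from), by = chunk)) {
    ii <- s:min(s + chunk - 1L, nrow(from))
    fa <- from[ii, , drop = FALSE]
    d2 <- outer(rowSums(fa^2), n2, `+`) - 2 * fa %*% t(to)
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Spatial concordance of two segmentations
#'
#' @param a,b [voi_mask]s on the same grid (e.g. PET-based vs
#'   morphologic).
#' @return A `concordance_result` list: `dsc`, `mda_mm`,
#'   `delta_volume_cm3` (`b - a`) and `delta_volume_pct` (relative to
#'   `a`).
#' @export
concordance <- function(a, b) {
  va <- volume_cm3(a); vb <- volume_cm3(b)
  structure(list(dsc = dice(a, b), mda_mm = mda(a, b),
                 delta_volume_cm3 = vb - va,
                 delta_volume_pct = (vb - va) / va * 100),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> DSC %.3f, MDA %.2f mm, dV %+.2f cm^3 (%+.1f%%)\n",
              x$dsc, x$mda_mm, x$delta_volume_cm3, x$delta_volume_pct))
  invisible(x)
}

#' Cumulative DVH curve for export
#'
#' @param dvh A [compute_dvh()] result.
#' @param n Number of dose points.
#' @return Data frame with `dose_Gy` and `volume_fraction` (fraction of
#'   the VOI receiving at least that dose).
#' @export
dvh_curve <- function(dvh, n = 200) {
  stopifnot(inherits(dvh, "dvh"))
  grid <- seq(0, max(dvh$doses), length.out = n)
  data.frame(dose_Gy = grid,
             volume_fraction = vapply(grid, function(g)
               mean(dvh$doses >= g), numeric(1)))
}
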