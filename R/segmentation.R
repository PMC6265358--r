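#' Gradient-segmentation initialization and parameters
#'
#' `gradient_init()` describes the operator interaction of the
#' ray/ellipsoid-initialized gradient method: a seed point at the lesion
#' center plus six signed axis ray lengths (+x, -x, +y, -y, +z, -z, mm)
#' dragged toward the lesion boundary.  The eight ellipsoid octants with
#' semi-axes taken from the matching signed rays, inflated by `margin`,
#' bound the edge search.
#'
#' @param seed Seed point, mm (3-vector).
#' @param ray_lengths Six positive ray lengths, mm, in the order
#'   +x, -x, +y, -y, +z, -z.
#' @param margin Factor >= 1 applied to the rays to form the search
#'   bound, so the true edge remains searchable when the rays are
#'   under-drawn.
#' @return A `gradient_init` object.
#' @export
gradient_init <- function(seed, ray_lengths, margin = 1.3) {
  seed <- as.numeric(seed)
  ray_lengths <- as.numeric(ray_lengths)
  stopifnot(length(seed) == 3L, length(ray_lengths) == 6L)
  if (any(!is.finite(ray_lengths)) || any(ray_lengths <= 0))
    stop("ray lengths must be positive", call. = FALSE)
  if (!is.finite(margin) || margin < 1)
    stop("`margin` must be >= 1", call. = FALSE)
  structure(list(seed = seed, ray_lengths = ray_lengths, margin = margin),
            class = "gradient_init")
}

#' @rdname gradient_init
#' @param smooth_sigma Pre-smoothing Gaussian sigma for gradient
#'   computation, in voxels.
#' @param n_directions Number of search rays on the sphere (snapped up
#'   to the nearest subdivided-icosahedron count: 42, 162, 642, ...).
#' @param step Ray sampling step, mm; must not exceed the smallest
#'   voxel spacing.
#' @param r_min Minimum admissible radius, mm; default one voxel
#'   diagonal of the image the segmentation runs on.
#' @param profile_sigma_mm Gaussian sigma, mm, of the 1D smoothing of
#'   each sampled ray profile before differentiation.  Smoothing a
#'   blurred step edge *along the ray* widens the transition without
#'   moving its inflection, so this suppresses noise-induced spurious
#'   edges at essentially no localization cost (unlike extra 3D
#'   smoothing, whose curvature interaction biases small lesions
#'   inward).
#' @param regularization_iters Passes of angular neighbor-median
#'   smoothing of the per-ray radii.
#' @param refine_iters Maximum self-reinitialization passes: after the
#'   surface is voxelized, the seed and rays are re-derived from the
#'   detected mask and the search repeated until the mask stops
#'   changing — mirroring the interactive tool, whose displayed rays
#'   snap to its own gradient-determined edge.  Because the re-derived
#'   initialization is quantized to the voxel grid, runs started from
#'   slightly different operator inputs converge to the same fixed
#'   point, which is what makes the repeat segmentation nearly
#'   identical.
#' @param jitter_sigma Standard deviation, mm, of the Gaussian
#'   perturbation of seed and rays used for repeatability studies; 0
#'   disables jitter.
#' @export
gradient_params <- function(smooth_sigma = 0.5, n_directions = 642,
                            step = 1.0, r_min = NULL, profile_sigma_mm = 1.5,
                            regularization_iters = 2, refine_iters = 6,
                            jitter_sigma = 0) {
  if (n_directions < 42) stop("`n_directions` must be >= 42", call. = FALSE)
  stopifnot(smooth_sigma >= 0, step > 0, regularization_iters >= 0,
            refine_iters >= 0, jitter_sigma >= 0, profile_sigma_mm >= 0)
  structure(list(smooth_sigma = smooth_sigma, n_directions = n_directions,
                 step = step, r_min = r_min,
                 profile_sigma_mm = profile_sigma_mm,
                 regularization_iters = regularization_iters,
                 refine_iters = refine_iters, jitter_sigma = jitter_sigma),
            class = "gradient_params")
}

#' Initialize the gradient method from a morphologic mask
#'
#' Emulates the operator: the seed is placed at the mask centroid in the
#' axial slice of maximum mask area (snapped to the nearest in-mask
#' voxel when the centroid falls outside, as for rim lesions); the
#' in-plane rays are the distances from the seed to the mask boundary
#' along +/-x and +/-y within that slice, and the +/-z rays the
#' through-plane distances.
#'
#' @param ms A non-empty [voi_mask] (the morphologic segmentation).
#' @param margin Search-bound inflation factor, passed to
#'   [gradient_init()].
#' @param slice Axial slice holding the seed: `"max_area"` (the plane
#'   of maximum morphological extent, as the operator would pick) or
#'   `"centroid"` (the slice nearest the mask z-centroid, which is
#'   stabler under single-voxel mask changes and is what the internal
#'   self-reinitialization passes use).
#' @return A [gradient_init()].
#' @export
init_from_mask <- function(ms, margin = 1.3, slice = c("max_area", "centroid")) {
  stopifnot(inherits(ms, "voi_mask"))
  slice <- match.arg(slice)
  v <- ms$values
  if (!any(v)) stop("init_from_mask: mask is empty", call. = FALSE)
  d <- dim(v)
  idx <- which(v)
  ijk <- arrayInd(idx, d)
  slice_area <- tabulate(ijk[, 3], nbins = d[3])
  k0 <- if (slice == "max_area") {
    # ties between equal-area slices broken toward the z-centroid
    cand <- which(slice_area == max(slice_area))
    cand[which.min(abs(cand - mean(ijk[, 3])))]
  } else max(1L, min(d[3], round(mean(ijk[, 3]))))
  if (slice_area[k0] == 0L) k0 <- which.max(slice_area)
  in_slice <- ijk[ijk[, 3] == k0, , drop = FALSE]
  ij <- colMeans(in_slice[, 1:2, drop = FALSE])
  i0 <- round(ij[1]); j0 <- round(ij[2])
  if (!v[i0, j0, k0]) {
    # centroid outside the mask (e.g. rim lesion): snap to the nearest
    # in-mask voxel of the slice
    d2 <- (in_slice[, 1] - ij[1])^2 * ms$spacing[1]^2 +
          (in_slice[, 2] - ij[2])^2 * ms$spacing[2]^2
    nearest <- in_slice[which.min(d2), ]
    i0 <- nearest[1]; j0 <- nearest[2]
  }
  init_at_voxel(ms, c(i0, j0, k0), margin)
}

# build a gradient_init whose seed is the given in-mask voxel and whose
# rays are the axis distances to the mask boundary from there
init_at_voxel <- function(ms, ijk, margin = 1.3) {
  v <- ms$values
  d <- dim(v)
  i0 <- ijk[1]; j0 <- ijk[2]; k0 <- ijk[3]
  seed <- ms$origin + (c(i0, j0, k0) - 1) * ms$spacing
  walk <- function(axis, dir) {
    pos <- c(i0, j0, k0)
    steps <- 0L
    repeat {
      nxt <- pos
      nxt[axis] <- nxt[axis] + dir
      if (nxt[axis] < 1L || nxt[axis] > d[axis] ||
          !v[nxt[1], nxt[2], nxt[3]]) break
      pos <- nxt
      steps <- steps + 1L
    }
    (steps + 0.5) * ms$spacing[axis]
  }
  rays <- c(walk(1, +1L), walk(1, -1L), walk(2, +1L), walk(2, -1L),
            walk(3, +1L), walk(3, -1L))
  gradient_init(seed, rays, margin = margin)
}

# trilinear interpolation of image values at mm points; NA outside grid
trilinear_sample <- function(values, spacing, origin, pts) {
  d <- dim(values)
  u <- sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`) + 1
  i0 <- floor(u)
  fr <- u - i0
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] &
        i0[, 2] >= 1 & i0[, 2] < d[2] &
        i0[, 3] >= 1 & i0[, 3] < d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  lin <- function(di, dj, dk)
    values[cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)]
  w000 <- (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3])
  w100 <- fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3])
  w010 <- (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3])
  w110 <- fr[, 1] * fr[, 2] * (1 - fr[, 3])
  w001 <- (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3]
  w101 <- fr[, 1] * (1 - fr[, 2]) * fr[, 3]
  w011 <- (1 - fr[, 1]) * fr[, 2] * fr[, 3]
  w111 <- fr[, 1] * fr[, 2] * fr[, 3]
  out[ok] <- w000 * lin(0, 0, 0) + w100 * lin(1, 0, 0) +
    w010 * lin(0, 1, 0) + w110 * lin(1, 1, 0) +
    w001 * lin(0, 0, 1) + w101 * lin(1, 0, 1) +
    w011 * lin(0, 1, 1) + w111 * lin(1, 1, 1)
  out
}

# per-direction search-bound radius from the octant ellipsoid
octant_bound <- function(dirs, rays, margin, margin_add = 0) {
  sa <- pmax(rays * margin, rays + margin_add)
  ax <- ifelse(dirs[, 1] >= 0, sa[1], sa[2])
  ay <- ifelse(dirs[, 2] >= 0, sa[3], sa[4])
  az <- ifelse(dirs[, 3] >= 0, sa[5], sa[6])
  1 / sqrt((dirs[, 1] / ax)^2 + (dirs[, 2] / ay)^2 + (dirs[, 3] / az)^2)
}

#' Gradient-based (edge-detection) lesion segmentation
#'
#' Segments one hot lesion from an activity image by directional edge
#' detection: the image is pre-smoothed, dense near-uniform rays are cast
#' from the seed, the radius along each ray is set where the outward
#' directional derivative is most negative (the falling edge) within the
#' octant-ellipsoid search bound, the radii are regularized by angular
#' neighbor-median smoothing, and the resulting star-convex surface is
#' voxelized by a center-inside test.  The gradient location is invariant
#' to positive rescaling of the image.
#'
#' @param img A [voxel_image] (activity concentration or unitless).
#' @param init A [gradient_init()], e.g. from [init_from_mask()].
#' @param params A [gradient_params()].
#' @param seed RNG seed used only when `params$jitter_sigma > 0` to
#'   perturb the seed point and ray lengths (repeatability studies).
#' @return A [voi_mask] containing the seed voxel.
#' @export
gradient_segment <- function(img, init, params = gradient_params(),
                             seed = NULL) {
  stopifnot(inherits(img, "voxel_image"), inherits(init, "gradient_init"),
            inherits(params, "gradient_params"))
  spacing <- img$spacing
  if (params$step > min(spacing) + 1e-9)
    stop("`step` must not exceed the smallest voxel spacing", call. = FALSE)
  seed_pt <- init$seed
  rays <- init$ray_lengths
  if (params$jitter_sigma > 0) {
    jit <- with_seed(seed, list(s = stats::rnorm(3, 0, params$jitter_sigma),
                                r = stats::rnorm(6, 0, params$jitter_sigma)))
    seed_pt <- seed_pt + jit$s
    rays <- pmax(rays + jit$r, min(spacing))
  }
  d <- dim(img$values)
  lo <- img$origin
  hi <- img$origin + (d - 1) * spacing
  if (any(seed_pt < lo) || any(seed_pt > hi))
    stop("seed point lies outside the image grid", call. = FALSE)

  r_min <- if (is.null(params$r_min)) sqrt(sum(spacing^2)) else params$r_min
  sm <- gaussian_blur_vox(img$values, rep(params$smooth_sigma, 3))
  ico <- icosphere_directions(params$n_directions)

  mask <- gradient_segment_once(img, sm, ico, seed_pt, rays, init$margin,
                                params, r_min)
  # snap the initialization to the detected edge (quantized to the voxel
  # grid) and repeat until the mask is a fixed point (see
  # `refine_iters`); the additive escape band lets the search recover
  # the true edge even when a badly under-drawn initialization clipped
  # the first-pass surface.  A 2-cycle is resolved canonically (larger
  # mask) so that runs entering the cycle at different phases agree.
  prev <- NULL
  for (it in seq_len(params$refine_iters)) {
    init2 <- init_from_mask(mask, margin = init$margin, slice = "centroid")
    # a refinement pass that finds no edges must not discard the surface
    # already found; keep the previous mask instead
    mask2 <- tryCatch(
      gradient_segment_once(img, sm, ico, init2$seed,
                            init2$ray_lengths, init2$margin,
                            params, r_min,
                            margin_add = 2 * max(img$spacing)),
      error = function(e) NULL)
    if (is.null(mask2)) break
    if (identical(mask2$values, mask$values)) {
      mask <- mask2
      break
    }
    if (!is.null(prev) && identical(mask2$values, prev$values)) {
      mask <- if (sum(mask2$values) >= sum(mask$values)) mask2 else mask
      break
    }
    prev <- mask
    mask <- mask2
  }
  mask
}

gradient_segment_once <- function(img, sm, ico, seed_pt, rays, margin,
                                  params, r_min, margin_add = 0) {
  spacing <- img$spacing
  dirs <- ico$directions
  nd <- nrow(dirs)
  bound <- octant_bound(dirs, rays, margin, margin_add)
  step <- params$step
  ts <- seq(step, max(bound) + step, by = step)
  nt <- length(ts)
  pts <- matrix(0, nd * nt, 3)
  for (a in 1:3)
    pts[, a] <- seed_pt[a] + rep(dirs[, a], times = nt) *
      rep(ts, each = nd)
  S <- matrix(trilinear_sample(sm, spacing, img$origin, pts), nd, nt)

  if (params$profile_sigma_mm > 0 && nt >= 3) {
    # NA-aware 1D smoothing of each profile along the ray
    k <- gauss_kernel_1d(params$profile_sigma_mm / step)
    h <- (length(k) - 1L) / 2L
    K <- matrix(0, nt, nt)
    for (off in -h:h) {
      i <- seq_len(nt); j <- i + off
      okk <- j >= 1L & j <= nt
      K[cbind(i[okk], j[okk])] <- k[off + h + 1L]
    }
    W <- (!is.na(S)) * 1
    Z <- S; Z[is.na(Z)] <- 0
    num <- Z %*% t(K)
    den <- W %*% t(K)
    S <- ifelse(den > 0.5, num / den, NA_real_)
  }

  # central-difference outward derivative along each ray
  D <- matrix(NA_real_, nd, nt)
  if (nt >= 3)
    D[, 2:(nt - 1)] <- (S[, 3:nt] - S[, 1:(nt - 2)]) / (2 * step)
  # the lower search limit is capped per direction at 55% of the bound
  # so that short initializations (small lesions) keep a usable window
  r_lo <- pmin(r_min, 0.55 * bound)
  tmat <- matrix(rep(ts, each = nd), nd, nt)
  valid <- !is.na(D) & tmat >= r_lo & tmat <= bound
  Dv <- ifelse(valid & D < 0, D, Inf)
  jstar <- max.col(-Dv, ties.method = "first")
  failed <- !is.finite(Dv[cbind(seq_len(nd), jstar)])
  # a flat ray carries no edge evidence at all; rays that merely lack a
  # falling edge (e.g. rising toward a hotter region) are filled from
  # their angular neighbors below, but a mostly-flat image is an error
  Sv <- ifelse(valid, S[, seq_len(nt)], NA_real_)
  rng <- apply(Sv, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    diff(range(x))
  })
  scale_ref <- max(abs(S), na.rm = TRUE)
  flat <- (rng <= 1e-9 * max(scale_ref, 1e-300)) | rowSums(valid) == 0
  if (mean(flat) > 0.2 || all(failed))
    stop("degenerate input: no falling edge found on more than 20% of rays",
         call. = FALSE)
  radius <- ts[jstar]
  # sub-step refinement: parabola through the derivative triplet
  refine <- which(!failed & jstar > 1 & jstar < nt)
  if (length(refine)) {
    jm <- jstar[refine]
    dm1 <- D[cbind(refine, jm - 1L)]
    d0 <- D[cbind(refine, jm)]
    dp1 <- D[cbind(refine, jm + 1L)]
    den <- dm1 - 2 * d0 + dp1
    off <- ifelse(is.finite(den) & abs(den) > 1e-12,
                  0.5 * (dm1 - dp1) / den, 0)
    off[is.na(off)] <- 0
    radius[refine] <- radius[refine] + step * pmax(pmin(off, 1), -1)
  }
  radius[failed] <- NA_real_
  radius <- pmin(pmax(radius, r_lo), bound)
  if (anyNA(radius))
    radius[is.na(radius)] <- stats::median(radius, na.rm = TRUE)
  for (it in seq_len(params$regularization_iters))
    radius <- vapply(seq_len(nd), function(i)
      stats::median(c(radius[i], radius[ico$neighbors[[i]]])),
      numeric(1))

  voxelize_star(radius, dirs, seed_pt, img)
}

# voxelize a star-convex surface r(direction) about `seed_pt` by testing
# voxel centers; the radius at an arbitrary direction is an
# inverse-angle-weighted blend of the three nearest mesh directions
voxelize_star <- function(radius, dirs, seed_pt, img) {
  d <- dim(img$values)
  spacing <- img$spacing
  origin <- img$origin
  rmax <- max(radius) + max(spacing)
  i_lo <- pmax(floor((seed_pt - rmax - origin) / spacing) + 1, 1)
  i_hi <- pmin(ceiling((seed_pt + rmax - origin) / spacing) + 1, d)
  xs <- origin[1] + (seq(i_lo[1], i_hi[1]) - 1) * spacing[1] - seed_pt[1]
  ys <- origin[2] + (seq(i_lo[2], i_hi[2]) - 1) * spacing[2] - seed_pt[2]
  zs <- origin[3] + (seq(i_lo[3], i_hi[3]) - 1) * spacing[3] - seed_pt[3]
  nb <- c(length(xs), length(ys), length(zs))
  rel <- cbind(rep(xs, times = nb[2] * nb[3]),
               rep(rep(ys, each = nb[1]), times = nb[3]),
               rep(zs, each = nb[1] * nb[2]))
  rho <- sqrt(rowSums(rel^2))
  inside <- logical(nrow(rel))
  inside[rho < 1e-9] <- TRUE
  todo <- which(rho >= 1e-9 & rho <= max(radius))
  chunk <- 20000L
  tdirs <- t(dirs)
  for (s in seq(1, length(todo), by = chunk)) {
    ii <- todo[s:min(s + chunk - 1L, length(todo))]
    U <- rel[ii, , drop = FALSE] / rho[ii]
    M <- U %*% tdirs
    r_int <- numeric(length(ii))
    wsum <- numeric(length(ii))
    Mw <- M
    for (k in 1:3) {
      j <- max.col(Mw, ties.method = "first")
      sel <- cbind(seq_along(ii), j)
      ang <- acos(pmin(pmax(Mw[sel], -1), 1))
      w <- 1 / (ang + 1e-3)
      r_int <- r_int + w * radius[j]
      wsum <- wsum + w
      Mw[sel] <- -Inf
    }
    inside[ii] <- rho[ii] <= r_int / wsum
  }
  mask <- array(FALSE, d)
  mask[seq(i_lo[1], i_hi[1]), seq(i_lo[2], i_hi[2]),
       seq(i_lo[3], i_hi[3])] <- array(inside, nb)
  voi_mask(mask, spacing, origin)
}

#' Percent-of-maximum threshold segmentation
#'
#' Thresholds the image at `pct` percent of its maximum within a
#' bounding mask and keeps the 26-connected component of the
#' supra-threshold voxels that contains the in-bound maximum.
#'
#' @param img A [voxel_image].
#' @param bound A non-empty [voi_mask] bounding the search (e.g. a
#'   sphere with ~1 cm margin around the target); see
#'   [threshold_bound()].
#' @param pct Threshold as percent of the in-bound maximum, in (0, 100).
#' @return A [voi_mask].
#' @export
threshold_segment <- function(img, bound, pct) {
  stopifnot(inherits(img, "voxel_image"), inherits(bound, "voi_mask"))
  stop_if_grid_mismatch(img, bound, "image and bound")
  if (!any(bound$values)) stop("threshold bound is empty", call. = FALSE)
  if (!is.finite(pct) || pct <= 0 || pct >= 100)
    stop("`pct` must lie strictly between 0 and 100", call. = FALSE)
  v <- img$values
  inb <- which(bound$values)
  mx_idx <- inb[which.max(v[inb])]
  thr <- pct / 100 * v[mx_idx]
  cand <- (v >= thr) & bound$values
  comp <- flood_fill26(cand, mx_idx)
  voi_mask(comp, img$spacing, img$origin)
}

# 26-connected component of `cand` containing linear index `start`
flood_fill26 <- function(cand, start) {
  d <- dim(cand)
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  visited <- array(FALSE, d)
  visited[start] <- TRUE
  frontier <- matrix(arrayInd(start, d), ncol = 3)
  while (nrow(frontier)) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o)
      sweep(frontier, 2, offsets[o, ], `+`)))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    keep <- cand[lin] & !visited[lin]
    lin <- unique(lin[keep])
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  visited
}

#' @rdname threshold_segment
#' @param ms The morphologic mask around which the bounding sphere is
#'   placed: radius = equivalent-sphere radius of `ms` plus
#'   `margin_mm`.
#' @param margin_mm Margin added to the equivalent-sphere radius, mm.
#' @export
threshold_bound <- function(ms, margin_mm = 10) {
  stopifnot(inherits(ms, "voi_mask"))
  if (!any(ms$values)) stop("mask is empty", call. = FALSE)
  idx <- which(ms$values)
  ctr <- colMeans(voxel_centers_mm(ms, idx))
  r_eq <- (3 * volume_cm3(ms) * 1000 / (4 * pi))^(1 / 3)
  voi_mask(rasterize_ellipsoid(dim(ms$values), ms$spacing, ms$origin,
                               ctr, rep(r_eq + margin_mm, 3)),
           ms$spacing, ms$origin)
}

#' @rdname threshold_segment
#' @param target_volume_cm3 Volume the threshold should reproduce, cm^3.
#' @param pct_grid Candidate thresholds scanned, percent.
#' @return [optimal_threshold()] returns the percent minimizing the
#'   absolute volume error (ties broken toward the lower percent).
#' @export
optimal_threshold <- function(img, bound, target_volume_cm3,
                              pct_grid = seq(1, 99, by = 0.5)) {
  stopifnot(target_volume_cm3 > 0)
  vols <- vapply(pct_grid, function(p)
    volume_cm3(threshold_segment(img, bound, p)), numeric(1))
  pct_grid[which.min(abs(vols - target_volume_cm3))]
}
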