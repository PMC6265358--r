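#' Voxel images and binary masks
#'
#' A `voxel_image` is a 3D scalar grid with anisotropic physical spacing,
#' a physical origin and a unit label; it carries PET activity
#' concentration (Bq/mL) or absorbed dose (Gy).  A `voi_mask` is a binary
#' volume of interest on the same kind of grid.  Voxel index `(i, j, k)`
#' (1-based) maps to the physical *center* `origin + (i - 1, j - 1, k - 1)
#' * spacing` in mm; all distances in the package are between voxel
#' centers.
#'
#' @param values 3D numeric (image) or logical (mask) array.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin Numeric length-3, physical position of the center of
#'   voxel `(1, 1, 1)` in mm.
#' @param unit Unit label, e.g. `"Bq/mL"`, `"Gy"` or `"1"` (unitless).
#' @return `voxel_image()` returns an object of class `voxel_image`;
#'   `voi_mask()` an object of class `voi_mask`.
#' @examples
#' img <- voxel_image(array(1, c(10, 10, 10)), spacing = c(4.07, 4.07, 3))
#' m   <- voi_mask(img$values > 0, spacing = img$spacing, origin = img$origin)
#' volume_cm3(m)
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0), unit = "1") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("image values must be finite (no NA/NaN/Inf)", call. = FALSE)
  values <- array(as.double(values), dim(values))  # drop stray attributes
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = as.character(unit)[1]),
            class = "voxel_image")
}

#' @rdname voxel_image
#' @export
voi_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask `values` must be a 3D array", call. = FALSE)
  if (anyNA(values)) stop("mask values must not contain NA", call. = FALSE)
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1", call. = FALSE)
    values <- array(values != 0, dim(values))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values",
         call. = FALSE)
  values <- array(as.logical(values), dim(values))  # drop stray attributes
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voi_mask")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  cat(sprintf("  range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voi_mask> %d x %d x %d voxels, %d set (%.4g cm^3)\n",
              d[1], d[2], d[3], sum(x$values), volume_cm3(x)))
  invisible(x)
}

## geometry helpers shared across modules ------------------------------

voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

# physical center coordinates of every grid point along one axis (mm)
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$values)[axis]) - 1) * x$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " must share one grid (same shape, spacing and origin)",
         call. = FALSE)
  invisible(TRUE)
}

# mm coordinates (n x 3) of voxel centers for a logical/index selection
voxel_centers_mm <- function(x, which_idx) {
  d <- dim(x$values)
  ijk <- arrayInd(which_idx, d)
  cbind(x$origin[1] + (ijk[, 1] - 1) * x$spacing[1],
        x$origin[2] + (ijk[, 2] - 1) * x$spacing[2],
        x$origin[3] + (ijk[, 3] - 1) * x$spacing[3])
}

#' Mask volume in cubic centimeters
#'
#' @param mask A [voi_mask].
#' @return Number of set voxels times the voxel volume, in cm^3.
#' @examples
#' m <- voi_mask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' volume_cm3(m)  # 1 cm^3
#' @export
volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$values) * voxel_volume_cm3(mask)
}

#' Surface (boundary) voxels of a mask
#'
#' Returns the voxels of `mask` that have at least one 6-connected
#' neighbor outside the mask; the grid border counts as outside.  This
#' is the surface definition used by the mean-distance-to-agreement
#' metric.
#'
#' @param mask A non-empty [voi_mask].
#' @return A [voi_mask] containing only the boundary voxels.
#' @export
boundary_voxels <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  v <- mask$values
  if (!any(v)) stop("boundary_voxels: mask is empty", call. = FALSE)
  interior <- shift_and(v)
  voi_mask(v & !interior, spacing = mask$spacing, origin = mask$origin)
}

# logical AND of the six 6-connected neighbors (FALSE beyond the border):
# TRUE where a voxel is fully interior
shift_and <- function(v) {
  d <- dim(v)
  out <- v
  pad <- function(arr, axis, dir) {
    # neighbor value along `axis` in direction `dir`, FALSE off-grid
    n <- d[axis]
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx
    if (dir > 0) src[[axis]] <- c(2:n, NA) else src[[axis]] <- c(NA, 1:(n - 1))
    res <- array(FALSE, d)
    keep <- !is.na(src[[axis]])
    tgt <- idx
    tgt[[axis]] <- which(keep)
    srcv <- src
    srcv[[axis]] <- src[[axis]][keep]
    res[tgt[[1]], tgt[[2]], tgt[[3]]] <-
      v[srcv[[1]], srcv[[2]], srcv[[3]]]
    res
  }
  for (axis in 1:3) {
    out <- out & pad(v, axis, +1L)
    out <- out & pad(v, axis, -1L)
  }
  out
}

# shift a logical array by one voxel along an axis (vacated plane FALSE);
# used for 1-voxel dilation in lesion placement
shift_logical <- function(v, axis, dir) {
  d <- dim(v)
  n <- d[axis]
  res <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  tgt <- idx; src <- idx
  if (dir > 0) { tgt[[axis]] <- 2:n;       src[[axis]] <- 1:(n - 1) }
  else         { tgt[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  res[tgt[[1]], tgt[[2]], tgt[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  res
}

dilate6 <- function(v) {
  out <- v
  for (axis in 1:3) {
    out <- out | shift_logical(v, axis, +1L)
    out <- out | shift_logical(v, axis, -1L)
  }
  out
}

## seeded RNG that does not disturb the caller's stream ----------------

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# derive a child seed (< 2^31) from a master seed and a stream label
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.numeric(seed) * 1103 + h * 12289 + 49297) %% 2147483629
}
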