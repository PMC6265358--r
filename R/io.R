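#' Read and write voxel images
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) is the canonical on-disk format; NRRD
#' (`.nrrd`, attached header) is additionally accepted on read.  Voxel
#' spacing is stored in the NIfTI `pixdim` field and the origin in the
#' sform/qform translation.  Masks are stored as `uint8` 0/1 volumes and
#' can be re-read with [read_mask()].
#'
#' @param path File path.  The extension selects the format.
#' @param unit Unit label to attach to the returned image (the formats
#'   themselves do not carry one).
#' @return [read_image()] returns a [voxel_image]; [read_mask()] a
#'   [voi_mask].
#' @export
read_image <- function(path, unit = "1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    g <- read_nrrd(path)
  } else {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
      vals <- array(vals, dim(vals)[1:3])
    if (length(dim(vals)) != 3L)
      stop("format error: expected a 3D payload, field `dim` is ",
           paste(dim(vals), collapse = "x"), call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("format error: missing or non-positive spacing in field `pixdim`",
           call. = FALSE)
    xf <- RNifti::xform(img)
    g <- list(values = vals, spacing = abs(as.numeric(sp)),
              origin = as.numeric(xf[1:3, 4]))
  }
  voxel_image(g$values, spacing = g$spacing, origin = g$origin, unit = unit)
}

#' @rdname read_image
#' @param img A [voxel_image] (or, for [write_mask()], a [voi_mask]).
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  write_nifti_grid(img$values, img$spacing, img$origin, path,
                   datatype = "double")
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (!all(img$values %in% c(0, 1)))
    stop("format error: mask file contains values other than 0/1",
         call. = FALSE)
  voi_mask(img$values != 0, spacing = img$spacing, origin = img$origin)
}

#' @rdname read_image
#' @param mask A [voi_mask].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  write_nifti_grid(array(as.numeric(mask$values), dim(mask$values)),
                   mask$spacing, mask$origin, path, datatype = "uint8")
  invisible(path)
}

write_nifti_grid <- function(vals, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
}

## minimal NRRD reader (attached header; raw / gzip / ascii encodings) --

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic))
    stop("format error: not an NRRD file (bad magic)", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  need <- function(k) {
    if (is.null(fields[[k]]))
      stop("format error: NRRD header missing field `", k, "`", call. = FALSE)
    fields[[k]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L)
    stop("format error: expected a 3D payload, field `dimension` is ",
         ndim, call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  spacing <- nrrd_spacing(fields)
  origin <- nrrd_origin(fields)
  type <- tolower(need("type"))
  enc <- tolower(need("encoding"))
  n <- prod(sizes)
  rtype <- switch(type,
    "float" = list(what = "numeric", size = 4L),
    "double" = list(what = "numeric", size = 8L),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L),
    "ushort" = , "uint16" = list(what = "integer", size = 2L),
    "int" = , "int32" = list(what = "integer", size = 4L),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L),
    stop("format error: unsupported NRRD type `", type, "`", call. = FALSE))
  endian <- if (!is.null(fields[["endian"]]) &&
                tolower(fields[["endian"]]) == "big") "big" else "little"
  vals <- switch(enc,
    "raw" = readBin(con, rtype$what, n = n, size = rtype$size,
                    endian = endian,
                    signed = !type %in% c("uchar", "uint8", "unsigned char",
                                          "ushort", "uint16")),
    "gzip" = , "gz" = {
      payload <- readBin(con, "raw", n = file.size(path))
      gcon <- gzcon(rawConnection(payload))
      on.exit(close(gcon), add = TRUE)
      readBin(gcon, rtype$what, n = n, size = rtype$size, endian = endian)
    },
    "ascii" = , "text" = , "txt" =
      as.numeric(scan(con, what = "character", n = n, quiet = TRUE)),
    stop("format error: unsupported NRRD encoding `", enc, "`",
         call. = FALSE))
  if (length(vals) != n)
    stop("format error: NRRD payload truncated (", length(vals), " of ",
         n, " values)", call. = FALSE)
  list(values = array(as.numeric(vals), sizes), spacing = spacing,
       origin = origin)
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]]))
    return(abs(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])))
  sd <- fields[["space directions"]]
  if (is.null(sd))
    stop("format error: NRRD header missing field `spacings`/`space directions`",
         call. = FALSE)
  vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
  sp <- vapply(vecs, function(v) {
    xs <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    sqrt(sum(xs^2))
  }, numeric(1))
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("format error: invalid `space directions` in NRRD header",
         call. = FALSE)
  unname(sp)
}

nrrd_origin <- function(fields) {
  so <- fields[["space origin"]]
  if (is.null(so)) return(c(0, 0, 0))
  as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
}
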