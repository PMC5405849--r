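#' Construct a volume
#'
#' A volume is a 3D scalar grid indexed `[z, y, x]` (so `dim = c(nz, ny, nx)`)
#' with an optional physical voxel spacing per axis. This axis order is used
#' everywhere in the package.
#'
#' @param data 3D numeric array, `[z, y, x]` order.
#' @param spacing numeric length-3 voxel size per axis `(z, y, x)`; defaults
#'   to isotropic unit voxels.
#' @return An object of class `volume`: a list with elements `data`,
#'   `spacing` and `dtype_info` (the value range of the source data).
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 dtype_info = range(data)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d (z,y,x), spacing %s, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              x$dtype_info[1], x$dtype_info[2]))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Read a 3D volume from MRC or HDF5
#'
#' MRC2014 (`.mrc`, `.map`, `.rec`) and HDF5 (`.h5`, `.hdf5`) files are
#' supported. The returned grid is always `[z, y, x]`. For MRC the
#' `mapc/mapr/maps` header words are honoured, so the file's
#' column/row/section axes are permuted onto `(x, y, z)` before reordering
#' to `(z, y, x)`. For HDF5 the dataset is assumed C-ordered `(z, y, x)`
#' (the convention of h5py-written tomograms); since HDF5 is read
#' column-major from R the dimensions are reversed on read.
#'
#' Non-finite voxels are rejected by default; `na_policy = "median"`
#' replaces them with the median of the finite voxels.
#'
#' @param path file path.
#' @param dataset HDF5 dataset name; if `NULL` the first 3D dataset found
#'   in the file is used. Ignored for MRC.
#' @param na_policy `"error"` or `"median"`.
#' @return A [volume].
#' @export
read_volume <- function(path, dataset = NULL, na_policy = c("error", "median")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  v <- if (ext %in% c("h5", "hdf5")) {
    read_hdf5_volume(path, dataset)
  } else if (ext %in% c("mrc", "map", "rec")) {
    read_mrc(path)
  } else stop("unsupported format: .", ext, " (expected .mrc or .h5/.hdf5)")
  if (!all(is.finite(v$data))) {
    if (na_policy == "error")
      stop("volume contains non-finite values (use na_policy = \"median\")")
    med <- median(v$data[is.finite(v$data)])
    v$data[!is.finite(v$data)] <- med
  }
  v$dtype_info <- range(v$data)
  v
}

read_hdf5_volume <- function(path, dataset = NULL) {
  if (is.null(dataset)) {
    ls <- rhdf5::h5ls(path)
    ds <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
    ndims <- vapply(strsplit(ds$dim, " x "), length, 1L)
    ds <- ds[ndims == 3L, , drop = FALSE]
    if (nrow(ds) == 0L) stop("non-3D dataset: no 3D dataset found in ", path)
    dataset <- paste(sub("^/$", "", ds$group[1]), ds$name[1], sep = "/")
  }
  x <- rhdf5::h5read(path, dataset)
  if (length(dim(x)) != 3L) stop("non-3D dataset: ", dataset)
  # file is (z,y,x) C-order; rhdf5 returns reversed dims -> aperm back
  volume(aperm(x, 3:1))
}

#' Write a volume to MRC or HDF5
#'
#' The inverse of [read_volume()]: HDF5 datasets are written so that a
#' C-order reader sees `(z, y, x)`; MRC files are written in standard axis
#' order (`mapc,mapr,maps = 1,2,3`), mode 2 (float32).
#'
#' @param v a [volume] or 3D array.
#' @param path output path; format chosen by extension.
#' @param dataset HDF5 dataset name.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, dataset = "data") {
  if (!inherits(v, "volume")) v <- volume(as_array3d(v))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(aperm(v$data, 3:1), path, dataset)
    rhdf5::h5closeAll()
  } else if (ext %in% c("mrc", "map", "rec")) {
    write_mrc(v, path)
  } else stop("unsupported format: .", ext)
  invisible(path)
}

# ---- MRC2014 ----------------------------------------------------------------
# 1024-byte header; words 1-3 = n columns/rows/sections (fastest to slowest),
# word 4 = mode, words 8-10 = mx,my,mz, words 11-13 = cell size, words 17-19 =
# mapc,mapr,maps (which of x=1,y=2,z=3 each file axis is), word 24 = extended
# header bytes, byte 212 = machine stamp (0x44 little-endian, 0x11 big-endian).

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("unreadable header: file shorter than 1024 bytes")
  endian <- if (as.integer(hdr_raw[213]) %in% c(0x11, 0x12)) "big" else "little"
  word <- function(i, what = "integer") # 1-based 4-byte word
    readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], what, size = 4L, endian = endian)
  nc <- word(1); nr <- word(2); ns <- word(3)
  mode <- word(4)
  mx <- word(8); my <- word(9); mz <- word(10)
  cella <- c(word(11, "numeric"), word(12, "numeric"), word(13, "numeric"))
  mapc <- word(17); mapr <- word(18); maps <- word(19)
  nsymbt <- word(24)
  if (any(c(nc, nr, ns) <= 0)) stop("unreadable header: non-positive dimensions")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  n <- as.numeric(nc) * nr * ns
  data <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1L, signed = TRUE, endian = endian)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    "6" = as.double(readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian)),
    stop("unsupported MRC mode: ", mode))
  if (length(data) < n) stop("unreadable header: data shorter than header promises")
  a <- array(data, dim = c(nc, nr, ns)) # file order: columns fastest
  axmap <- c(mapc, mapr, maps)
  if (!setequal(axmap, 1:3)) axmap <- 1:3 # tolerate invalid headers
  # output dim j (z,y,x) = file dim holding spatial axis (3,2,1)[j]
  perm <- vapply(c(3L, 2L, 1L), function(ax) which(axmap == ax), 1L)
  spacing <- rep(1, 3)
  mxyz <- c(mx, my, mz)
  if (all(mxyz > 0) && all(cella > 0)) spacing <- (cella / mxyz)[c(3, 2, 1)]
  volume(aperm(a, perm), spacing = spacing)
}

write_mrc <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  d <- dim(v$data) # (nz, ny, nx)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(d[3], d[2], d[1])) # nx, ny, nz as columns/rows/sections
  wi(2)                   # mode 2: float32
  wi(c(0, 0, 0))          # nxstart
  wi(c(d[3], d[2], d[1])) # mx, my, mz
  wf(c(d[3] * v$spacing[3], d[2] * v$spacing[2], d[1] * v$spacing[1]))
  wf(c(90, 90, 90))       # cell angles
  wi(c(1, 2, 3))          # mapc, mapr, maps
  wf(c(min(v$data), max(v$data), mean(v$data)))
  wi(c(0, 0))             # ispg, nsymbt
  writeBin(raw(100), con) # extra words 25-49
  wf(c(0, 0, 0))          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(sd(v$data))
  wi(0)                   # nlabl
  writeBin(raw(800), con) # labels
  writeBin(as.numeric(aperm(v$data, c(3, 2, 1))), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- RoI --------------------------------------------------------------------

#' Region of interest (bounding cuboid)
#'
#' Half-open 0-based voxel index ranges `[min, max)` per axis, matching the
#' package-wide 0-based indexing of region ids.
#'
#' @param zmin,zmax,ymin,ymax,xmin,xmax integer bounds, `0 <= min < max`.
#' @return An object of class `roi`.
#' @export
roi <- function(zmin, zmax, ymin, ymax, xmin, xmax) {
  r <- as.integer(c(zmin, zmax, ymin, ymax, xmin, xmax))
  if (any(is.na(r))) stop("roi bounds must be integers")
  if (r[1] < 0 || r[3] < 0 || r[5] < 0 || r[1] >= r[2] || r[3] >= r[4] || r[5] >= r[6])
    stop("roi requires 0 <= min < max on every axis")
  structure(list(zmin = r[1], zmax = r[2], ymin = r[3], ymax = r[4],
                 xmin = r[5], xmax = r[6]), class = "roi")
}

#' Clip a volume to a region of interest
#'
#' @param v a [volume] or 3D array.
#' @param r an [roi]; must lie within the volume bounds.
#' @return A [volume] of shape `(zmax-zmin, ymax-ymin, xmax-xmin)` with the
#'   values copied verbatim.
#' @export
clip_to_roi <- function(v, r) {
  spacing <- if (inherits(v, "volume")) v$spacing else c(1, 1, 1)
  a <- as_array3d(v)
  stopifnot(inherits(r, "roi"))
  d <- dim(a)
  if (r$zmax > d[1] || r$ymax > d[2] || r$xmax > d[3])
    stop("roi out of bounds for volume of shape ",
         paste(d, collapse = "x"))
  volume(a[(r$zmin + 1):r$zmax, (r$ymin + 1):r$ymax, (r$xmin + 1):r$xmax,
           drop = FALSE], spacing = spacing)
}

#' Automatic contrast limits
#'
#' Returns the two data percentiles used for display scaling; the data are
#' never modified. On a constant volume both limits coincide and the result
#' carries a `degenerate` attribute.
#'
#' @param v a [volume] or 3D array.
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return Numeric length-2 `(low, high)`; attribute `degenerate` is `TRUE`
#'   when `low == high`.
#' @export
contrast_limits <- function(v, low_pct = 1, high_pct = 99) {
  a <- as_array3d(v)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  lim <- unname(quantile(a, c(low_pct, high_pct) / 100, names = FALSE))
  attr(lim, "degenerate") <- lim[1] == lim[2]
  lim
}
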