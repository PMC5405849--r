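# HDF5 sidecar: one file holds all intermediate products of a segmentation
# session under a fixed group layout:
#   /data                         source volume
#   /features/<name>              feature channels
#   /superregions/supervoxels     supervoxel label grid
#   /superregions/megavoxels      megavoxel label grid
#   /annotations/<level>          annotation label grids (-1 = unlabelled)
#   /predictions/labels           refined label grid
#   /predictions/probs            per-region probability matrix
#   /cache/...                    pipeline stage cache (see run_pipeline)
# 3D grids are stored so that C-order readers see (z,y,x); matrices are
# stored transposed for the same reason.

#' Create an empty HDF5 sidecar file
#'
#' @param path file path (`.h5`); an existing file is replaced.
#' @return `path`, invisibly.
#' @export
sidecar_create <- function(path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (g in c("features", "superregions", "annotations", "predictions", "cache"))
    rhdf5::h5createGroup(path, g)
  rhdf5::h5closeAll()
  invisible(path)
}

# link-by-link existence check; H5Lexists cannot probe past a missing group
h5_exists <- function(path, name) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  sofar <- character(0)
  for (p in parts) {
    sofar <- c(sofar, p)
    if (!rhdf5::H5Lexists(fid, paste(sofar, collapse = "/"))) return(FALSE)
  }
  TRUE
}

#' Write an object to a sidecar dataset
#'
#' 3D arrays and matrices are written with dimensions reversed so external
#' C-order tools see the package's `(z, y, x)` convention; [sidecar_read()]
#' inverts this, making round trips bit-exact. Parent groups are created
#' as needed and existing datasets replaced.
#'
#' @param path sidecar file.
#' @param name dataset name, e.g. `"features/gauss"`.
#' @param obj numeric/integer array, matrix or vector.
#' @param attrs named list of scalar/character attributes to attach.
#' @return `path`, invisibly.
#' @export
sidecar_write <- function(path, name, obj, attrs = list()) {
  if (!file.exists(path)) sidecar_create(path)
  if (h5_exists(path, name)) rhdf5::h5delete(path, name)
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) > 1L) {
    for (i in seq_len(length(parts) - 1L)) {
      grp <- paste(parts[seq_len(i)], collapse = "/")
      if (!h5_exists(path, grp)) rhdf5::h5createGroup(path, grp)
    }
  }
  stored <- if (is.array(obj) && length(dim(obj)) > 1L)
    aperm(obj, rev(seq_along(dim(obj)))) else obj
  rhdf5::h5write(stored, path, name)
  if (length(attrs)) {
    fid <- rhdf5::H5Fopen(path)
    oid <- rhdf5::H5Oopen(fid, name)
    for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], oid, nm)
    rhdf5::H5Oclose(oid)
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a sidecar dataset
#'
#' @param path sidecar file.
#' @param name dataset name.
#' @return The stored object with the package's dimension order restored.
#' @export
sidecar_read <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  rhdf5::h5closeAll()
  if (is.array(x) && length(dim(x)) > 1L) x <- aperm(x, rev(seq_along(dim(x))))
  x
}

#' Test whether a sidecar dataset exists
#' @param path sidecar file.
#' @param name dataset name.
#' @return Logical.
#' @export
sidecar_exists <- function(path, name) {
  if (!file.exists(path)) return(FALSE)
  on.exit(rhdf5::h5closeAll())
  h5_exists(path, name)
}

#' Read one attribute of a sidecar dataset
#' @param path sidecar file.
#' @param name dataset name.
#' @param attr attribute name.
#' @return The attribute value, or `NULL` if absent.
#' @export
sidecar_attr <- function(path, name, attr) {
  if (!sidecar_exists(path, name)) return(NULL)
  on.exit(rhdf5::h5closeAll())
  at <- rhdf5::h5readAttributes(path, name)
  if (is.null(at[[attr]])) NULL else as.vector(at[[attr]])
}
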