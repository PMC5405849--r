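# Label hierarchy and annotation volumes. Labels form a forest (children
# constrain training/prediction to their parent's territory); annotations
# are per-voxel integer grids with -1 = unlabelled plus a provenance code
# (how each voxel was labelled: manually, by region painting, or accepted
# from a confident prediction).

PROV_NONE <- 0L
PROV_MANUAL <- 1L
PROV_REGION <- 2L
PROV_ACCEPTED <- 3L

#' Create a label hierarchy
#'
#' @return An empty `label_hierarchy` (data.frame of id, name, colour,
#'   parent).
#' @export
label_hierarchy <- function() {
  structure(data.frame(id = integer(), name = character(),
                       colour = character(), parent = integer()),
            class = c("label_hierarchy", "data.frame"))
}

#' Add a label to a hierarchy
#'
#' Labels may be nested arbitrarily deep, although two levels (large
#' regions, then objects within them) are usually sufficient. The parent
#' graph must remain a forest.
#'
#' @param h a [label_hierarchy()].
#' @param id unique non-negative integer label id.
#' @param name label name.
#' @param colour display colour (any string).
#' @param parent id of the parent label, or `NA` for a root label.
#' @return The extended hierarchy.
#' @export
add_label <- function(h, id, name, colour = "#888888", parent = NA_integer_) {
  stopifnot(inherits(h, "label_hierarchy"))
  id <- as.integer(id)
  if (id < 0) stop("label ids must be >= 0")
  if (id %in% h$id) stop("duplicate label id: ", id)
  if (!is.na(parent) && !parent %in% h$id)
    stop("parent label ", parent, " is not declared")
  out <- rbind(h, data.frame(id = id, name = name, colour = colour,
                             parent = as.integer(parent)))
  class(out) <- class(h)
  out # forest by construction: parents must pre-exist, ids unique
}

#' Depth of each label in the hierarchy
#' @param h a [label_hierarchy()].
#' @return Named integer vector (0 = root).
#' @export
label_depth <- function(h) {
  depth <- integer(nrow(h))
  names(depth) <- as.character(h$id)
  for (i in seq_len(nrow(h))) {
    d <- 0L
    p <- h$parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      p <- h$parent[match(p, h$id)]
    }
    depth[i] <- d
  }
  depth
}

#' Create an empty annotation volume
#'
#' @param shape integer length-3 `(nz, ny, nx)`.
#' @return An `annotation_volume`: list with `labels` (3D integer array,
#'   -1 = unlabelled) and `provenance` (0 none, 1 manual, 2 region,
#'   3 accepted).
#' @export
annotation_volume <- function(shape) {
  structure(list(labels = array(-1L, dim = shape),
                 provenance = array(PROV_NONE, dim = shape)),
            class = "annotation_volume")
}

#' @export
print.annotation_volume <- function(x, ...) {
  n <- sum(x$labels >= 0)
  cat(sprintf("<annotation_volume> %s grid, %d voxels labelled (%.3g%%)\n",
              paste(dim(x$labels), collapse = "x"), n,
              100 * n / length(x$labels)))
  invisible(x)
}

#' Paint annotations at a super-region level
#'
#' At voxel level only the listed voxels receive the label; at supervoxel
#' or megavoxel level every voxel of every region the path touches does.
#' Repainting with the same label is idempotent.
#'
#' @param ann an [annotation_volume()].
#' @param coords integer matrix of voxel coordinates (columns z, y, x;
#'   1-based), e.g. a pen path.
#' @param level `"voxel"`, `"supervoxel"` or `"megavoxel"`.
#' @param label label id to assign (must be declared when `hierarchy`
#'   given).
#' @param partition `supervoxel_partition` (required above voxel level).
#' @param mv `megavoxel_partition` (required at megavoxel level).
#' @param hierarchy optional [label_hierarchy()] used to validate `label`.
#' @return The updated annotation volume.
#' @export
paint <- function(ann, coords, level = c("voxel", "supervoxel", "megavoxel"),
                  label, partition = NULL, mv = NULL, hierarchy = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(ann, "annotation_volume"))
  label <- as.integer(label)
  if (!is.null(hierarchy) && !label %in% hierarchy$id)
    stop("undeclared label: ", label)
  coords <- matrix(as.integer(coords), ncol = 3L)
  d <- dim(ann$labels)
  if (any(coords < 1L) || any(coords[, 1] > d[1]) || any(coords[, 2] > d[2]) ||
      any(coords[, 3] > d[3]))
    stop("coordinates out of bounds")
  if (level == "voxel") {
    ann$labels[coords] <- label
    ann$provenance[coords] <- PROV_MANUAL
    return(ann)
  }
  if (is.null(partition)) stop("`partition` required at ", level, " level")
  labs <- partition_labels(partition)
  touched_sv <- unique(labs[coords])
  sel <- if (level == "supervoxel") {
    as.vector(labs) %in% touched_sv
  } else {
    if (is.null(mv)) stop("`mv` required at megavoxel level")
    touched_mv <- unique(mv$sv_to_mv[touched_sv + 1L])
    mv$sv_to_mv[as.vector(labs) + 1L] %in% touched_mv
  }
  ann$labels[sel] <- label
  ann$provenance[sel] <- PROV_REGION
  ann
}

#' Restrict regions to a parent label's territory
#'
#' A region belongs to the parent when a strict majority of its voxels lie
#' inside the parent mask (ties are broken toward exclusion). Training and
#' prediction of child labels should be restricted to the returned
#' regions; everything outside keeps the parent-level labelling.
#'
#' @param p a `supervoxel_partition` or 0-based label grid.
#' @param parent_mask logical/0-1 3D array, the parent label segmentation.
#' @return Logical vector over regions: `TRUE` = inside the parent.
#' @export
constrain_to_parent <- function(p, parent_mask) {
  labs <- partition_labels(p)
  if (!any(parent_mask)) stop("empty parent mask")
  if (!identical(dim(labs), dim(parent_mask)))
    stop("mask shape must match the partition")
  inside <- rowsum_at(as.numeric(parent_mask), as.vector(labs) + 1L,
                      n_regions(p))
  inside > region_sizes(p) / 2
}

#' Export per-label masks or masked data
#'
#' @param labels_grid 3D integer array of label ids (an annotation grid or
#'   a refined segmentation).
#' @param label_ids labels to export; default all non-negative labels
#'   present.
#' @param mode `"mask"` for binary masks, `"masked_data"` to zero the data
#'   outside each mask.
#' @param data source volume/array (required for `"masked_data"`).
#' @return Named list of 3D arrays, one per label id.
#' @export
export_masks <- function(labels_grid, label_ids = NULL,
                         mode = c("mask", "masked_data"), data = NULL) {
  mode <- match.arg(mode)
  if (inherits(labels_grid, "annotation_volume")) labels_grid <- labels_grid$labels
  present <- sort(unique(as.vector(labels_grid)))
  present <- present[present >= 0]
  if (is.null(label_ids)) label_ids <- present
  if (mode == "masked_data") {
    if (is.null(data)) stop("`data` required for masked_data mode")
    data <- as_array3d(data, "data")
  }
  out <- lapply(label_ids, function(id) {
    m <- labels_grid == id
    if (mode == "mask") array(m, dim(labels_grid)) else data * m
  })
  names(out) <- as.character(label_ids)
  out
}

#' Rebuild a label grid from binary masks
#'
#' Inverse of [export_masks()] for non-overlapping masks: voxels covered
#' by no mask become -1.
#'
#' @param masks named list of logical 3D arrays (names = label ids).
#' @return 3D integer label grid.
#' @export
import_masks <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(-1L, d)
  for (nm in names(masks)) out[masks[[nm]]] <- as.integer(nm)
  out
}
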