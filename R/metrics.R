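# Evaluation metrics for partitions and segmentations.

boundary_mask <- function(labels_grid) {
  d <- dim(labels_grid)
  b <- array(FALSE, d)
  if (d[1] > 1) {
    df <- labels_grid[2:d[1], , , drop = FALSE] != labels_grid[1:(d[1] - 1), , , drop = FALSE]
    b[2:d[1], , ][df] <- TRUE
    b[1:(d[1] - 1), , ][df] <- TRUE
  }
  if (d[2] > 1) {
    df <- labels_grid[, 2:d[2], , drop = FALSE] != labels_grid[, 1:(d[2] - 1), , drop = FALSE]
    b[, 2:d[2], ][df] <- TRUE
    b[, 1:(d[2] - 1), ][df] <- TRUE
  }
  if (d[3] > 1) {
    df <- labels_grid[, , 2:d[3], drop = FALSE] != labels_grid[, , 1:(d[3] - 1), drop = FALSE]
    b[, , 2:d[3]][df] <- TRUE
    b[, , 1:(d[3] - 1)][df] <- TRUE
  }
  b
}

#' Boundary recall of a partition against ground truth
#'
#' Fraction of true boundary voxels (voxels with a face neighbour of a
#' different ground-truth label) lying within Chebyshev distance
#' `tolerance` of a partition boundary voxel. High recall means the
#' over-segmentation adheres to the true phase boundaries.
#'
#' @param p a `supervoxel_partition` or 0-based label grid.
#' @param gt ground-truth 3D integer label grid.
#' @param tolerance Chebyshev distance tolerance in voxels.
#' @return Scalar recall in `[0, 1]` (1 when the ground truth has no
#'   boundary at all).
#' @export
boundary_recall <- function(p, gt, tolerance = 1L) {
  labs <- partition_labels(p)
  stopifnot(identical(dim(labs), dim(gt)))
  gt_b <- boundary_mask(gt)
  if (!any(gt_b)) return(1)
  p_b <- boundary_mask(labs)
  if (tolerance > 0)
    p_b <- binary_dilate(p_b, cube_offsets(tolerance))
  mean(p_b[gt_b])
}

#' Voxelwise segmentation accuracy
#'
#' @param pred predicted 3D label grid.
#' @param gt ground-truth 3D label grid.
#' @return Fraction of voxels with matching labels.
#' @export
segmentation_accuracy <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  mean(pred == gt)
}

#' Achievable accuracy of a partition (under-segmentation ceiling)
#'
#' Accuracy obtained when every region takes its majority ground-truth
#' label: the best any region-level classifier could do.
#'
#' @param p a `supervoxel_partition` or 0-based label grid.
#' @param gt ground-truth 3D label grid.
#' @return Scalar in `[0, 1]`.
#' @export
achievable_accuracy <- function(p, gt) {
  best <- annotations_to_regions(gt, p)
  segmentation_accuracy(refine_to_voxels(best, p), gt)
}
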