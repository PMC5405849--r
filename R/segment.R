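# High-level convenience workflow: volume + sparse voxel annotations ->
# refined voxel segmentation, chaining features -> supervoxels ->
# descriptors -> classifier -> MRF refinement with package defaults.

#' Segment a volume from sparse annotations
#'
#' Runs the default end-to-end workflow: feature channels
#' ([default_channels()]), SLIC supervoxels on the Gaussian-denoised
#' channel, neighbourhood-augmented z-scored supervoxel mean descriptors,
#' an ERF classifier trained on the annotated supervoxels, and MRF
#' refinement of the probabilities, propagated back to voxels.
#'
#' @param v a [volume] or 3D array.
#' @param ann an `annotation_volume` (or 3D integer grid, -1 = unlabelled)
#'   with sparse voxel annotations of >= 2 labels.
#' @param channels channel spec list; default [default_channels()].
#' @param spacing,compactness SLIC parameters.
#' @param classifier,seed passed to [train_model()].
#' @param lambda MRF pairwise strength.
#' @param connectivity region-graph connectivity.
#' @param parent_mask optional logical 3D array restricting training and
#'   prediction to regions majority-inside the mask; outside regions keep
#'   the raw argmax of the parent labelling (label -1 if none).
#' @return List: `labels` (refined 3D label grid), `raw_labels` (argmax
#'   before refinement), `probs` (probability field), `partition`,
#'   `graph`, `descriptors`, `model`, `mrf`, `energy`.
#' @export
segment_volume <- function(v, ann, channels = default_channels(),
                           spacing = c(10, 10, 10), compactness = 30,
                           classifier = "erf", seed = 1L, lambda = 1,
                           connectivity = 6L, parent_mask = NULL) {
  fs <- feature_stack(v, channels)
  sv_channel <- if ("gauss2" %in% names(fs$channels)) fs$channels$gauss2 else
    fs$channels[[1]]
  p <- slic_supervoxels(sv_channel, spacing = spacing, compactness = compactness)
  g <- build_region_graph(p, connectivity)
  desc <- normalise_descriptors(supervoxel_mean(fs, p), "zscore")
  desc <- augment_neighbors(desc, g)
  rann <- annotations_to_regions(ann, p)
  keep <- rep(TRUE, p$K)
  if (!is.null(parent_mask)) {
    keep <- constrain_to_parent(p, parent_mask)
    rann[!keep] <- -1L
  }
  model <- train_model(desc[keep, , drop = FALSE], rann[keep],
                       classifier = classifier, seed = seed)
  probs_in <- predict_probs(model, desc[keep, , drop = FALSE])
  L <- length(model$label_ids)
  probs <- matrix(1 / L, p$K, L)
  probs[keep, ] <- probs_in
  probs <- structure(probs, label_ids = model$label_ids,
                     class = "probability_field")
  raw_region <- model$label_ids[max.col(probs, ties.method = "first")]
  m <- build_mrf(probs, g, desc, lambda = lambda)
  sol <- solve_mrf(m)
  refined_region <- sol$labels
  if (!is.null(parent_mask)) refined_region[!keep] <- -1L
  if (!is.null(parent_mask)) raw_region[!keep] <- -1L
  list(labels = refine_to_voxels(refined_region, p),
       raw_labels = refine_to_voxels(raw_region, p),
       probs = probs, partition = p, graph = g, descriptors = desc,
       model = model, mrf = m, energy = sol$energy)
}
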