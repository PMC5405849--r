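# internal helpers shared across modules

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_array3d <- function(v, arg = "v") {
  if (inherits(v, "volume")) v <- v$data
  if (!is.array(v) || length(dim(v)) != 3L)
    stop("`", arg, "` must be a 3D array or volume", call. = FALSE)
  storage.mode(v) <- "double"
  v
}

check_finite <- function(v, arg = "v") {
  if (!all(is.finite(v)))
    stop("`", arg, "` contains non-finite values", call. = FALSE)
  invisible(v)
}

# labels grid (0-based) from a partition object or raw integer array
partition_labels <- function(p) {
  if (inherits(p, "supervoxel_partition")) return(p$labels)
  if (is.array(p) && length(dim(p)) == 3L) {
    storage.mode(p) <- "integer"
    return(p)
  }
  stop("expected a supervoxel_partition or a 3D integer label array", call. = FALSE)
}

n_regions <- function(p) {
  if (inherits(p, "supervoxel_partition")) return(p$K)
  max(partition_labels(p)) + 1L
}

region_sizes <- function(p) {
  labs <- partition_labels(p)
  tabulate(as.vector(labs) + 1L, nbins = n_regions(p))
}

rowmax_idx <- function(m) max.col(m, ties.method = "first")
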