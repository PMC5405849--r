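# Voxel and supervoxel descriptors. Descriptor matrices have one row per
# region (voxel or supervoxel); row i corresponds to region id i-1. Every
# seeded operation is bit-reproducible under the same seed.

stack_matrix <- function(fs, channels = NULL) {
  if (!inherits(fs, "feature_stack")) stop("`fs` must be a feature_stack")
  if (is.null(channels)) channels <- names(fs$channels)
  missing <- setdiff(channels, names(fs$channels))
  if (length(missing)) stop("unknown channel name(s): ", paste(missing, collapse = ", "))
  X <- vapply(channels, function(nm) as.vector(fs$channels[[nm]]),
              numeric(prod(fs$shape)))
  colnames(X) <- channels
  X
}

descriptor_matrix <- function(X, method, normalisation = "none") {
  structure(X, method = method, normalisation = normalisation,
            class = c("descriptor_matrix", class(X)))
}

#' Per-voxel descriptors
#'
#' One row per voxel (in `[z, y, x]` column-major order, z fastest), one
#' column per selected feature channel.
#'
#' @param fs a [feature_stack()].
#' @param channels channel names to include; default all.
#' @param normalisation `"none"`, `"zscore"` (per column) or `"unit"`
#'   (per row L2).
#' @return A descriptor matrix (`n_voxels` x `n_channels`).
#' @export
voxel_descriptors <- function(fs, channels = NULL,
                              normalisation = c("none", "zscore", "unit")) {
  normalisation <- match.arg(normalisation)
  X <- stack_matrix(fs, channels)
  descriptor_matrix(normalise_descriptors(X, normalisation), "voxel", normalisation)
}

#' Normalise a descriptor matrix
#'
#' `"zscore"` standardises each column (constant columns become 0);
#' `"unit"` scales each row to unit L2 norm (zero rows stay zero).
#'
#' @param d descriptor matrix.
#' @param method `"none"`, `"zscore"` or `"unit"`.
#' @return The normalised matrix.
#' @export
normalise_descriptors <- function(d, method = c("zscore", "unit", "none")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  out <- switch(method,
    none = d,
    zscore = {
      mu <- colMeans(d)
      s <- apply(d, 2, sd)
      s[s == 0] <- 1
      sweep(sweep(d, 2, mu), 2, s, "/")
    },
    unit = {
      nr <- sqrt(rowSums(d^2))
      nr[nr == 0] <- 1
      d / nr
    })
  out
}

#' Supervoxel mean descriptors
#'
#' Row i = per-channel mean over the voxels of supervoxel i-1. The
#' size-weighted mean of the rows reproduces the global channel mean
#' exactly (conservation).
#'
#' @param fs a [feature_stack()].
#' @param p a `supervoxel_partition`.
#' @param channels channel names; default all.
#' @return A descriptor matrix (`K` x `n_channels`).
#' @export
supervoxel_mean <- function(fs, p, channels = NULL) {
  X <- stack_matrix(fs, channels)
  labs <- as.vector(partition_labels(p))
  if (length(labs) != nrow(X)) stop("feature stack and partition shapes differ")
  sums <- rowsum(X, labs, reorder = TRUE)
  sizes <- region_sizes(p)
  descriptor_matrix(sums / sizes, "mean")
}

# fit a seeded k-means codebook on a voxel sample and assign all rows
codebook_assign <- function(X, k, sample_fraction, seed) {
  n <- nrow(X)
  ns <- max(k, ceiling(sample_fraction * n))
  ns <- min(ns, n)
  if (k > ns) stop("k exceeds the number of sampled voxels")
  fit <- with_seed(seed, {
    idx <- sample.int(n, ns)
    kmeans(X[idx, , drop = FALSE], centers = k, nstart = 10L, iter.max = 50L)
  })
  centers <- fit$centers
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  max.col(-d2, ties.method = "first")
}

region_code_histogram <- function(codes, labs, K, k) {
  counts <- matrix(0, K, k)
  tab <- rowsum(diag(k)[codes, , drop = FALSE], labs, reorder = TRUE)
  counts[as.integer(rownames(tab)) + 1L, ] <- tab
  counts / pmax(rowSums(counts), 1)
}

#' Supervoxel histogram descriptors
#'
#' A k-means codebook is fitted on a seeded random sample of voxel
#' descriptors; row i is the normalised histogram of code assignments of
#' the voxels in supervoxel i-1. Rows sum to 1.
#'
#' @inheritParams supervoxel_mean
#' @param k codebook size (>= 1).
#' @param sample_fraction fraction of voxels sampled for the codebook fit.
#' @param seed RNG seed (k-means++-style restarts, 10 by default).
#' @return A descriptor matrix (`K` x `k`), rows summing to 1.
#' @export
supervoxel_histogram <- function(fs, p, k = 16L, sample_fraction = 0.05,
                                 seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  X <- stack_matrix(fs)
  labs <- as.vector(partition_labels(p))
  K <- n_regions(p)
  if (k == 1L)
    return(descriptor_matrix(matrix(1, K, 1), "histogram"))
  codes <- codebook_assign(X, k, sample_fraction, seed)
  descriptor_matrix(region_code_histogram(codes, labs, K, k), "histogram")
}

#' Supervoxel texton descriptors
#'
#' Voxel descriptors are projected onto their leading principal components,
#' a k-means texton codebook is fitted on a seeded sample of the projected
#' rows, and row i is the normalised texton histogram of supervoxel i-1.
#'
#' @inheritParams supervoxel_histogram
#' @param pca_dims number of principal components (<= channel count).
#' @return A descriptor matrix (`K` x `k`), rows summing to 1.
#' @export
supervoxel_textons <- function(fs, p, pca_dims, k = 16L, sample_fraction = 0.05,
                               seed = 1L) {
  X <- stack_matrix(fs)
  if (pca_dims > ncol(X)) stop("pca_dims must be <= channel count")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  Z <- pc$x[, seq_len(pca_dims), drop = FALSE]
  labs <- as.vector(partition_labels(p))
  K <- n_regions(p)
  if (k == 1L)
    return(descriptor_matrix(matrix(1, K, 1), "texton"))
  codes <- codebook_assign(Z, k, sample_fraction, seed)
  descriptor_matrix(region_code_histogram(codes, labs, K, k), "texton")
}

#' Supervoxel sigma-set descriptors
#'
#' First- and second-order statistics per supervoxel: row i concatenates
#' the per-channel mean with the lower-triangular Cholesky factor of the
#' regularised within-supervoxel channel covariance `Sigma + eps * I`,
#' `eps = 1e-6 * trace(Sigma) / C` (floored at 1e-12 so the factor always
#' exists). Descriptor length is `C + C * (C + 1) / 2`.
#'
#' @inheritParams supervoxel_mean
#' @return A descriptor matrix (`K` x `C + C(C+1)/2`).
#' @export
supervoxel_sigmaset <- function(fs, p, channels = NULL) {
  X <- stack_matrix(fs, channels)
  C <- ncol(X)
  labs <- as.vector(partition_labels(p))
  K <- n_regions(p)
  sizes <- region_sizes(p)
  mu <- rowsum(X, labs, reorder = TRUE) / sizes
  # per-region second moments for all channel pairs
  pairs <- which(upper.tri(matrix(0, C, C), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  m2 <- rowsum(XX, labs, reorder = TRUE) / sizes
  ltri <- which(lower.tri(matrix(0, C, C), diag = TRUE), arr.ind = TRUE)
  out <- matrix(0, K, C + nrow(ltri))
  for (i in seq_len(K)) {
    S <- matrix(0, C, C)
    S[pairs] <- m2[i, ]
    S[pairs[, 2:1, drop = FALSE]] <- m2[i, ]
    S <- S - tcrossprod(mu[i, ])
    eps <- max(1e-6 * sum(diag(S)) / C, 1e-12)
    L <- t(chol(S + diag(eps, C)))
    out[i, ] <- c(mu[i, ], L[ltri])
  }
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("ch", seq_len(C))
  colnames(out) <- c(paste0("mean_", cn),
                     paste0("chol_", ltri[, 1], "_", ltri[, 2]))
  descriptor_matrix(out, "sigmaset")
}

#' Neighbourhood-augmented descriptors
#'
#' Appends to each region descriptor the unweighted mean of its graph
#' neighbours' descriptors, doubling the width: row i becomes
#' `(s_i, mean_{j in N_i} s_j)`. An isolated region uses its own
#' descriptor as the neighbour block.
#'
#' @param desc descriptor matrix, one row per graph node.
#' @param g a [build_region_graph()] result over the same regions.
#' @return A descriptor matrix of twice the input width.
#' @export
augment_neighbors <- function(desc, g) {
  desc <- as.matrix(desc)
  if (nrow(desc) != g$n_nodes)
    stop("descriptor rows must match graph nodes")
  f <- g$edges$from + 1L
  t <- g$edges$to + 1L
  acc <- matrix(0, nrow(desc), ncol(desc))
  cnt <- numeric(nrow(desc))
  if (length(f)) {
    acc <- rowsum(rbind(desc[t, , drop = FALSE], desc[f, , drop = FALSE]),
                  c(f, t), reorder = TRUE)
    got <- as.integer(rownames(acc))
    full <- matrix(0, nrow(desc), ncol(desc))
    full[got, ] <- acc
    acc <- full
    cnt <- tabulate(c(f, t), nbins = nrow(desc))
  }
  nb <- desc # isolated nodes fall back to themselves
  has <- cnt > 0
  nb[has, ] <- acc[has, , drop = FALSE] / cnt[has]
  out <- cbind(desc, nb)
  cn <- colnames(desc)
  if (!is.null(cn)) colnames(out) <- c(cn, paste0("nb_", cn))
  descriptor_matrix(out, paste0(attr(desc, "method") %||% "desc", "+neighbors"))
}

#' Region-level annotations from a voxel annotation grid
#'
#' Each region takes the majority label among its annotated voxels
#' (ties to the lowest label id); regions with no annotated voxel stay
#' unlabelled (-1).
#'
#' @param ann voxel annotation grid (3D integer array, -1 = unlabelled) or
#'   an `annotation_volume`.
#' @param p a `supervoxel_partition` or 0-based label grid.
#' @return Integer vector of length K, -1 where unlabelled.
#' @export
annotations_to_regions <- function(ann, p) {
  if (inherits(ann, "annotation_volume")) ann <- ann$labels
  labs <- as.vector(partition_labels(p))
  a <- as.vector(ann)
  K <- n_regions(p)
  out <- rep(-1L, K)
  sel <- a >= 0
  if (!any(sel)) return(out)
  tab <- table(region = labs[sel], label = a[sel])
  regs <- as.integer(rownames(tab))
  lab_ids <- as.integer(colnames(tab))
  best <- lab_ids[apply(tab, 1, which.max)] # which.max: first max = lowest id
  out[regs + 1L] <- best
  out
}
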