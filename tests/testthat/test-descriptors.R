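# Voxel/supervoxel descriptors and neighbourhood augmentation.

test_that("voxel descriptors read channels verbatim and z-score correctly", {
  d <- c(2, 1, 1)
  a <- array(c(3, 7), d)
  fs <- feature_stack(a, list(raw = list(type = "raw"),
                              g0 = list(type = "gaussian", sigma = 0)))
  vd <- voxel_descriptors(fs)
  expect_equal(dim(vd), c(2, 2))
  expect_equal(unclass(vd)[, "raw"], c(3, 7), ignore_attr = TRUE)
  expect_equal(unclass(vd)[, "g0"], c(3, 7), ignore_attr = TRUE)
  const <- feature_stack(array(1, c(3, 3, 3)), list(raw = list(type = "raw")))
  vc <- voxel_descriptors(const)
  expect_true(all(vc == vc[1, 1]))
  set.seed(30)
  fs2 <- feature_stack(array(rnorm(5^3), c(5, 5, 5)),
                       list(raw = list(type = "raw"),
                            g = list(type = "gaussian", sigma = 1)))
  vz <- voxel_descriptors(fs2, normalisation = "zscore")
  expect_equal(colMeans(vz), c(raw = 0, g = 0), tolerance = 1e-10)
  expect_equal(apply(vz, 2, sd), c(raw = 1, g = 1), tolerance = 1e-10)
  expect_error(voxel_descriptors(fs2, channels = "missing"), "unknown channel")
})

test_that("supervoxel means match a brute-force oracle and conserve the global mean", {
  fx <- tiny_stack()
  desc <- supervoxel_mean(fx$fs, fx$p)
  for (nm in names(fx$fs$channels)) {
    want <- brute_region_means(fx$fs$channels[[nm]], fx$p$labels)
    expect_equal(unclass(desc)[, nm], want, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  sizes <- tabulate(fx$p$labels + 1L, fx$p$K)
  global <- colSums(unclass(desc) * sizes) / sum(sizes)
  expect_equal(global[["raw"]], mean(fx$fs$channels$raw), tolerance = 1e-12)
  expect_equal(global[["g1"]], mean(fx$fs$channels$g1), tolerance = 1e-12)
  # constant channel: every row equals the constant
  cfs <- feature_stack(array(2.5, dim(fx$p$labels)), list(c1 = list(type = "raw")))
  cd <- supervoxel_mean(cfs, fx$p)
  expect_true(all(abs(cd - 2.5) < 1e-12))
})

test_that("histogram descriptors are probability vectors and phase-pure on two phases", {
  fx <- tiny_stack()
  h <- supervoxel_histogram(fx$fs, fx$p, k = 4, seed = 3)
  expect_equal(rowSums(h), rep(1, fx$p$K), ignore_attr = TRUE)
  expect_equal(unclass(supervoxel_histogram(fx$fs, fx$p, k = 1)),
               matrix(1, fx$p$K, 1), ignore_attr = TRUE)
  # two-phase phantom with k = 2: rows one-hot per phase
  tp <- two_phase(40L)
  p <- slic_supervoxels(tp$volume, spacing = c(10, 10, 10))
  fs <- feature_stack(tp$volume, list(raw = list(type = "raw")))
  h2 <- supervoxel_histogram(fs, p, k = 2, sample_fraction = 0.2, seed = 5)
  expect_true(all(apply(h2, 1, max) == 1))
  phase <- annotations_to_regions(tp$gt, p)
  expect_equal(length(unique(max.col(h2)[phase == 0])), 1L)
  expect_equal(length(unique(max.col(h2)[phase == 1])), 1L)
  # determinism under a fixed seed
  expect_identical(supervoxel_histogram(fx$fs, fx$p, k = 4, seed = 3), h)
  expect_error(supervoxel_histogram(fx$fs, fx$p, k = 0), "k must be")
})

test_that("full-dimension texton descriptors match histogram partitions", {
  fx <- tiny_stack()
  C <- length(fx$fs$channels)
  h <- supervoxel_histogram(fx$fs, fx$p, k = 3, sample_fraction = 0.5, seed = 9)
  t3 <- supervoxel_textons(fx$fs, fx$p, pca_dims = C, k = 3,
                           sample_fraction = 0.5, seed = 9)
  expect_equal(rowSums(t3), rep(1, fx$p$K), ignore_attr = TRUE)
  # full-dimensional PCA is a rigid rotation: k-means sees identical
  # distances, so the histograms agree up to a permutation of codebook bins
  perm_match <- function(a, b) {
    for (pm in asplit(rbind(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                            c(3, 1, 2), c(3, 2, 1)), 1)) {
      if (isTRUE(all.equal(unclass(a), unclass(b)[, pm],
                           check.attributes = FALSE, tolerance = 1e-8)))
        return(TRUE)
    }
    FALSE
  }
  expect_true(perm_match(t3, h))
  expect_identical(supervoxel_textons(fx$fs, fx$p, pca_dims = C, k = 3,
                                      sample_fraction = 0.5, seed = 9), t3)
  expect_error(supervoxel_textons(fx$fs, fx$p, pca_dims = C + 1), "pca_dims")
})

test_that("sigma-set descriptors carry means and Cholesky factors", {
  fx <- tiny_stack()
  C <- length(fx$fs$channels)
  ss <- supervoxel_sigmaset(fx$fs, fx$p)
  expect_equal(ncol(ss), C + C * (C + 1) / 2)
  # 2-channel oracle on one supervoxel: population covariance + chol
  id <- 0L
  sel <- fx$p$labels == id
  X <- cbind(fx$fs$channels$raw[sel], fx$fs$channels$g1[sel])
  n <- nrow(X)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / n
  eps <- max(1e-6 * sum(diag(S)) / 2, 1e-12)
  L <- t(chol(S + diag(eps, 2)))
  expect_equal(unname(unclass(ss)[1, ]), c(mu, L[1, 1], L[2, 1], L[2, 2]),
               tolerance = 1e-10)
  # constant channels: mean block constant, covariance block = chol(eps I)
  cfs <- feature_stack(array(4, dim(fx$p$labels)),
                       list(c1 = list(type = "raw")))
  cs <- supervoxel_sigmaset(cfs, fx$p)
  expect_true(all(abs(cs[, 1] - 4) < 1e-12))
  expect_true(all(abs(cs[, 2] - sqrt(1e-12)) < 1e-12))
})

test_that("neighbour augmentation evaluates the mean-of-neighbours rule", {
  # 3-node path with scalar descriptors 0, 1, 2
  g <- structure(list(edges = data.frame(from = c(0L, 1L), to = c(1L, 2L),
                                         boundary_count = c(1L, 1L)),
                      n_nodes = 3L, connectivity = 6L),
                 class = "region_graph")
  desc <- matrix(c(0, 1, 2), 3, 1)
  phi <- augment_neighbors(desc, g)
  expect_equal(ncol(phi), 2L)
  expect_equal(unclass(phi)[2, ], c(1, 1), ignore_attr = TRUE)  # middle node
  expect_equal(unclass(phi)[1, ], c(0, 1), ignore_attr = TRUE)  # end node
  # identical rows: phi = (s, s); isolated node falls back to itself
  g2 <- structure(list(edges = data.frame(from = 0L, to = 1L,
                                          boundary_count = 1L),
                       n_nodes = 3L, connectivity = 6L),
                  class = "region_graph")
  same <- matrix(5, 3, 2)
  phi2 <- augment_neighbors(same, g2)
  expect_true(all(phi2 == 5))
  iso <- matrix(c(1, 2, 9), 3, 1)
  phi3 <- augment_neighbors(iso, g2)
  expect_equal(unclass(phi3)[3, ], c(9, 9), ignore_attr = TRUE)
  expect_error(augment_neighbors(matrix(0, 2, 1), g), "match graph nodes")
})

test_that("region annotations take the majority label with low-id ties", {
  labs <- array(0L, c(4, 4, 4))
  labs[, , 3:4] <- 1L
  ann <- array(-1L, c(4, 4, 4))
  ann[1, 1, 1] <- 5L; ann[2, 1, 1] <- 5L; ann[3, 1, 1] <- 2L # majority 5
  ann[1, 1, 3] <- 4L; ann[1, 2, 3] <- 7L                     # tie -> 4
  r <- annotations_to_regions(ann, labs)
  expect_equal(r, c(5L, 4L))
})
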