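# MRF construction, energies and inference.

test_that("MRF weights follow the boundary-and-similarity formula", {
  # 2-node hand check
  pf <- structure(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2), label_ids = 0:1,
                  class = "probability_field")
  g <- structure(list(edges = data.frame(from = 0L, to = 1L,
                                         boundary_count = 4L),
                      n_nodes = 2L, connectivity = 6L), class = "region_graph")
  desc <- matrix(c(0, 3, 0, 4), 2, 2) # distance 5
  m <- build_mrf(pf, g, desc, lambda = 2, sigma_w = 2)
  expect_equal(m$unary, -log(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)))
  expect_equal(m$edges$weight, 1 * exp(-25 / 8)) # b/bmax = 1, d^2 = 25
  # identical descriptors + uniform boundary counts: all weights equal
  set.seed(50)
  n <- 6
  pairs <- t(combn(n, 2))
  g2 <- structure(list(edges = data.frame(from = pairs[, 1] - 1L,
                                          to = pairs[, 2] - 1L,
                                          boundary_count = rep(3L, nrow(pairs))),
                       n_nodes = n, connectivity = 6L), class = "region_graph")
  probs <- matrix(runif(n * 2), n, 2); probs <- probs / rowSums(probs)
  pf2 <- structure(probs, label_ids = 0:1, class = "probability_field")
  m2 <- build_mrf(pf2, g2, matrix(1, n, 3), lambda = 1)
  expect_equal(length(unique(round(m2$edges$weight, 12))), 1L)
  # p = 1 on the true class: zero unary there
  pf3 <- structure(matrix(c(1, 0, 0, 1), 2, 2), label_ids = 0:1,
                   class = "probability_field")
  m3 <- build_mrf(pf3, g, desc)
  expect_equal(m3$unary[1, 1], 0)
  expect_equal(m3$unary[2, 2], 0)
  expect_true(all(is.finite(m3$unary))) # p_floor bounds the zeros
})

test_that("energies match hand-computed values", {
  una <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2) # 3 nodes, 2 labels
  m <- structure(list(unary = una,
                      edges = data.frame(from = c(0L, 0L, 1L),
                                         to = c(1L, 2L, 2L),
                                         weight = c(0.5, 2, 1)),
                      lambda = 3, label_ids = 0:1), class = "mrf_problem")
  # single-node slice: agreeing labelling pays unaries only
  expect_equal(mrf_energy(m, c(1L, 1L, 1L)), 1 + 2 + 3)
  expect_equal(mrf_energy(m, c(2L, 2L, 2L)), 4 + 5 + 6)
  # triangle with disagreements: edges (0,1) and (1,2) cut
  expect_equal(mrf_energy(m, c(1L, 2L, 1L)), 1 + 5 + 3 + 3 * (0.5 + 1))
  expect_error(mrf_energy(m, c(1L, 9L, 1L)), "invalid label")
  m1 <- structure(list(unary = matrix(c(2, 7), 1, 2),
                       edges = data.frame(from = integer(), to = integer(),
                                          weight = numeric()),
                       lambda = 1, label_ids = 0:1), class = "mrf_problem")
  expect_equal(mrf_energy(m1, 1L), 2)
})

test_that("lambda = 0 refinement returns the argmax labelling bit-exactly", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    L <- sample(2:5, 1)
    m <- random_mrf(n, L, seed = rep, lambda = 0)
    sol <- solve_mrf(m)
    expect_identical(sol$labelling, max.col(-m$unary, ties.method = "first"))
  }
})

test_that("two-label inference attains the exhaustive minimum on small problems", {
  for (rep in 1:40) {
    m <- random_mrf(n = sample(2:10, 1), L = 2, seed = 1000 + rep)
    sol <- solve_mrf(m, "alpha_expansion")
    expect_equal(sol$energy, brute_mrf_min(m), tolerance = 1e-9)
    expect_equal(mrf_energy(m, sol$labelling), sol$energy)
  }
})

test_that("alpha-expansion never loses to ICM and beats raw argmax", {
  for (rep in 1:25) {
    m <- random_mrf(n = sample(4:12, 1), L = 3, seed = 2000 + rep)
    ea <- solve_mrf(m, "alpha_expansion")$energy
    ei <- solve_mrf(m, "icm")$energy
    expect_lte(ea, ei + 1e-9)
    raw <- max.col(-m$unary, ties.method = "first")
    expect_lte(ea, mrf_energy(m, raw) + 1e-9)
  }
})

test_that("strong smoothing collapses a connected graph to the best single label", {
  set.seed(52)
  n <- 8
  m <- random_mrf(n, 3, seed = 7)
  # ensure connectivity: chain edges, then crank lambda
  m$edges <- data.frame(from = 0:(n - 2), to = 1:(n - 1), weight = 1)
  m$lambda <- 1e6
  sol <- solve_mrf(m)
  expect_equal(length(unique(sol$labelling)), 1L)
  expect_equal(sol$labelling[1], which.min(colSums(m$unary)))
})

test_that("voxel propagation preserves label histograms", {
  fx <- tiny_stack()
  labelling <- sample(c(10L, 20L, 30L), fx$p$K, replace = TRUE)
  grid <- refine_to_voxels(labelling, fx$p)
  expect_equal(dim(grid), dim(fx$p$labels))
  sizes <- tabulate(fx$p$labels + 1L, fx$p$K)
  for (lab in c(10L, 20L, 30L))
    expect_equal(sum(grid == lab), sum(sizes[labelling == lab]))
  # spot lookups
  for (i in sample(length(grid), 25))
    expect_equal(grid[i], labelling[fx$p$labels[i] + 1L])
  expect_true(all(refine_to_voxels(rep(4L, fx$p$K), fx$p) == 4L))
})

test_that("refinement repairs label-flip noise injected into probabilities", {
  fx <- small_phantom()
  p <- slic_supervoxels(gaussian_filter(fx$ph$volume$data, 1))
  g <- build_region_graph(p, 6L)
  fs <- feature_stack(fx$ph$volume$data, list(g1 = list(type = "gaussian", sigma = 1)))
  desc <- normalise_descriptors(supervoxel_mean(fs, p), "zscore")
  true_region <- annotations_to_regions(fx$ph$labels, p)
  ids <- sort(unique(true_region))
  L <- length(ids)
  set.seed(53)
  noisy <- ifelse(runif(p$K) < 0.2,
                  ids[sample.int(L, p$K, replace = TRUE)], true_region)
  probs <- matrix(0.05 / (L - 1), p$K, L)
  probs[cbind(seq_len(p$K), match(noisy, ids))] <- 0.95
  pf <- structure(probs / rowSums(probs), label_ids = ids,
                  class = "probability_field")
  # pairwise strength sized against the confident (0.95) unaries so the
  # smoothing term is actually active
  m <- build_mrf(pf, g, desc, lambda = 10)
  sol <- solve_mrf(m)
  raw <- ids[max.col(pf, ties.method = "first")]
  acc_raw <- segmentation_accuracy(refine_to_voxels(raw, p), fx$ph$labels)
  acc_ref <- segmentation_accuracy(refine_to_voxels(sol$labels, p), fx$ph$labels)
  expect_gte(acc_ref, acc_raw)
  expect_lte(sol$energy, mrf_energy(m, match(raw, ids)))
  # the refinement must actually fix most injected flips
  expect_gt(acc_ref, 0.95)
})
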