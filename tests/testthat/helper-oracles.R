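# Independent oracles: brute-force / closed-form reference implementations
# kept deliberately naive and separate from the package code paths.

# per-label channel means by explicit looping
brute_region_means <- function(channel, labels) {
  ids <- sort(unique(as.vector(labels)))
  vapply(ids, function(id) mean(channel[labels == id]), numeric(1))
}

# region adjacency by exhaustive voxel-pair scan
brute_region_edges <- function(labels, connectivity = 6L) {
  d <- dim(labels)
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(0,1,0), c(0,0,1)),
    "18" = rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(0,1,1), c(0,1,-1),
                 c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1)),
    "26" = rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(0,1,1), c(0,1,-1),
                 c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
                 c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1)))
  counts <- list()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    for (o in seq_len(nrow(offs))) {
      p2 <- c(z, y, x) + offs[o, ]
      if (any(p2 < 1) || any(p2 > d)) next
      a <- labels[z, y, x]
      b <- labels[p2[1], p2[2], p2[3]]
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    return(data.frame(from = integer(), to = integer(),
                      boundary_count = integer()))
  }
  parts <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  out <- data.frame(from = parts[, 1], to = parts[, 2],
                    boundary_count = unlist(counts))
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive enumeration of the MRF minimum energy
brute_mrf_min <- function(m) {
  n <- nrow(m$unary)
  L <- ncol(m$unary)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), n)))
  min(apply(grid, 1, function(lab) mrf_energy(m, as.integer(lab))))
}

# type-7 percentile by explicit sort + linear interpolation
sort_percentile <- function(x, pct) {
  s <- sort(as.vector(x))
  n <- length(s)
  h <- (n - 1) * pct / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# random MRF problem over a random connected-ish graph
random_mrf <- function(n, L, seed, lambda = NULL) {
  set.seed(seed)
  probs <- matrix(runif(n * L), n, L)
  probs <- probs / rowSums(probs)
  pf <- structure(probs, label_ids = 0:(L - 1), class = "probability_field")
  npairs <- n * (n - 1) / 2
  ne <- sample(seq_len(npairs), 1)
  pairs <- t(combn(n, 2))[sample(npairs, ne), , drop = FALSE]
  g <- structure(list(edges = data.frame(from = pairs[, 1] - 1L,
                                         to = pairs[, 2] - 1L,
                                         boundary_count = sample(1:5, ne, TRUE)),
                      n_nodes = n, connectivity = 6L),
                 class = "region_graph")
  desc <- matrix(rnorm(n * 3), n, 3)
  build_mrf(pf, g, desc, lambda = lambda %||% runif(1, 0, 3))
}

# discretised TV objective matching the package's forward-difference scheme
# (argument named `target`, not `f`, so optim() cannot partial-match it)
rof_objective <- function(u, target, weight, eps = 1e-12) {
  f <- target
  d <- dim(f)
  u <- array(u, d)
  g1 <- array(0, d); g2 <- array(0, d); g3 <- array(0, d)
  if (d[1] > 1) g1[1:(d[1] - 1), , ] <- u[2:d[1], , ] - u[1:(d[1] - 1), , ]
  if (d[2] > 1) g2[, 1:(d[2] - 1), ] <- u[, 2:d[2], ] - u[, 1:(d[2] - 1), ]
  if (d[3] > 1) g3[, , 1:(d[3] - 1)] <- u[, , 2:d[3]] - u[, , 1:(d[3] - 1)]
  0.5 * sum((u - f)^2) + weight * sum(sqrt(g1^2 + g2^2 + g3^2 + eps))
}
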