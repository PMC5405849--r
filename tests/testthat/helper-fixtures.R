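# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# small noisy phantom + annotations used by several modules
small_phantom <- function() memo("small_phantom", function() {
  ph <- make_phantom(c(48, 48, 48), n_organelles = 4L, snr = 5, seed = 101L)
  ann <- sparse_annotations(ph$labels, fraction = 0.01, seed = 102L)
  list(ph = ph, ann = ann)
})

# two-phase phantom: bright cube in dark background with exact ground truth
two_phase <- function(n = 40L) {
  a <- array(0, c(n, n, n))
  gt <- array(0L, c(n, n, n))
  lo <- round(n / 4) + 1L
  hi <- round(3 * n / 4)
  a[lo:hi, lo:hi, lo:hi] <- 1
  gt[lo:hi, lo:hi, lo:hi] <- 1L
  list(volume = a, gt = gt)
}

# tiny feature stack + partition on a deterministic pattern
tiny_stack <- function() memo("tiny_stack", function() {
  d <- c(8, 8, 8)
  set.seed(7)
  a <- array(rnorm(prod(d)), d)
  fs <- feature_stack(a, list(raw = list(type = "raw"),
                              g1 = list(type = "gaussian", sigma = 1)))
  p <- slic_supervoxels(a, spacing = c(4, 4, 4), compactness = 50)
  list(fs = fs, p = p, a = a)
})
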