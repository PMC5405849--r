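# Denoising and textural feature channels.

test_that("gaussian filter: identity at sigma 0, mean preservation, kernel values", {
  set.seed(10)
  a <- array(rnorm(6^3), c(6, 6, 6))
  expect_identical(gaussian_filter(a, 0), a)
  const <- array(3.5, c(6, 6, 6))
  expect_equal(gaussian_filter(const, 2), const, tolerance = 1e-12)
  # impulse response: explicit separable kernel construction
  d <- c(11, 11, 11)
  imp <- array(0, d)
  imp[6, 6, 6] <- 1
  out <- gaussian_filter(imp, 1)
  k <- surseg:::gaussian_kernel(1, 0L) # radius 4 -> length 9
  expected <- array(0, d)
  expected[2:10, 2:10, 2:10] <- outer(outer(k, k), k)
  expect_equal(out, expected, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_error(gaussian_filter(a, -1))
})

test_that("gaussian derivatives: zero on constants, slope on ramps, order 0 = smoothing", {
  const <- array(2, c(9, 9, 9))
  expect_equal(max(abs(gaussian_derivative(const, 1, c(0, 0, 1)))), 0,
               tolerance = 1e-12)
  # ramp along x with slope 0.7: interior derivative equals the slope
  d <- c(9, 9, 15)
  ramp <- array(rep(0.7 * (0:14), each = 81), d)
  dx <- gaussian_derivative(ramp, 1.5, c(0, 0, 1))
  expect_equal(max(abs(dx[, , 7:9] - 0.7)), 0, tolerance = 1e-8)
  set.seed(11)
  a <- array(rnorm(7^3), c(7, 7, 7))
  expect_equal(gaussian_derivative(a, 1, c(0, 0, 0)), gaussian_filter(a, 1))
  expect_error(gaussian_derivative(a, 1, c(1, 1, 1)), "total order")
})

test_that("difference of Gaussians is the explicit subtraction", {
  set.seed(12)
  a <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(difference_of_gaussians(a, 1, 2),
               gaussian_filter(a, 1) - gaussian_filter(a, 2))
  const <- array(1, c(8, 8, 8))
  expect_equal(max(abs(difference_of_gaussians(const, 1, 2))), 0,
               tolerance = 1e-12)
  # impulse: centre value equals the difference of the kernel peaks
  d <- c(15, 15, 15)
  imp <- array(0, d); imp[8, 8, 8] <- 1
  k1 <- surseg:::gaussian_kernel(1, 0L)
  k2 <- surseg:::gaussian_kernel(2, 0L)
  peak <- max(k1)^3 - max(k2)^3
  expect_equal(difference_of_gaussians(imp, 1, 2)[8, 8, 8], peak,
               tolerance = 1e-12)
  expect_error(difference_of_gaussians(a, 2, 1))
})

test_that("Laplacian of Gaussian: zero on ramps, negative extremum on matched blobs", {
  const <- array(4, c(9, 9, 9))
  expect_equal(max(abs(laplacian_of_gaussian(const, 1))), 0, tolerance = 1e-10)
  ramp <- array(rep(0:16, each = 81), c(9, 9, 17))
  lg <- laplacian_of_gaussian(ramp, 1.5)
  expect_lt(max(abs(lg[, , 8:10])), 1e-8)
  # bright Gaussian blob of scale s, filtered at sigma = s: strong negative
  # centre response (analytic LoG of a Gaussian peaks negatively at 0)
  d <- c(21, 21, 21)
  s <- 2
  idx <- as.matrix(expand.grid(z = 1:21, y = 1:21, x = 1:21))
  r2 <- rowSums((idx - 11)^2)
  blob <- array(exp(-r2 / (2 * s^2)), d)
  lgb <- laplacian_of_gaussian(blob, s)
  expect_equal(which.min(lgb), which(r2 == 0))
  expect_lt(lgb[11, 11, 11], -0.1)
  expect_error(laplacian_of_gaussian(const, 0))
})

test_that("gradient magnitude: zero on constants, |slope| on ramps, flip symmetric", {
  const <- array(1, c(9, 9, 9))
  expect_equal(max(gradient_magnitude(const, 1)), 0, tolerance = 1e-10)
  ramp <- array(rep(-0.5 * (0:16), each = 81), c(9, 9, 17))
  gm <- gradient_magnitude(ramp, 1.5)
  expect_equal(max(abs(gm[, , 8:10] - 0.5)), 0, tolerance = 1e-8)
  set.seed(13)
  a <- array(rnorm(8^3), c(8, 8, 8))
  flipped <- a[8:1, , ]
  expect_equal(gradient_magnitude(flipped, 1),
               gradient_magnitude(a, 1)[8:1, , ], tolerance = 1e-12)
  expect_true(all(gradient_magnitude(a, 1) >= 0))
})

test_that("Hessian eigenvalues: analytic on a quadratic bowl, sorted", {
  const <- array(1, c(8, 8, 8))
  he <- hessian_eigenvalues(const, 1)
  expect_equal(max(abs(he$e1)), 0, tolerance = 1e-10)
  # bowl a*(x^2+y^2+z^2): Hessian = diag(2a, 2a, 2a)
  acoef <- 0.3
  d <- c(13, 13, 13)
  idx <- as.matrix(expand.grid(z = 1:13, y = 1:13, x = 1:13))
  bowl <- array(acoef * rowSums((idx - 7)^2), d)
  hb <- hessian_eigenvalues(bowl, 1)
  ctr <- 6:8
  for (e in hb) expect_equal(max(abs(e[ctr, ctr, ctr] - 2 * acoef)), 0,
                             tolerance = 1e-6)
  set.seed(14)
  r <- array(rnorm(7^3), c(7, 7, 7))
  hr <- hessian_eigenvalues(r, 1)
  expect_true(all(hr$e1 >= hr$e2 - 1e-12) && all(hr$e2 >= hr$e3 - 1e-12))
})

test_that("structure tensor eigenvalues: PSD, dominant direction on extruded edges", {
  const <- array(2, c(8, 8, 8))
  se <- structure_tensor_eigenvalues(const, 1, 1)
  expect_equal(max(abs(se$e1)), 0, tolerance = 1e-10)
  # 1D step extruded along y and z: one dominant eigenvalue near the edge
  d <- c(11, 11, 16)
  edge <- array(rep(c(rep(0, 8), rep(1, 8)), each = 121), d)
  st <- structure_tensor_eigenvalues(edge, 1, 2)
  mid <- st$e1[6, 6, 8]
  expect_gt(mid, 10 * max(st$e2[6, 6, 8], 1e-12))
  # direct tensor assembly oracle at the same voxel: gradient only along x
  gx <- gaussian_derivative(edge, 1, c(0, 0, 1))
  gz <- gaussian_derivative(edge, 1, c(1, 0, 0))
  expect_gt(abs(gx[6, 6, 8]), 100 * abs(gz[6, 6, 8]) + 1e-12)
  set.seed(15)
  r <- array(rnorm(7^3), c(7, 7, 7))
  sr <- structure_tensor_eigenvalues(r, 1, 1)
  expect_true(all(sr$e3 >= 0))
})

test_that("invariant response: single-scale equality, blob scale selection, flip symmetry", {
  set.seed(16)
  a <- array(rnorm(9^3), c(9, 9, 9))
  one <- invariant_response(a, "gradient", sigmas = 1.5)
  expect_equal(one, 1.5 * gradient_magnitude(a, 1.5))
  # dimension-adapted gamma-normalised LoG selects the blob's own scale
  d <- c(25, 25, 25)
  s <- 2.5
  idx <- as.matrix(expand.grid(z = 1:25, y = 1:25, x = 1:25))
  blob <- array(exp(-rowSums((idx - 13)^2) / (2 * s^2)), d)
  rs <- invariant_response(blob, "log", sigmas = c(1, 1.5, 2, 2.5, 3, 4),
                           return_scale = TRUE)
  expect_equal(rs$scale[13, 13, 13], 2.5)
  flipped <- a[, 9:1, ]
  expect_equal(invariant_response(flipped, "log", c(1, 2)),
               invariant_response(a, "log", c(1, 2))[, 9:1, ])
  expect_error(invariant_response(a, "log", numeric(0)))
})

test_that("TV denoising minimises the ROF objective and preserves step edges", {
  const <- array(5, c(8, 8, 8))
  expect_equal(tv_denoise(const, 0.2), const, ignore_attr = TRUE,
               tolerance = 1e-12)
  set.seed(17)
  a <- array(rnorm(6^3), c(6, 6, 6))
  # weight -> 0+: output approaches the input
  tiny <- suppressWarnings(tv_denoise(a, 1e-6))
  expect_lt(max(abs(tiny - a)), 1e-4)
  # independent convex-solver oracle on a small grid
  f <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  w <- 0.3
  out <- suppressWarnings(tv_denoise(f, w, max_iter = 2000, tol = 1e-10))
  oracle <- optim(as.vector(f), rof_objective, target = f, weight = w,
                  method = "BFGS", control = list(maxit = 3000, reltol = 1e-14))
  expect_lte(rof_objective(out, f, w), oracle$value + 1e-3)
  expect_lt(max(abs(out - array(oracle$par, dim(f)))), 0.05)
  # noisy extruded step: within-side variance drops, edge stays within 1 voxel
  d <- c(8, 8, 20)
  step <- array(rep(c(rep(0, 10), rep(1, 10)), each = 64), d)
  noisy <- step + array(rnorm(prod(d), sd = 0.15), d)
  den <- suppressWarnings(tv_denoise(noisy, 0.12))
  lhs <- den[, , 1:10]; rhs <- den[, , 11:20]
  expect_lt(var(as.vector(lhs)) + var(as.vector(rhs)),
            var(as.vector(noisy[, , 1:10])) + var(as.vector(noisy[, , 11:20])))
  profile <- apply(den, 3, mean)
  jump <- which.max(diff(profile))
  expect_true(abs(jump - 10) <= 1)
  expect_error(tv_denoise(a, 0))
})

test_that("feature stacks are deterministic and shape-preserving", {
  set.seed(18)
  a <- array(rnorm(10^3), c(10, 10, 10))
  specs <- list(raw = list(type = "raw"),
                g = list(type = "gaussian", sigma = 1.5),
                dg = list(type = "dog", sigma1 = 1, sigma2 = 2),
                h1 = list(type = "hessian_eig1", sigma = 1))
  fs1 <- feature_stack(a, specs)
  fs2 <- feature_stack(a, specs)
  for (nm in names(specs)) {
    expect_identical(fs1$channels[[nm]], fs2$channels[[nm]])
    expect_equal(dim(fs1$channels[[nm]]), c(10, 10, 10))
  }
  expect_error(feature_stack(a, list(a = list(type = "nope"))), "unknown channel")
  expect_error(feature_stack(a, list(list(type = "raw"))), "named")
})
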