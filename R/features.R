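# Denoising and textural feature channels. All filters operate in full 3D,
# preserve the grid shape, and use half-sample symmetric ("reflect") boundary
# padding. Filters are deterministic: recomputing a channel from its stored
# parameters is bit-identical.

# Sampled Gaussian (derivative) kernel. Order 0 kernels are normalised to
# sum 1; order 1 kernels have zero DC and unit first moment (exact on linear
# ramps); order 2 kernels have zero DC and respond 1 to x^2/2 (exact on
# quadratics).
gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma >= 0, order %in% 0:2)
  if (sigma == 0) {
    if (order > 0) stop("derivative kernels require sigma > 0")
    return(1)
  }
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- switch(as.character(order),
    "0" = g / sum(g),
    "1" = {
      k <- (x / sigma^2) * g
      k <- k - mean(k)
      k / sum(x * k)
    },
    "2" = {
      k <- ((x^2 - sigma^2) / sigma^4) * g
      k <- k - mean(k)
      k / sum(x^2 * k / 2)
    })
  k
}

sigma3 <- function(sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  stopifnot(length(sigma) == 3L)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  as.numeric(sigma)
}

convolve_separable <- function(a, kernels) {
  d <- dim(a)
  out <- as.vector(a)
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (length(k) == 1L && k[1] == 1) next
    out <- cpp_convolve_axis(out, d, k, ax - 1L)
  }
  array(out, dim = d)
}

#' Gaussian smoothing
#'
#' Separable 3D Gaussian convolution with reflect boundary handling.
#' `sigma = 0` (on any axis) leaves that axis untouched, so `sigma = 0`
#' overall is the identity.
#'
#' @param v a [volume] or 3D array.
#' @param sigma scalar or per-axis `(z, y, x)` standard deviation in voxels.
#' @return A 3D array of the same shape.
#' @export
gaussian_filter <- function(v, sigma) {
  a <- check_finite(as_array3d(v))
  s <- sigma3(sigma)
  convolve_separable(a, lapply(s, gaussian_kernel, order = 0L))
}

#' Gaussian derivative filter
#'
#' Derivative-of-Gaussian response with per-axis derivative orders
#' `(z, y, x)`; the total order must not exceed 2. Order `(0,0,0)` equals
#' [gaussian_filter()].
#'
#' @inheritParams gaussian_filter
#' @param order integer length-3 derivative order per axis, total <= 2.
#' @return A 3D array of the same shape.
#' @export
gaussian_derivative <- function(v, sigma, order) {
  a <- check_finite(as_array3d(v))
  s <- sigma3(sigma)
  order <- as.integer(order)
  stopifnot(length(order) == 3L)
  if (any(order < 0) || sum(order) > 2L)
    stop("derivative orders must be >= 0 with total order <= 2")
  convolve_separable(a, Map(gaussian_kernel, s, order))
}

#' Difference of Gaussians
#'
#' `gaussian_filter(v, sigma1) - gaussian_filter(v, sigma2)`; a band-pass
#' blob detector. Requires `sigma1 < sigma2`.
#'
#' @inheritParams gaussian_filter
#' @param sigma1,sigma2 inner and outer scales, `sigma1 < sigma2`.
#' @return A 3D array of the same shape.
#' @export
difference_of_gaussians <- function(v, sigma1, sigma2) {
  if (!all(sigma3(sigma1) < sigma3(sigma2)))
    stop("sigma1 must be < sigma2")
  gaussian_filter(v, sigma1) - gaussian_filter(v, sigma2)
}

#' Laplacian of Gaussian
#'
#' Sum of the three unmixed second Gaussian derivatives. Responds ~0 on
#' linear ramps and strongly (negatively) at the centre of bright blobs of
#' matching scale.
#'
#' @inheritParams gaussian_filter
#' @return A 3D array of the same shape.
#' @export
laplacian_of_gaussian <- function(v, sigma) {
  if (any(sigma3(sigma) <= 0)) stop("sigma must be > 0")
  gaussian_derivative(v, sigma, c(2, 0, 0)) +
    gaussian_derivative(v, sigma, c(0, 2, 0)) +
    gaussian_derivative(v, sigma, c(0, 0, 2))
}

#' Gaussian gradient magnitude
#'
#' Euclidean norm of the three first Gaussian derivatives; non-negative,
#' and approximately `|m|` in the interior of a ramp of slope `m`.
#'
#' @inheritParams gaussian_filter
#' @return A 3D array of the same shape.
#' @export
gradient_magnitude <- function(v, sigma) {
  if (any(sigma3(sigma) <= 0)) stop("sigma must be > 0")
  gz <- gaussian_derivative(v, sigma, c(1, 0, 0))
  gy <- gaussian_derivative(v, sigma, c(0, 1, 0))
  gx <- gaussian_derivative(v, sigma, c(0, 0, 1))
  sqrt(gz^2 + gy^2 + gx^2)
}

#' Eigenvalues of the Gaussian Hessian
#'
#' Per-voxel eigenvalues of the 3x3 matrix of second Gaussian derivatives,
#' sorted descending by signed value. Useful for plate/tube/blob texture
#' channels.
#'
#' @inheritParams gaussian_filter
#' @return A list of three 3D arrays `e1 >= e2 >= e3`.
#' @export
hessian_eigenvalues <- function(v, sigma) {
  if (any(sigma3(sigma) <= 0)) stop("sigma must be > 0")
  d <- dim(as_array3d(v))
  hzz <- gaussian_derivative(v, sigma, c(2, 0, 0))
  hyy <- gaussian_derivative(v, sigma, c(0, 2, 0))
  hxx <- gaussian_derivative(v, sigma, c(0, 0, 2))
  hzy <- gaussian_derivative(v, sigma, c(1, 1, 0))
  hzx <- gaussian_derivative(v, sigma, c(1, 0, 1))
  hyx <- gaussian_derivative(v, sigma, c(0, 1, 1))
  e <- cpp_sym3_eigenvalues(as.vector(hzz), as.vector(hzy), as.vector(hzx),
                            as.vector(hyy), as.vector(hyx), as.vector(hxx))
  list(e1 = array(e[, 1], d), e2 = array(e[, 2], d), e3 = array(e[, 3], d))
}

#' Eigenvalues of the structure tensor
#'
#' Gradient outer products at scale `sigma_grad`, window-averaged with a
#' Gaussian of scale `sigma_window`; eigenvalues are sorted descending and
#' are non-negative (the tensor is positive semi-definite).
#'
#' @inheritParams gaussian_filter
#' @param sigma_grad derivative scale (voxels).
#' @param sigma_window integration window scale (voxels).
#' @return A list of three 3D arrays `e1 >= e2 >= e3 >= 0`.
#' @export
structure_tensor_eigenvalues <- function(v, sigma_grad, sigma_window) {
  if (any(sigma3(sigma_grad) <= 0) || any(sigma3(sigma_window) <= 0))
    stop("both sigmas must be > 0")
  d <- dim(as_array3d(v))
  gz <- gaussian_derivative(v, sigma_grad, c(1, 0, 0))
  gy <- gaussian_derivative(v, sigma_grad, c(0, 1, 0))
  gx <- gaussian_derivative(v, sigma_grad, c(0, 0, 1))
  w <- function(x) gaussian_filter(x, sigma_window)
  e <- cpp_sym3_eigenvalues(as.vector(w(gz * gz)), as.vector(w(gz * gy)),
                            as.vector(w(gz * gx)), as.vector(w(gy * gy)),
                            as.vector(w(gy * gx)), as.vector(w(gx * gx)))
  e[e < 0] <- 0 # clip tiny negative round-off; tensor is PSD
  list(e1 = array(e[, 1], d), e2 = array(e[, 2], d), e3 = array(e[, 3], d))
}

#' Rotation- and scale-invariant filter response
#'
#' Per-voxel maximum of gamma-normalised responses of a rotation-invariant
#' base filter over a list of scales. The base responses are
#' `sigma^(5/2) * (-LoG)` (so bright blobs peak positively) or
#' `sigma * |grad|`; taking the max over normalised scales makes the
#' channel scale-invariant, and the bases themselves are
#' rotation-invariant. The LoG exponent is the dimension-adapted
#' `(D + 2) / 2` with `D = 3`, which makes the response of a Gaussian blob
#' of scale `s` peak at filter scale `s` (the classic exponent 2 is the
#' 2D case).
#'
#' @inheritParams gaussian_filter
#' @param base_filter `"log"` or `"gradient"`.
#' @param sigmas numeric vector of scales (>= 1 entry).
#' @param return_scale if `TRUE`, also return the argmax scale per voxel.
#' @return A 3D array, or a list `(response, scale)` if `return_scale`.
#' @export
invariant_response <- function(v, base_filter = c("log", "gradient"), sigmas,
                               return_scale = FALSE) {
  base_filter <- match.arg(base_filter)
  if (length(sigmas) < 1L) stop("at least one scale is required")
  best <- NULL
  best_s <- NULL
  for (s in sigmas) {
    r <- switch(base_filter,
      log = s^2.5 * (-laplacian_of_gaussian(v, s)),
      gradient = s * gradient_magnitude(v, s))
    if (is.null(best)) {
      best <- r
      best_s <- array(s, dim(r))
    } else {
      upd <- r > best
      best[upd] <- r[upd]
      best_s[upd] <- s
    }
  }
  if (return_scale) list(response = best, scale = best_s) else best
}

#' Total variation denoising (Chambolle dual projection)
#'
#' Minimises the ROF objective `0.5 * ||u - f||^2 + weight * TV(u)` (TV =
#' sum of Euclidean norms of forward-difference gradients, Neumann
#' boundaries) with Chambolle's dual projection scheme in 3D. Larger
#' `weight` denoises more; the result is piecewise smooth with strong
#' edges preserved, which suits feature extraction better than Gaussian
#' over-smoothing. The iteration stops when the relative change of the primal energy
#' falls below `tol`; if `max_iter` is reached first the best iterate is
#' returned with a `converged = FALSE` attribute and a warning.
#'
#' @param v a [volume] or 3D array.
#' @param weight regularisation strength (> 0).
#' @param max_iter maximum iterations.
#' @param tol relative energy-change convergence threshold.
#' @return A 3D array with attribute `converged`.
#' @export
tv_denoise <- function(v, weight, max_iter = 200L, tol = 1e-4) {
  a <- check_finite(as_array3d(v))
  if (weight <= 0) stop("weight must be > 0")
  d <- dim(a)
  shift_diff <- function(x, ax) {
    # forward difference, zero on the last slice (Neumann boundary)
    n <- dim(x)[ax]
    g <- array(0, dim(x))
    if (n < 2L) return(g)
    if (ax == 1L) g[1:(n - 1), , ] <- x[2:n, , ] - x[1:(n - 1), , ]
    if (ax == 2L) g[, 1:(n - 1), ] <- x[, 2:n, ] - x[, 1:(n - 1), ]
    if (ax == 3L) g[, , 1:(n - 1)] <- x[, , 2:n] - x[, , 1:(n - 1)]
    g
  }
  adj_div <- function(p, ax) {
    # negative adjoint of shift_diff (divergence contribution)
    n <- dim(p)[ax]
    o <- array(0, dim(p))
    if (n < 2L) return(o)
    if (ax == 1L) { o[1:(n - 1), , ] <- p[1:(n - 1), , ]; o[2:n, , ] <- o[2:n, , ] - p[1:(n - 1), , ] }
    if (ax == 2L) { o[, 1:(n - 1), ] <- p[, 1:(n - 1), ]; o[, 2:n, ] <- o[, 2:n, ] - p[, 1:(n - 1), ] }
    if (ax == 3L) { o[, , 1:(n - 1)] <- p[, , 1:(n - 1)]; o[, , 2:n] <- o[, , 2:n] - p[, , 1:(n - 1)] }
    o
  }
  p1 <- array(0, d); p2 <- array(0, d); p3 <- array(0, d)
  tau <- 1 / 6 # 1 / (2 * ndim)
  out <- a
  e_init <- NA_real_
  e_prev <- NA_real_
  converged <- FALSE
  n_total <- length(a)
  for (i in seq_len(max_iter)) {
    if (i > 1L) {
      dvg <- -(adj_div(p1, 1L) + adj_div(p2, 2L) + adj_div(p3, 3L))
      out <- a + dvg
      e <- sum(dvg^2)
    } else e <- 0
    g1 <- shift_diff(out, 1L); g2 <- shift_diff(out, 2L); g3 <- shift_diff(out, 3L)
    nrm <- sqrt(g1^2 + g2^2 + g3^2)
    e <- (e + weight * sum(nrm)) / n_total
    scl <- 1 + nrm * (tau / weight)
    p1 <- (p1 - tau * g1) / scl
    p2 <- (p2 - tau * g2) / scl
    p3 <- (p3 - tau * g3) / scl
    if (i == 1L) {
      e_init <- e
      e_prev <- e
    } else {
      # zero-energy inputs (constants) converge immediately
      if (abs(e_prev - e) <= tol * max(e_init, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      e_prev <- e
    }
  }
  if (!converged && max_iter > 2L)
    warning("TV denoising did not converge within max_iter; returning best iterate")
  attr(out, "converged") <- converged
  out
}

#' Compute a named stack of feature channels
#'
#' Each channel spec is a list with a `type` and the parameters of the
#' corresponding filter, e.g. `list(type = "gaussian", sigma = 2)`.
#' Supported types: `raw`, `gaussian`, `tv`, `gaussian_derivative`, `dog`,
#' `log`, `gradient`, `hessian_eig1/2/3`, `structure_eig1/2/3`,
#' `invariant_log`, `invariant_gradient`.
#'
#' @param v a [volume] or 3D array.
#' @param channels named list of channel specs; names must be unique.
#' @return An object of class `feature_stack`: list with `channels` (named
#'   list of 3D arrays), `params`, and `shape`.
#' @export
feature_stack <- function(v, channels) {
  a <- check_finite(as_array3d(v))
  if (is.null(names(channels)) || anyDuplicated(names(channels)))
    stop("channels must be a uniquely named list")
  out <- vector("list", length(channels))
  names(out) <- names(channels)
  for (nm in names(channels)) {
    spec <- channels[[nm]]
    type <- spec$type
    out[[nm]] <- switch(type,
      raw = a,
      gaussian = gaussian_filter(a, spec$sigma),
      tv = tv_denoise(a, spec$weight,
                      max_iter = spec$max_iter %||% 200L,
                      tol = spec$tol %||% 1e-4),
      gaussian_derivative = gaussian_derivative(a, spec$sigma, spec$order),
      dog = difference_of_gaussians(a, spec$sigma1, spec$sigma2),
      log = laplacian_of_gaussian(a, spec$sigma),
      gradient = gradient_magnitude(a, spec$sigma),
      hessian_eig1 = hessian_eigenvalues(a, spec$sigma)$e1,
      hessian_eig2 = hessian_eigenvalues(a, spec$sigma)$e2,
      hessian_eig3 = hessian_eigenvalues(a, spec$sigma)$e3,
      structure_eig1 = structure_tensor_eigenvalues(a, spec$sigma_grad, spec$sigma_window)$e1,
      structure_eig2 = structure_tensor_eigenvalues(a, spec$sigma_grad, spec$sigma_window)$e2,
      structure_eig3 = structure_tensor_eigenvalues(a, spec$sigma_grad, spec$sigma_window)$e3,
      invariant_log = invariant_response(a, "log", spec$sigmas),
      invariant_gradient = invariant_response(a, "gradient", spec$sigmas),
      stop("unknown channel type: ", type))
    attr(out[[nm]], "converged") <- NULL
  }
  structure(list(channels = out, params = channels, shape = dim(a)),
            class = "feature_stack")
}

#' Default feature channel set for segmentation
#'
#' Raw intensity plus Gaussian smoothing at two scales and the gradient
#' magnitude: a small, robust set suited to intensity-separated phases.
#'
#' @return A named list of channel specs for [feature_stack()].
#' @export
default_channels <- function() {
  list(raw = list(type = "raw"),
       gauss1 = list(type = "gaussian", sigma = 1),
       gauss2 = list(type = "gaussian", sigma = 2),
       gradmag = list(type = "gradient", sigma = 1))
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d channel(s) on %s grid: %s\n",
              length(x$channels), paste(x$shape, collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
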