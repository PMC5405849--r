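# Synthetic cellular phantoms with voxel-exact ground truth, emulating the
# piecewise-smooth, low-SNR appearance of cryo soft X-ray / electron
# tomograms: background ice, cell body, nucleus, nucleoli and organelles
# with distinct mean intensities, a smooth low-frequency bias field, and
# additive Gaussian noise. Every stage of the package is testable on these
# phantoms without any data download.

PHANTOM_LABELS <- c(background = 0L, cytoplasm = 1L, nucleus = 2L,
                    nucleolus = 3L, organelle = 4L)
PHANTOM_MEANS <- c(0.10, 0.35, 0.55, 0.75, 0.90)

ellipsoid_mask <- function(d, centre, radii) {
  z <- (seq_len(d[1]) - centre[1]) / radii[1]
  y <- (seq_len(d[2]) - centre[2]) / radii[2]
  x <- (seq_len(d[3]) - centre[3]) / radii[3]
  outer(outer(z^2, y^2, "+"), x^2, "+") <= 1
}

#' Generate a cellular phantom volume with ground truth
#'
#' Builds a piecewise-smooth phantom: an ellipsoidal cell body containing
#' an ellipsoidal nucleus with two nucleoli, plus `n_organelles`
#' non-overlapping random ellipsoids in the cytoplasm. Phase mean
#' intensities are `(0.10, 0.35, 0.55, 0.75, 0.90)` for background,
#' cytoplasm, nucleus, nucleolus and organelle. A smooth random bias field
#' (amplitude 0.05, below half the smallest phase gap) makes regions
#' smooth rather than constant while keeping the noiseless phases exactly
#' recoverable by midpoint thresholding. Gaussian noise is added with
#' `sd = sd(clean) / snr`; at the default `snr = 5` adjacent phase means
#' are >= 2 noise-sd apart, so segmentation is well-posed but not trivial.
#'
#' @param shape integer length-3 `(nz, ny, nx)`, each >= 32.
#' @param n_organelles number of organelles to place (>= 0); if placement
#'   without overlap fails after bounded retries, fewer are placed with a
#'   warning.
#' @param snr signal-to-noise ratio `sd(clean) / sd(noise)`; `Inf` for a
#'   noiseless phantom.
#' @param seed RNG seed; the same seed reproduces the phantom exactly.
#' @param missing_wedge if `TRUE`, blur the clean signal anisotropically
#'   along z (sigma 1.5 voxels) to mimic missing-wedge elongation.
#' @return List of class `phantom`: `volume` (a [volume]), `labels`
#'   (ground-truth 3D integer grid, values 0..4), `means`, `noise_sd`.
#' @export
make_phantom <- function(shape = c(64, 64, 64), n_organelles = 8L, snr = 5,
                         seed = 1L, missing_wedge = FALSE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (any(shape < 32L)) stop("shape must be >= 32 on every axis")
  if (n_organelles < 0L) stop("n_organelles must be >= 0")
  d <- shape
  with_seed(seed, {
    gt <- array(PHANTOM_LABELS[["background"]], d)
    centre <- d / 2
    cell <- ellipsoid_mask(d, centre, 0.42 * d)
    gt[cell] <- PHANTOM_LABELS[["cytoplasm"]]
    nuc_centre <- centre + 0.08 * d * runif(3, -1, 1)
    nucleus <- ellipsoid_mask(d, nuc_centre, 0.20 * d)
    gt[nucleus & cell] <- PHANTOM_LABELS[["nucleus"]]
    for (i in 1:2) {
      nc <- nuc_centre + 0.08 * d * runif(3, -1, 1)
      nl <- ellipsoid_mask(d, nc, pmax(2.5, 0.05 * d))
      gt[nl & nucleus & cell] <- PHANTOM_LABELS[["nucleolus"]]
    }
    placed <- 0L
    org_masks <- gt == -99L # all FALSE
    if (n_organelles > 0L) {
      cyto <- gt == PHANTOM_LABELS[["cytoplasm"]]
      for (i in seq_len(n_organelles)) {
        ok <- FALSE
        for (try in 1:100) {
          ctr <- runif(3) * (d - 8) + 4
          rad <- pmax(2, runif(3, 0.04, 0.08) * min(d))
          m <- ellipsoid_mask(d, ctr, rad)
          if (all(cyto[m]) && !any(org_masks[m])) {
            org_masks <- org_masks | m
            ok <- TRUE
            break
          }
        }
        if (ok) placed <- placed + 1L
      }
      if (placed < n_organelles)
        warning("placed only ", placed, " of ", n_organelles,
                " organelles without overlap")
      gt[org_masks] <- PHANTOM_LABELS[["organelle"]]
    }
    clean <- array(PHANTOM_MEANS[gt + 1L], d)
    # smooth low-frequency bias field, amplitude 0.05 (< half the smallest
    # phase gap, so midpoint thresholding still recovers phases exactly)
    bias <- gaussian_filter(array(rnorm(prod(d)), d), pmax(4, d / 8))
    bias <- 0.05 * bias / max(abs(bias))
    clean <- clean + bias
    if (missing_wedge) clean <- gaussian_filter(clean, c(1.5, 0, 0))
    noise_sd <- if (is.finite(snr)) sd(clean) / snr else 0
    vol <- clean
    if (noise_sd > 0) vol <- vol + rnorm(prod(d), sd = noise_sd)
    structure(list(volume = volume(array(vol, d)), labels = gt,
                   means = PHANTOM_MEANS, noise_sd = noise_sd,
                   n_organelles_placed = placed),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s grid, %d organelles, noise sd %.4g\n",
              paste(dim(x$labels), collapse = "x"),
              x$n_organelles_placed, x$noise_sd))
  invisible(x)
}

#' Sparse stroke-like annotations from ground truth
#'
#' Emulates brief pen annotations: short straight runs of voxels sampled
#' inside each ground-truth class, allocated across classes proportionally
#' to class size (every non-empty class gets at least one stroke). The
#' total labelled fraction never exceeds `fraction`.
#'
#' @param gt ground-truth 3D integer label grid.
#' @param fraction target labelled fraction of all voxels, in `(0, 0.1]`.
#' @param seed RNG seed.
#' @param stroke_len maximum stroke length in voxels.
#' @return An `annotation_volume` (provenance "manual").
#' @export
sparse_annotations <- function(gt, fraction = 0.01, seed = 1L, stroke_len = 15L) {
  if (fraction <= 0 || fraction > 0.1) stop("fraction must lie in (0, 0.1]")
  d <- dim(gt)
  ann <- annotation_volume(d)
  n <- prod(d)
  classes <- sort(unique(as.vector(gt)))
  classes <- classes[classes >= 0]
  sizes <- vapply(classes, function(cl) sum(gt == cl), numeric(1))
  if (any(sizes == 0)) {
    warning("skipping empty class(es): ",
            paste(classes[sizes == 0], collapse = ", "))
    classes <- classes[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  budget <- floor(fraction * n)
  quota <- pmax(1L, floor(budget * sizes / sum(sizes)))
  while (sum(quota) > budget && any(quota > 1L)) {
    i <- which.max(quota)
    quota[i] <- quota[i] - 1L
  }
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      idx_pool <- which(gt == cl)
      labelled <- 0L
      guard <- 0L
      while (labelled < quota[ci] && guard < 50L * quota[ci]) {
        guard <- guard + 1L
        start <- idx_pool[sample.int(length(idx_pool), 1L)]
        z <- ((start - 1L) %% d[1]) + 1L
        y <- (((start - 1L) %/% d[1]) %% d[2]) + 1L
        x <- ((start - 1L) %/% (d[1] * d[2])) + 1L
        dir <- dirs[sample.int(nrow(dirs), 1L), ] * sample(c(-1L, 1L), 1L)
        for (s in 0:(stroke_len - 1L)) {
          p <- c(z, y, x) + s * dir
          if (any(p < 1L) || any(p > d)) break
          if (gt[p[1], p[2], p[3]] != cl) break
          if (ann$labels[p[1], p[2], p[3]] < 0L) {
            if (labelled >= quota[ci]) break
            ann$labels[p[1], p[2], p[3]] <- cl
            ann$provenance[p[1], p[2], p[3]] <- PROV_MANUAL
            labelled <- labelled + 1L
          }
        }
      }
    }
  })
  ann
}
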