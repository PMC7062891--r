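#' Build a box-region brain phantom
#'
#' A schematic analysis grid with named rectangular regions carrying
#' per-regressor effect amplitudes.  The default phantom holds two disjoint
#' 4 x 4 x 4-voxel boxes: `"VS"`, a ventral-striatum-like region placed at
#' the ventral-anterior midline, and `"VTA_SN"`, a dopaminergic-midbrain-like
#' region placed ventrally and posterior to it.  The affine is RAS with the
#' grid centred at the origin, in the spirit of MNI space.
#'
#' @param shape integer grid dimensions (x, y, z).
#' @param voxel_size voxel edge lengths in mm (scalar or length 3).
#' @param regions named list; each element is a list with `min` and `max`
#'   voxel index triples (inclusive bounds).
#' @return An object of class `phantom` with `shape`, `voxel_size`, `affine`
#'   and a named list of logical `masks`.
#' @export
build_phantom <- function(shape = c(20L, 24L, 18L), voxel_size = 3,
                          regions = default_phantom_regions(shape)) {
  shape <- as.integer(shape)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  masks <- list()
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    if (any(rg$min < 1L) || any(rg$max > shape) || any(rg$min > rg$max))
      stop_tdbold("region '", nm, "' lies outside the grid")
    m <- array(FALSE, dim = shape)
    m[rg$min[1]:rg$max[1], rg$min[2]:rg$max[2], rg$min[3]:rg$max[3]] <- TRUE
    masks[[nm]] <- m
  }
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine,
                 masks = masks),
            class = "phantom")
}

#' Default phantom regions
#' @param shape grid dimensions.
#' @return Named list of region boxes for [build_phantom()].
#' @export
default_phantom_regions <- function(shape = c(20L, 24L, 18L)) {
  c0 <- pmax(1L, round(shape / 2))
  list(
    VS = list(min = c(c0[1] - 2L, c0[2] + 2L, c0[3] - 4L),
              max = c(c0[1] + 1L, c0[2] + 5L, c0[3] - 1L)),
    VTA_SN = list(min = c(c0[1] - 2L, c0[2] - 6L, c0[3] - 6L),
                  max = c(c0[1] + 1L, c0[2] - 3L, c0[3] - 3L))
  )
}

#' Region volume in cubic millimetres
#' @param phantom a [build_phantom()] result.
#' @param region region name.
#' @return Scalar volume (voxel count times voxel volume).
#' @export
region_volume <- function(phantom, region) {
  sum(phantom$masks[[region]]) * prod(phantom$voxel_size)
}

#' Temporal noise specification
#'
#' Realizes the noise process the estimator assumes: Gaussian innovations of
#' standard deviation `sd` passed through a first-order autoregressive
#' filter with coefficient `phi` (stationary start), plus an optional slow
#' sinusoidal drift, on top of a constant baseline.
#'
#' @param sd innovation standard deviation, in percent-signal units.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param drift_amplitude amplitude of the slow drift (same units; 0 = none).
#' @param drift_period drift period in seconds.
#' @param baseline constant baseline level.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 1, phi = 0.2, drift_amplitude = 0,
                       drift_period = 300, baseline = 100) {
  if (abs(phi) >= 1) stop_tdbold("|phi| must be below 1")
  if (sd < 0) stop_tdbold("sd must be non-negative")
  structure(list(sd = sd, phi = phi, drift_amplitude = drift_amplitude,
                 drift_period = drift_period, baseline = baseline),
            class = "noise_spec")
}

# stationary AR(1) series, one column per voxel
ar1_noise <- function(n_time, n_voxels, sd, phi) {
  if (sd == 0) return(matrix(0, n_time, n_voxels))
  w <- matrix(stats::rnorm(n_time * n_voxels, sd = sd), n_time, n_voxels)
  if (phi != 0) {
    w[1, ] <- w[1, ] / sqrt(1 - phi^2)  # stationary start
    w <- stats::filter(w, phi, method = "recursive")
  }
  matrix(w, n_time, n_voxels)
}

#' Simulate one subject's 4-D BOLD series
#'
#' Every voxel's series is baseline + sum over regions/regressors of
#' amplitude x regressor (for voxels inside the region) + AR(1) noise +
#' optional drift.  Deterministic given `seed`.
#'
#' @param phantom a [build_phantom()].
#' @param design an `fmri_design`; its task columns drive the signal.
#' @param noise a [noise_spec()].
#' @param amplitudes named list: `amplitudes$REGION$regressor = value` in
#'   the same units as the noise sd.
#' @param seed integer seed.
#' @param subject optional subject identifier stored with the series.
#' @return A `volume_series`: 4-D array (x, y, z, t) with attributes `tr`,
#'   `affine`, `subject`.
#' @export
simulate_subject <- function(phantom, design, noise = noise_spec(),
                             amplitudes = list(), seed = 1L,
                             subject = "sub-01") {
  n_t <- design$n_scans
  shape <- phantom$shape
  n_vox <- prod(shape)
  signal <- matrix(0, n_t, n_vox)
  for (rg in names(amplitudes)) {
    if (!rg %in% names(phantom$masks))
      stop_tdbold("amplitude for unknown region '", rg, "'")
    mask_idx <- which(phantom$masks[[rg]])
    for (cn in names(amplitudes[[rg]])) {
      if (!cn %in% colnames(design$X))
        stop_tdbold("amplitude for unknown regressor '", cn, "'")
      signal[, mask_idx] <- signal[, mask_idx] +
        amplitudes[[rg]][[cn]] * design$X[, cn]
    }
  }
  eps <- with_seed(seed, ar1_noise(n_t, n_vox, noise$sd, noise$phi))
  y <- noise$baseline + signal + eps
  if (noise$drift_amplitude != 0) {
    tt <- (seq_len(n_t) - 1) * design$tr
    y <- y + noise$drift_amplitude * sin(2 * pi * tt / noise$drift_period)
  }
  vol <- array(t(y), dim = c(shape, n_t))
  structure(vol, tr = design$tr, affine = phantom$affine, subject = subject,
            class = c("volume_series", "array"))
}

#' Cohort specification
#' @param n_subjects number of subjects, at least 1.
#' @param between_sd between-subject standard deviation of every planted
#'   amplitude (scalar).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, between_sd = 0.1, seed = 1L) {
  if (n_subjects < 1) stop_tdbold("n_subjects must be at least 1")
  if (between_sd < 0) stop_tdbold("between_sd must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 between_sd = between_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of subjects
#'
#' Per-subject amplitudes are drawn as group amplitude plus a Gaussian
#' deviation with the cohort's between-subject sd (modelling random effects
#' of subjects); each subject's data are then generated by
#' [simulate_subject()] with a seed derived from the master seed.
#'
#' @param phantom,design,noise as in [simulate_subject()].
#' @param cohort a [cohort_spec()].
#' @param group_amplitudes named list of group-mean amplitudes, same layout
#'   as `amplitudes` in [simulate_subject()].
#' @return List of `volume_series`, one per subject.
#' @export
simulate_cohort <- function(phantom, design, noise = noise_spec(),
                            cohort, group_amplitudes = list()) {
  lapply(seq_len(cohort$n_subjects), function(i) {
    amp_i <- group_amplitudes
    if (cohort$between_sd > 0) {
      k <- 0L
      for (rg in names(amp_i)) for (cn in names(amp_i[[rg]])) {
        k <- k + 1L
        dev <- with_seed(derive_seed(cohort$seed, 1000L * i + k),
                         stats::rnorm(1, sd = cohort$between_sd))
        amp_i[[rg]][[cn]] <- amp_i[[rg]][[cn]] + dev
      }
    }
    simulate_subject(phantom, design, noise, amp_i,
                     seed = derive_seed(cohort$seed, i),
                     subject = sprintf("sub-%02d", i))
  })
}

# 1-D Gaussian smoothing matrix along an axis, balanced to be (numerically)
# doubly stochastic so that flat images stay flat and the spatial mean is
# preserved at truncated borders (D-B3 edge handling).
smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma_vox^2))
  half <- ceiling(4 * sigma_vox)
  K[abs(d) > half] <- 0
  for (it in 1:100) {  # Sinkhorn balancing; symmetric input converges fast
    K <- K / rowSums(K)
    K <- t(t(K) / colSums(K))
  }
  K / rowSums(K)
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing of each volume, with
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\log 2})} per axis in voxel units.
#' `fwhm_mm = 0` is the identity.  Border kernels are mass-balanced so a
#' flat image stays flat and each volume's spatial mean is preserved.
#'
#' @param x a `volume_series` (4-D) or a 3-D statistic/contrast map.
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_size voxel sizes in mm; taken from the attribute `voxel_size`
#'   or derived from the affine when present.
#' @return Object of the same shape and class as `x`.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size = NULL) {
  if (fwhm_mm < 0) stop_tdbold("fwhm must be non-negative")
  if (fwhm_mm == 0) return(x)
  if (is.null(voxel_size)) {
    aff <- attr(x, "affine")
    voxel_size <- if (!is.null(aff)) abs(diag(aff)[1:3]) else rep(1, 3)
  }
  voxel_size <- rep(voxel_size, length.out = 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  d <- dim(x)
  at <- attributes(x)
  if (length(d) == 3L) {
    out <- x
    for (ax in 1:3) out <- apply_axis(out, smooth_matrix(d[ax], sigma[ax]), ax)
  } else if (length(d) == 4L) {
    out <- x
    for (ax in 1:3) {
      M <- smooth_matrix(d[ax], sigma[ax])
      out <- apply_axis(out, M, ax)
    }
  } else stop_tdbold("expected a 3-D map or 4-D series")
  attributes(out) <- at
  out
}

#' Write a 4-D series or 3-D map as NIfTI-1
#'
#' @param x a `volume_series` or 3-D array with an `affine` attribute.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr repetition time recorded in the time-axis header field;
#'   defaults to the `tr` attribute.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, tr = attr(x, "tr")) {
  aff <- attr(x, "affine") %||% diag(4)
  pixdim <- c(abs(diag(aff)[1:3]), if (!is.null(tr)) tr else 1)
  img <- RNifti::asNifti(unclass(x))
  img <- RNifti::`pixdim<-`(img, pixdim[seq_along(dim(x))])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#' @param path file path.
#' @return Array with `tr` attribute when 4-D.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (length(dim(arr)) == 4L) attr(arr, "tr") <- pd[4]
  arr
}
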