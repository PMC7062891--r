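#' First-level GLM with AR(1) prewhitening
#'
#' Fits the design to every voxel's time series by ordinary least squares,
#' estimates a single AR(1) coefficient from the lag-1 autocorrelation of
#' the residuals pooled over voxels, whitens data and design with the
#' corresponding filter (first row scaled by \eqn{\sqrt{1-\rho^2}}, later
#' rows \eqn{y_t - \rho y_{t-1}}), and re-estimates the coefficients on the
#' whitened system.  Degrees of freedom are scans minus design rank, with
#' no correction for the AR estimation.
#'
#' @param series a `volume_series` (4-D array) or a scans x voxels matrix.
#' @param design an `fmri_design` (or plain matrix with column names).
#' @param ar `"pooled"` (default), `"voxelwise"`, or `"none"` (plain OLS).
#' @return A `first_level_fit`: coefficient matrix `beta` (columns x
#'   voxels), `sigma2`, `rho`, `dof`, `XtXinv`, grid `shape`, column names.
#' @export
fit_first_level <- function(series, design, ar = c("pooled", "voxelwise", "none")) {
  ar <- match.arg(ar)
  X <- if (inherits(design, "fmri_design")) design$X else design
  shape <- NULL
  if (is.array(series) && length(dim(series)) == 4L) {
    shape <- dim(series)[1:3]
    Y <- t(matrix(series, nrow = prod(shape)))
  } else {
    Y <- as.matrix(series)
  }
  n <- nrow(Y)
  if (n != nrow(X)) stop_tdbold("series length does not match design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_tdbold("design is rank deficient; collinear column(s): ",
                paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  rho <- 0
  if (ar != "none") {
    num <- colSums(res[-1, , drop = FALSE] * res[-n, , drop = FALSE])
    den <- colSums(res^2)
    rho <- if (ar == "pooled") sum(num) / sum(den) else ifelse(den > 0, num / den, 0)
  }
  whiten <- function(M, r) {
    W <- M[-1, , drop = FALSE] - r * M[-nrow(M), , drop = FALSE]
    rbind(sqrt(1 - r^2) * M[1, , drop = FALSE], W)
  }
  if (ar == "voxelwise") {
    # whiten each voxel with its own coefficient; design varies per voxel,
    # so fall back to a loop (exposed option, not the default path)
    p <- ncol(X)
    beta <- matrix(NA_real_, p, ncol(Y))
    sigma2 <- numeric(ncol(Y))
    dof <- n - qx$rank
    XtXinv_ref <- NULL
    for (v in seq_len(ncol(Y))) {
      Xw <- whiten(X, rho[v]); yw <- whiten(Y[, v, drop = FALSE], rho[v])
      qv <- qr(Xw)
      beta[, v] <- qr.coef(qv, yw)
      sigma2[v] <- sum(qr.resid(qv, yw)^2) / dof
    }
    Xw <- whiten(X, mean(rho))
    XtXinv <- chol2inv(chol(crossprod(Xw)))
  } else {
    Xw <- whiten(X, rho); Yw <- whiten(Y, rho)
    qw <- qr(Xw)
    beta <- qr.coef(qw, Yw)
    dof <- n - qw$rank
    sigma2 <- colSums(qr.resid(qw, Yw)^2) / dof
    XtXinv <- chol2inv(chol(crossprod(Xw)))
  }
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, rho = rho, dof = dof,
                 XtXinv = XtXinv, shape = shape, columns = colnames(X)),
            class = "first_level_fit")
}

#' Whitened residual series (diagnostic)
#'
#' Re-derives the whitened residuals of a fitted model, e.g. to check that
#' prewhitening removed the lag-1 serial correlation.
#'
#' @param series,design as in [fit_first_level()].
#' @param fit the corresponding `first_level_fit`.
#' @return Matrix of whitened residuals (scans-after-whitening x voxels).
#' @export
whitened_residuals <- function(series, design, fit) {
  X <- if (inherits(design, "fmri_design")) design$X else design
  Y <- if (is.array(series) && length(dim(series)) == 4L)
    t(matrix(series, nrow = prod(dim(series)[1:3]))) else as.matrix(series)
  r <- if (length(fit$rho) == 1L) fit$rho else mean(fit$rho)
  wh <- function(M) rbind(sqrt(1 - r^2) * M[1, , drop = FALSE],
                          M[-1, , drop = FALSE] - r * M[-nrow(M), , drop = FALSE])
  qr.resid(qr(wh(X)), wh(Y))
}

map_from_vector <- function(v, shape) {
  if (is.null(shape)) return(v)
  array(v, dim = shape)
}

#' Contrast effect and t maps
#'
#' @param fit a [fit_first_level()] result.
#' @param weights named numeric vector or list of contrast weights keyed to
#'   design columns; unnamed columns get weight 0.
#' @return A `contrast_result`: `effect` and `t` maps (arrays when the fit
#'   came from a 4-D series), `se`, `dof`, `weights`.  Voxels with zero
#'   residual variance get `NA` in the t map (`zero_variance` mask).
#' @export
contrast_map <- function(fit, weights) {
  w <- unlist(weights)
  unknown <- setdiff(names(w), fit$columns)
  if (length(unknown))
    stop_tdbold("contrast names unknown column(s): ",
                paste(unknown, collapse = ", "))
  cvec <- stats::setNames(numeric(length(fit$columns)), fit$columns)
  cvec[names(w)] <- w
  effect <- drop(crossprod(cvec, fit$beta))
  var_c <- drop(t(cvec) %*% fit$XtXinv %*% cvec)
  se <- sqrt(fit$sigma2 * var_c)
  zero_var <- se <= 0 | !is.finite(se)
  tval <- ifelse(zero_var, NA_real_, effect / se)
  if (all(cvec == 0)) tval[] <- NA_real_
  structure(list(effect = map_from_vector(effect, fit$shape),
                 t = map_from_vector(tval, fit$shape),
                 se = map_from_vector(se, fit$shape),
                 dof = fit$dof, weights = cvec,
                 zero_variance = map_from_vector(zero_var, fit$shape)),
            class = "contrast_result")
}

#' Second-level random-effects analysis
#'
#' Summary-statistics group inference: subjects' first-level contrast maps
#' are the unit of observation.  `"one_sample"` tests the per-voxel mean
#' against zero (dof n-1); `"two_sample"` compares two groups of subjects
#' with a pooled-variance t (dof n1+n2-2), as in the between-experiments
#' interaction analysis.
#'
#' @param contrast_maps list of per-subject maps (arrays or vectors of equal
#'   length), or a voxels x subjects matrix.
#' @param design_type `"one_sample"` or `"two_sample"`.
#' @param group_labels for `"two_sample"`, a vector with exactly two levels.
#' @return A `group_result`: `t` map, `mean` (or group difference), `dof`,
#'   `n`, the stacked subject matrix `maps`, and `shape`.
#' @export
second_level <- function(contrast_maps,
                         design_type = c("one_sample", "two_sample"),
                         group_labels = NULL) {
  design_type <- match.arg(design_type)
  if (is.matrix(contrast_maps)) {
    M <- contrast_maps; shape <- NULL
  } else {
    shape <- if (is.array(contrast_maps[[1]])) dim(contrast_maps[[1]]) else NULL
    M <- sapply(contrast_maps, as.vector)
  }
  n <- ncol(M)
  if (design_type == "one_sample") {
    if (n < 2L) stop_tdbold("one-sample analysis needs at least 2 maps")
    m <- rowMeans(M)
    s <- sqrt(rowSums((M - m)^2) / (n - 1L))
    se <- s / sqrt(n)
    tval <- ifelse(se > 0, m / se, NA_real_)
    dof <- n - 1L
    eff <- m
  } else {
    if (is.null(group_labels) || length(unique(group_labels)) != 2L)
      stop_tdbold("two-sample analysis needs labels with two groups")
    g <- as.integer(factor(group_labels))
    n1 <- sum(g == 1L); n2 <- sum(g == 2L)
    if (n1 < 2L || n2 < 2L) stop_tdbold("each group needs at least 2 maps")
    m1 <- rowMeans(M[, g == 1L, drop = FALSE])
    m2 <- rowMeans(M[, g == 2L, drop = FALSE])
    ss <- rowSums((M[, g == 1L, drop = FALSE] - m1)^2) +
      rowSums((M[, g == 2L, drop = FALSE] - m2)^2)
    dof <- n1 + n2 - 2L
    sp2 <- ss / dof
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
    eff <- m1 - m2
  }
  structure(list(t = map_from_vector(tval, shape),
                 mean = map_from_vector(eff, shape),
                 dof = dof, n = n, analysis = design_type,
                 maps = M, group_labels = group_labels, shape = shape),
            class = "group_result")
}

#' Region-averaged coefficients of a first-level fit
#' @param fit a `first_level_fit` from a 4-D series.
#' @param mask logical 3-D array.
#' @return Named vector: mean coefficient over in-mask voxels, per column.
#' @export
roi_betas <- function(fit, mask) {
  idx <- which(as.vector(mask))
  if (!length(idx)) stop_tdbold("empty mask")
  rowMeans(fit$beta[, idx, drop = FALSE])
}

#' Fitted BOLD time course with point-wise confidence band
#'
#' Reconstructs the fitted trial-locked signal per condition from a
#' target-event design with polynomial time modulators: the fitted curve is
#' the sum of the cue fit, the patch main effect and the polynomial
#' expansion fits, evaluated on a fine trial time grid; the 90% band is
#' mean +/- 1.645 standard errors across subjects, point-wise, analogously
#' to a second-level analysis of the coefficients.
#'
#' @param beta_matrix subjects x design-columns matrix of (typically
#'   region-averaged) first-level coefficients; column names must match the
#'   design.
#' @param design the `fmri_design` (from [build_target_event_design()] plus
#'   [add_polynomial_time_modulators()]) the coefficients came from.
#' @param config the [task_config()] giving trial timing.
#' @param dt time grid step in seconds.
#' @param conf confidence level of the point-wise band.
#' @return A `time_course_fit`: `time` plus per-condition `mean`, `lower`,
#'   `upper` curves.
#' @export
fitted_time_course <- function(beta_matrix, design, config = task_config(),
                               dt = 0.1, conf = 0.90) {
  need <- c("target_low_t1", "target_high_t1")
  if (!all(need %in% colnames(design$X)))
    stop_tdbold("design lacks polynomial patch modulator columns")
  beta_matrix <- as.matrix(beta_matrix)
  trial_len <- config$cue_duration + config$interval_duration +
    config$patch_duration + config$iti_duration
  grid <- seq(0, trial_len, by = dt)
  kern <- canonical_hrf(design$hrf, tr = dt, oversampling = 1L)
  n_fine <- length(grid)
  conv_grid <- function(onsets, durations, heights) {
    x <- numeric(n_fine)
    for (j in seq_along(onsets)) {
      i0 <- min(n_fine, floor(onsets[j] / dt) + 1L)
      if (durations[j] > 0) {
        i1 <- min(n_fine, ceiling((onsets[j] + durations[j]) / dt))
        x[i0:i1] <- x[i0:i1] + heights[j]
      } else x[i0] <- x[i0] + heights[j] / dt
    }
    stats::convolve(x, rev(kern), type = "open")[seq_len(n_fine)]
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  patch0 <- config$cue_duration + config$interval_duration
  out <- list(time = grid)
  targets <- design$targets
  for (lv in c("low", "high")) {
    tg <- targets[targets$level == lv, , drop = FALSE]
    n_tr <- max(1L, length(unique(tg$trial)))
    basis <- list()
    basis[[paste0("cue_", lv)]] <- conv_grid(0, config$cue_duration, 1)
    basis[[paste0("target_", lv)]] <-
      conv_grid(patch0 + tg$within, rep(0, nrow(tg)), rep(1 / n_tr, nrow(tg)))
    d <- 1L
    repeat {
      nm <- paste0("target_", lv, "_t", d)
      if (!nm %in% colnames(design$X)) break
      w <- tg$within^d; w <- w - mean(w)
      basis[[nm]] <- conv_grid(patch0 + tg$within, rep(0, nrow(tg)), w / n_tr)
      d <- d + 1L
    }
    B <- do.call(cbind, basis)
    curves <- B %*% t(beta_matrix[, colnames(B), drop = FALSE])
    m <- rowMeans(curves)
    nsub <- ncol(curves)
    se <- if (nsub > 1L)
      sqrt(rowSums((curves - m)^2) / (nsub - 1L)) / sqrt(nsub) else 0
    out[[lv]] <- list(mean = m, lower = m - z * se, upper = m + z * se)
  }
  structure(out, class = "time_course_fit")
}
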