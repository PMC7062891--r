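#' Canonical double-gamma haemodynamic response specification
#'
#' The de-facto standard shape: a gamma density peaking about 6 s after the
#' event minus a scaled gamma undershoot peaking about 16 s after, sampled
#' over 32 s.  The kernel is scaled to unit peak so regression coefficients
#' read directly in signal units.
#'
#' @param peak_delay,undershoot_delay gamma peak delays in seconds.
#' @param peak_dispersion,undershoot_dispersion gamma dispersions in seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel length in seconds.
#' @param oversampling fine-grid samples per TR used when building designs.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     ratio = 6, length = 32, oversampling = 16L) {
  if (length <= 0) stop_tdbold("kernel length must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, length = length,
                 oversampling = as.integer(oversampling)),
            class = "hrf_spec")
}

#' Sample the canonical haemodynamic response kernel
#'
#' @param spec an [hrf_spec()].
#' @param tr repetition time in seconds.
#' @param oversampling samples per TR; the kernel is sampled at
#'   `tr / oversampling`.
#' @return Numeric kernel starting at t = 0, scaled to unit peak.
#' @export
canonical_hrf <- function(spec = hrf_spec(), tr,
                          oversampling = spec$oversampling) {
  if (tr <= 0) stop_tdbold("TR must be positive")
  dt <- tr / oversampling
  t <- seq(0, spec$length, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion) / spec$ratio
  h / max(h)
}

# Build one convolved regressor column: events placed on a fine grid
# (boxcars of their duration, or unit-area impulses when duration is 0),
# convolved with the kernel and decimated at the scan times (D-D5).
convolve_events <- function(onsets, durations, heights, kern, tr, n_scans,
                            oversampling) {
  dt <- tr / oversampling
  n_fine <- n_scans * oversampling
  x <- numeric(n_fine)
  for (j in seq_along(onsets)) {
    i0 <- floor(onsets[j] / dt) + 1L
    if (i0 > n_fine) next
    if (durations[j] > 0) {
      i1 <- min(n_fine, ceiling((onsets[j] + durations[j]) / dt))
      x[i0:i1] <- x[i0:i1] + heights[j]
    } else {
      x[i0] <- x[i0] + heights[j] / dt  # unit-area impulse
    }
  }
  y <- stats::convolve(x, rev(kern), type = "open")[seq_len(n_fine)]
  y[(seq_len(n_scans) - 1L) * oversampling + 1L]
}

new_design <- function(X, kind, tr, n_scans, hrf, events, oversampling) {
  structure(list(X = X, kind = kind, tr = tr, n_scans = n_scans,
                 hrf = hrf, events = events, oversampling = oversampling),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("fmri_design: %d scans x %d columns (TR %.3g s)\n",
              x$n_scans, ncol(x$X), x$tr))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Discrete-cosine high-pass drift basis
#'
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds.
#' @return Matrix of cosine regressors with periods above `cutoff` removed,
#'   one column per retained frequency (may have zero columns).
#' @export
dct_drift_basis <- function(n_scans, tr, cutoff = 128) {
  k_max <- floor(2 * n_scans * tr / cutoff)
  if (k_max < 1L) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  t <- seq_len(n_scans) - 1L
  B <- sapply(seq_len(k_max), function(k)
    cos(pi * (2 * t + 1) * k / (2 * n_scans)))
  B <- matrix(B, nrow = n_scans)
  colnames(B) <- paste0("drift_", seq_len(k_max))
  B
}

#' Boxcar (block) first-level design
#'
#' The cue and foraging phases of each trial enter as separate boxcar
#' regressors of their phase durations, one per reward level, convolved with
#' the canonical haemodynamic response of equal amplitude, plus an intercept
#' and optionally a discrete-cosine drift basis.
#'
#' @param schedule a [generate_schedule()] result.
#' @param tr repetition time in seconds.
#' @param n_scans number of scans; defaults to cover the schedule.
#' @param hrf an [hrf_spec()].
#' @param drift_cutoff high-pass cutoff in seconds, or `NULL` for none.
#' @return An `fmri_design` with task columns among `cue_low`, `cue_high`,
#'   `patch_low`, `patch_high` (absent conditions are dropped).
#' @export
build_block_design <- function(schedule, tr, n_scans = NULL,
                               hrf = hrf_spec(), drift_cutoff = NULL) {
  if (is.null(n_scans)) n_scans <- ceiling(schedule$total_duration / tr)
  ev <- schedule_events(schedule)
  if (nrow(ev) && max(ev$onset + ev$duration) > n_scans * tr)
    warning("events extend beyond the scan window and are truncated")
  kern <- canonical_hrf(hrf, tr)
  os <- hrf$oversampling
  cols <- list(); kinds <- character(0)
  for (cc in c("cue_low", "cue_high", "patch_low", "patch_high")) {
    e <- ev[ev$trial_type == cc, , drop = FALSE]
    if (!nrow(e)) next
    cols[[cc]] <- convolve_events(e$onset, e$duration, rep(1, nrow(e)),
                                  kern, tr, n_scans, os)
    kinds <- c(kinds, "task")
  }
  X <- do.call(cbind, c(cols, list(intercept = rep(1, n_scans))))
  kinds <- c(kinds, "intercept")
  if (!is.null(drift_cutoff)) {
    B <- dct_drift_basis(n_scans, tr, drift_cutoff)
    if (ncol(B)) {
      X <- cbind(X, B)
      kinds <- c(kinds, rep("drift", ncol(B)))
    }
  }
  new_design(X, kinds, tr, n_scans, hrf, ev, os)
}

#' Target-event first-level design
#'
#' Models the foraging phase as a series of events, one impulse per target
#' presentation, per reward level, alongside the cue boxcars.  Conditions
#' without any target yield an all-zero column and a warning.
#'
#' @inheritParams build_block_design
#' @return An `fmri_design` with `cue_*` boxcar and `target_*` event columns.
#' @export
build_target_event_design <- function(schedule, tr, n_scans = NULL,
                                      hrf = hrf_spec(), drift_cutoff = NULL) {
  if (is.null(n_scans)) n_scans <- ceiling(schedule$total_duration / tr)
  ev <- schedule_events(schedule)
  kern <- canonical_hrf(hrf, tr)
  os <- hrf$oversampling
  cols <- list(); kinds <- character(0)
  for (cc in c("cue_low", "cue_high")) {
    e <- ev[ev$trial_type == cc, , drop = FALSE]
    if (!nrow(e)) next
    cols[[cc]] <- convolve_events(e$onset, e$duration, rep(1, nrow(e)),
                                  kern, tr, n_scans, os)
    kinds <- c(kinds, "task")
  }
  targets <- target_table(schedule)
  for (lv in c("low", "high")) {
    tg <- targets[targets$level == lv, , drop = FALSE]
    nm <- paste0("target_", lv)
    if (!nrow(tg)) {
      warning("no targets for condition ", lv, "; all-zero event column")
      cols[[nm]] <- numeric(n_scans)
    } else {
      cols[[nm]] <- convolve_events(tg$onset, rep(0, nrow(tg)),
                                    rep(1, nrow(tg)), kern, tr, n_scans, os)
    }
    kinds <- c(kinds, "task")
  }
  X <- do.call(cbind, c(cols, list(intercept = rep(1, n_scans))))
  kinds <- c(kinds, "intercept")
  if (!is.null(drift_cutoff)) {
    B <- dct_drift_basis(n_scans, tr, drift_cutoff)
    if (ncol(B)) { X <- cbind(X, B); kinds <- c(kinds, rep("drift", ncol(B))) }
  }
  d <- new_design(X, kinds, tr, n_scans, hrf, ev, os)
  d$targets <- targets
  d
}

# per-target table with run onsets, within-patch times and levels
target_table <- function(schedule) {
  rows <- lapply(schedule$trials, function(tr) {
    if (!nrow(tr$targets)) return(NULL)
    data.frame(trial = tr$index, level = tr$reward_level,
               onset = tr$targets$onset,
               within = tr$targets$onset - tr$patch_onset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trial = integer(0), level = character(0),
                      onset = numeric(0), within = numeric(0))
  out
}

# Gram-Schmidt residualization of y against the columns of Z
residualize <- function(y, Z) {
  if (is.null(Z) || NCOL(Z) == 0L) return(y)
  qrz <- qr(Z)
  y - qr.fitted(qrz, y)
}

#' Polynomial within-patch time modulators
#'
#' Adds, per condition, parametric modulators of the target events built
#' from mean-centered powers of within-patch time up to `degree`, each
#' convolved with the haemodynamic response and then sequentially
#' orthogonalized against the condition's main target column and all its
#' lower-degree modulators.
#'
#' @param design an `fmri_design` from [build_target_event_design()].
#' @param degree highest polynomial degree, at least 1.
#' @return The design with columns `target_<level>_t<d>` appended.
#' @export
add_polynomial_time_modulators <- function(design, degree = 4L) {
  if (degree < 1L) stop_tdbold("degree must be at least 1")
  targets <- design$targets
  if (is.null(targets)) stop_tdbold("design carries no target events")
  kern <- canonical_hrf(design$hrf, design$tr)
  for (lv in c("low", "high")) {
    tg <- targets[targets$level == lv, , drop = FALSE]
    main <- paste0("target_", lv)
    if (!nrow(tg) || !main %in% colnames(design$X)) next
    prev <- design$X[, main, drop = FALSE]
    for (d in seq_len(degree)) {
      w <- tg$within^d
      w <- w - mean(w)
      if (all(abs(w) < 1e-12)) {
        warning("constant modulator (degree ", d, ", ", lv,
                ") is zero after centering; dropped for rank")
        next
      }
      col <- convolve_events(tg$onset, rep(0, nrow(tg)), w, kern,
                             design$tr, design$n_scans, design$oversampling)
      col <- residualize(col, prev)
      nrm <- sqrt(sum(col^2))
      if (nrm > 1e-12) col <- col / nrm  # unit norm: scale of t^d is arbitrary
      nm <- paste0(main, "_t", d)
      design$X <- cbind(design$X, col)
      colnames(design$X)[ncol(design$X)] <- nm
      design$kind <- c(design$kind, "modulator")
      prev <- cbind(prev, col)
    }
  }
  design
}

#' Trial-number modulators of the cues
#'
#' Adds one mean-centered trial-number parametric modulator per cue
#' condition: the cue boxcar of each trial is scaled by the trial's centered
#' ordinal position, then convolved.  The interaction of reward level with
#' time over trials is the contrast `+1 cue_high_trial, -1 cue_low_trial`.
#'
#' @param design an `fmri_design` containing cue events.
#' @return The design with columns `cue_<level>_trial` appended.
#' @export
add_trial_number_modulator <- function(design) {
  ev <- design$events
  kern <- canonical_hrf(design$hrf, design$tr)
  for (lv in c("low", "high")) {
    e <- ev[ev$trial_type == paste0("cue_", lv), , drop = FALSE]
    if (nrow(e) < 2L)
      stop_tdbold("fewer than 2 cues of level ", lv,
                  ": trial-number modulator is degenerate")
    e <- e[order(e$onset), , drop = FALSE]
    w <- seq_len(nrow(e))
    w <- w - mean(w)
    col <- convolve_events(e$onset, e$duration, w, kern, design$tr,
                           design$n_scans, design$oversampling)
    nm <- paste0("cue_", lv, "_trial")
    design$X <- cbind(design$X, col)
    colnames(design$X)[ncol(design$X)] <- nm
    design$kind <- c(design$kind, "modulator")
  }
  design
}

#' First- vs last-quartile patch modulators
#'
#' Adds, per condition, indicator modulators of the targets falling in the
#' first and last quartiles of the foraging patch, enabling the
#' last-minus-first contrast (`+1 target_<level>_q4, -1 target_<level>_q1`).
#'
#' @param design an `fmri_design` from [build_target_event_design()].
#' @param patch_duration patch length in seconds used for the quartile
#'   boundaries.
#' @return The design with `target_<level>_q1` / `_q4` columns appended.
#' @export
add_quartile_model <- function(design, patch_duration) {
  targets <- design$targets
  if (is.null(targets)) stop_tdbold("design carries no target events")
  if (patch_duration <= 0) stop_tdbold("patch too short for quartiles")
  q1 <- patch_duration / 4
  q4 <- 3 * patch_duration / 4
  kern <- canonical_hrf(design$hrf, design$tr)
  for (lv in c("low", "high")) {
    tg <- targets[targets$level == lv, , drop = FALSE]
    if (!nrow(tg)) next
    for (qq in c("q1", "q4")) {
      sel <- if (qq == "q1") tg$within < q1 else tg$within > q4
      if (!any(sel))
        stop_tdbold("no targets in ", qq, " of condition ", lv,
                    ": patch too short for quartiles")
      col <- convolve_events(tg$onset[sel], rep(0, sum(sel)),
                             rep(1, sum(sel)), kern, design$tr,
                             design$n_scans, design$oversampling)
      nm <- paste0("target_", lv, "_", qq)
      design$X <- cbind(design$X, col)
      colnames(design$X)[ncol(design$X)] <- nm
      design$kind <- c(design$kind, "modulator")
    }
  }
  design
}

#' Write a design matrix as a tab-separated table
#' @param design an `fmri_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design$X), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
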