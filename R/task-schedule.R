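#' Task configuration for the cued foraging paradigm
#'
#' The task consists of a sequence of trials, each made of a coloured cue
#' announcing the trial's reward level, a fixation interval, a "foraging
#' patch" during which target dots appear and every caught target pays the
#' trial's reward, and an inter-trial pause.  Reward levels alternate either
#' randomly (balanced within the run) or deterministically, and targets
#' appear at irregular (bounded-exponential) or regular intervals.
#'
#' @param n_trials number of trials in the run.
#' @param cue_duration cue display time in seconds.
#' @param interval_duration cue-to-patch fixation interval in seconds.
#' @param patch_duration foraging-patch length in seconds.
#' @param iti_duration inter-trial pause in seconds.
#' @param reward_low,reward_high reward per caught target, in cents.
#' @param target_mode `"irregular"` (bounded-exponential inter-target
#'   intervals) or `"regular"` (fixed intervals).
#' @param interval_bounds lower/upper truncation bounds of the inter-target
#'   interval distribution, in milliseconds.
#' @param interval_mean target mean of the truncated interval distribution,
#'   in milliseconds; the distribution's rate is calibrated to reach it.
#' @param regular_interval fixed inter-target interval for the regular mode,
#'   in milliseconds.
#' @param alternation `"random_balanced"` (seeded permutation with equal
#'   counts of each level) or `"regular"` (strict alternation).
#' @param start_level first reward level under regular alternation.
#' @param target_onscreen maximal target display time in milliseconds
#'   (bookkeeping only; it does not affect event timing).
#' @param seed integer seed controlling every random element of a schedule.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 12L,
                        cue_duration = 2,
                        interval_duration = 3,
                        patch_duration = 14.5,
                        iti_duration = 10,
                        reward_low = 1,
                        reward_high = 20,
                        target_mode = c("irregular", "regular"),
                        interval_bounds = c(300, 1800),
                        interval_mean = 1220,
                        regular_interval = 1250,
                        alternation = c("random_balanced", "regular"),
                        start_level = c("low", "high"),
                        target_onscreen = 800,
                        seed = 1L) {
  target_mode <- match.arg(target_mode)
  alternation <- match.arg(alternation)
  start_level <- match.arg(start_level)
  durs <- c(cue_duration, interval_duration, patch_duration, iti_duration)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop_tdbold("all phase durations must be positive")
  if (n_trials < 0) stop_tdbold("n_trials must be non-negative")
  if (interval_bounds[1] >= interval_bounds[2])
    stop_tdbold("interval_bounds must satisfy lower < upper")
  if (target_mode == "irregular" &&
      (interval_mean <= interval_bounds[1] || interval_mean >= interval_bounds[2]))
    stop_tdbold("interval_mean must lie strictly inside interval_bounds")
  structure(list(
    n_trials = as.integer(n_trials),
    cue_duration = cue_duration,
    interval_duration = interval_duration,
    patch_duration = patch_duration,
    iti_duration = iti_duration,
    reward_low = reward_low,
    reward_high = reward_high,
    target_mode = target_mode,
    interval_bounds = as.numeric(interval_bounds),
    interval_mean = interval_mean,
    regular_interval = regular_interval,
    alternation = alternation,
    start_level = start_level,
    target_onscreen = target_onscreen,
    seed = as.integer(seed)
  ), class = "task_config")
}

#' Sequence of trial reward levels
#'
#' `"regular"` returns a strict alternation starting at `start_level`;
#' `"random_balanced"` returns a seeded random permutation with exactly
#' `n_trials / 2` trials of each level.
#'
#' @param mode `"random_balanced"` or `"regular"`.
#' @param n_trials number of trials; must be even for the balanced mode.
#' @param seed integer seed (ignored for the regular mode).
#' @param start_level first level under regular alternation.
#' @return Character vector of `"low"` / `"high"`.
#' @export
alternation_sequence <- function(mode = c("random_balanced", "regular"),
                                 n_trials, seed = 1L,
                                 start_level = c("low", "high")) {
  mode <- match.arg(mode)
  start_level <- match.arg(start_level)
  if (n_trials < 0) stop_tdbold("n_trials must be non-negative")
  if (n_trials == 0L) return(character(0))
  if (mode == "regular") {
    lv <- if (start_level == "low") c("low", "high") else c("high", "low")
    return(rep_len(lv, n_trials))
  }
  if (n_trials %% 2L != 0L)
    stop_tdbold("random_balanced alternation requires an even n_trials")
  base <- rep(c("low", "high"), each = n_trials %/% 2L)
  with_seed(seed, sample(base))
}

# Mean of an exponential density restricted to [a, b] with rate `rate`.
# Continuous through rate -> 0 (the uniform limit) and monotone decreasing,
# which makes the calibration a well-posed scalar root-finding problem.
truncexp_mean <- function(rate, a, b) {
  w <- b - a
  if (abs(rate * w) < 1e-10) return(a + w / 2)
  a + 1 / rate - w / (exp(rate * w) - 1)
}

# Rate such that the [a, b]-truncated exponential has the requested mean.
# A mean above the midpoint of the bounds yields a negative rate (density
# increasing towards the upper bound), which is a valid member of the family.
calibrate_truncexp_rate <- function(mean_target, bounds) {
  a <- bounds[1]; b <- bounds[2]
  mid <- (a + b) / 2
  if (abs(mean_target - mid) < 1e-9) return(0)
  f <- function(r) truncexp_mean(r, a, b) - mean_target
  span <- 1 / (b - a)
  interval <- if (mean_target < mid) c(1e-12, 200 * span) else c(-200 * span, -1e-12)
  stats::uniroot(f, interval, tol = 1e-14)$root
}

# Inverse-CDF sampler of the truncated exponential (rate may be negative).
rtruncexp <- function(n, rate, a, b) {
  if (n == 0L) return(numeric(0))
  u <- stats::runif(n)
  if (abs(rate * (b - a)) < 1e-10) return(a + u * (b - a))
  ea <- exp(-rate * a); eb <- exp(-rate * b)
  -log(ea - u * (ea - eb)) / rate
}

#' Sample inter-target intervals
#'
#' In the irregular mode, intervals follow an exponential distribution
#' truncated to `config$interval_bounds`, with the rate calibrated so the
#' truncated mean equals `config$interval_mean`.  In the regular mode all
#' intervals equal `config$regular_interval`.
#'
#' @param mode `"irregular"` or `"regular"`.
#' @param n number of intervals to draw.
#' @param config a [task_config()].
#' @param seed integer seed.
#' @return Numeric vector of intervals in milliseconds.
#' @export
sample_target_intervals <- function(mode = c("irregular", "regular"),
                                    n, config = task_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (n < 0) stop_tdbold("n must be non-negative")
  if (mode == "regular") return(rep(config$regular_interval, n))
  b <- config$interval_bounds
  if (b[1] >= b[2]) stop_tdbold("infeasible interval bounds")
  rate <- calibrate_truncexp_rate(config$interval_mean, b)
  with_seed(seed, rtruncexp(n, rate, b[1], b[2]))
}

# Target onsets within one patch: the first onset falls one sampled interval
# after patch start; onsets are appended until the next would exceed the
# patch end (the patch itself always ends at its scheduled offset).
# `rate` lets callers reuse a calibrated rate across many trials.
sample_patch_targets <- function(config, seed, rate = NULL) {
  patch_ms <- config$patch_duration * 1000
  if (config$target_mode == "regular") {
    step <- config$regular_interval
    k <- floor(patch_ms / step)
    onsets <- step * seq_len(k)
    sides <- with_seed(seed, sample(c("left", "right"), k, replace = TRUE))
    return(list(onset_ms = onsets, side = sides))
  }
  if (is.null(rate))
    rate <- calibrate_truncexp_rate(config$interval_mean, config$interval_bounds)
  with_seed(seed, {
    onsets <- numeric(0)
    t_ms <- rtruncexp(1, rate, config$interval_bounds[1], config$interval_bounds[2])
    while (t_ms <= patch_ms) {
      onsets <- c(onsets, t_ms)
      t_ms <- t_ms + rtruncexp(1, rate, config$interval_bounds[1],
                               config$interval_bounds[2])
    }
    sides <- sample(c("left", "right"), length(onsets), replace = TRUE)
    list(onset_ms = onsets, side = sides)
  })
}

#' Generate a timed trial schedule
#'
#' Lays out `config$n_trials` trials back to back (cue, interval, patch,
#' pause), assigns reward levels per the configured alternation rule, and
#' packs target events into every patch.  Identical configurations produce
#' bit-identical schedules.
#'
#' @param config a [task_config()].
#' @return An object of class `trial_schedule` with elements `trials` (a list
#'   of per-trial records), `total_duration` (seconds), and `config`.
#' @export
generate_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  levels <- alternation_sequence(config$alternation, config$n_trials,
                                 seed = config$seed,
                                 start_level = config$start_level)
  trial_len <- config$cue_duration + config$interval_duration +
    config$patch_duration + config$iti_duration
  min_iv <- if (config$target_mode == "regular") config$regular_interval
            else config$interval_bounds[1]
  if (config$n_trials > 0L && config$patch_duration * 1000 < min_iv)
    warning("patch shorter than one minimal inter-target interval; patches have no targets")
  trials <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    t0 <- (i - 1) * trial_len
    lv <- levels[i]
    reward <- if (lv == "high") config$reward_high else config$reward_low
    tg <- sample_patch_targets(config, seed = derive_seed(config$seed, i))
    patch_onset <- t0 + config$cue_duration + config$interval_duration
    targets <- if (length(tg$onset_ms)) {
      data.frame(onset = patch_onset + tg$onset_ms / 1000,
                 side = tg$side, reward = reward,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(onset = numeric(0), side = character(0), reward = numeric(0))
    }
    trials[[i]] <- list(
      index = i, reward_level = lv, reward = reward,
      cue_onset = t0,
      interval_onset = t0 + config$cue_duration,
      patch_onset = patch_onset,
      iti_onset = patch_onset + config$patch_duration,
      targets = targets
    )
  }
  structure(list(trials = trials,
                 total_duration = config$n_trials * trial_len,
                 config = config),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("trial_schedule: %d trials, %.1f s total, %s targets, %s alternation\n",
              length(x$trials), x$total_duration,
              x$config$target_mode, x$config$alternation))
  invisible(x)
}

#' Write a schedule as an events table
#'
#' One `cue_<level>` row, one `patch_<level>` row and one `target` row per
#' target, per trial; tab-separated with columns `onset`, `duration`,
#' `trial_type`, `reward`, `side` (onsets and durations in seconds).
#'
#' @param schedule a [generate_schedule()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  ev <- schedule_events(schedule)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a schedule into an events data frame
#' @param schedule a `trial_schedule`.
#' @return A data frame with one row per cue, patch and target event.
#' @export
schedule_events <- function(schedule) {
  rows <- lapply(schedule$trials, function(tr) {
    cfg <- schedule$config
    base <- data.frame(
      onset = c(tr$cue_onset, tr$patch_onset),
      duration = c(cfg$cue_duration, cfg$patch_duration),
      trial_type = paste0(c("cue_", "patch_"), tr$reward_level),
      reward = tr$reward, side = "n/a", stringsAsFactors = FALSE)
    if (nrow(tr$targets)) {
      tg <- data.frame(onset = tr$targets$onset, duration = 0,
                       trial_type = "target", reward = tr$targets$reward,
                       side = tr$targets$side, stringsAsFactors = FALSE)
      base <- rbind(base, tg)
    }
    base
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     trial_type = character(0), reward = numeric(0),
                     side = character(0))
  }
  ev[order(ev$onset), , drop = FALSE]
}

#' Read an events table back into a schedule
#'
#' Inverse of [write_events()]: reconstructs trials from the cue/patch rows
#' and reattaches targets to the enclosing patch.  Durations of the phases
#' are recovered from the table itself plus the gaps between phases.
#'
#' @param path path to a tab-separated events table.
#' @return A `trial_schedule`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  needed <- c("onset", "duration", "trial_type", "reward", "side")
  missing <- setdiff(needed, names(ev))
  if (length(missing))
    stop_tdbold("events table is missing column(s): ",
                paste(missing, collapse = ", "))
  bad <- which(!is.finite(ev$onset))
  if (length(bad))
    stop_tdbold("malformed onset in events row ", bad[1])
  ev <- ev[order(ev$onset), , drop = FALSE]
  cues <- ev[grepl("^cue_", ev$trial_type), , drop = FALSE]
  patches <- ev[grepl("^patch_", ev$trial_type), , drop = FALSE]
  targets <- ev[ev$trial_type == "target", , drop = FALSE]
  if (nrow(cues) != nrow(patches))
    stop_tdbold("events table has unmatched cue/patch rows")
  n <- nrow(cues)
  if (n == 0L) {
    cfg <- task_config(n_trials = 0L)
    return(structure(list(trials = list(), total_duration = 0, config = cfg),
                     class = "trial_schedule"))
  }
  trial_len <- if (n > 1) cues$onset[2] - cues$onset[1] else NA
  cue_dur <- cues$duration[1]
  patch_dur <- patches$duration[1]
  interval_dur <- patches$onset[1] - (cues$onset[1] + cue_dur)
  iti_dur <- if (n > 1) trial_len - cue_dur - interval_dur - patch_dur else 10
  rl <- sub("^cue_", "", cues$trial_type)
  lo <- unique(cues$reward[rl == "low"]); hi <- unique(cues$reward[rl == "high"])
  cfg <- task_config(n_trials = n, cue_duration = cue_dur,
                     interval_duration = interval_dur,
                     patch_duration = patch_dur, iti_duration = iti_dur,
                     reward_low = if (length(lo)) lo[1] else 1,
                     reward_high = if (length(hi)) hi[1] else 20)
  trials <- lapply(seq_len(n), function(i) {
    p0 <- patches$onset[i]; p1 <- p0 + patch_dur
    sel <- targets$onset >= p0 & targets$onset <= p1
    tg <- targets[sel, , drop = FALSE]
    list(index = i, reward_level = rl[i], reward = cues$reward[i],
         cue_onset = cues$onset[i],
         interval_onset = cues$onset[i] + cue_dur,
         patch_onset = p0, iti_onset = p1,
         targets = data.frame(onset = tg$onset, side = tg$side,
                              reward = tg$reward, stringsAsFactors = FALSE))
  })
  structure(list(trials = trials,
                 total_duration = n * (cue_dur + interval_dur + patch_dur + iti_dur),
                 config = cfg),
            class = "trial_schedule")
}
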