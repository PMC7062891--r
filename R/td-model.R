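#' Configuration of the TD(0) learner
#'
#' The task is modelled as an undiscounted episodic Markov chain
#' (discount fixed at 1): each trial is one episode ending in a terminal
#' state whose value is pinned to 0.  State values are learned by
#' incrementing the current estimate by a fraction `alpha` of the one-step
#' prediction error \eqn{\delta(s_t) = V(s_{t+1}) - V(s_t) + r_t}.
#'
#' @param alpha learning-rate fraction in (0, 1].
#' @param n_train maximum number of training trials.
#' @param convergence_tol training stops once the largest value update in a
#'   trial falls below this; on stochastic chains this is typically never
#'   reached and the learner runs for `n_train` trials, flagged unconverged.
#' @param n_record number of post-training trials to record.
#' @param hit_prob probability that a presented target is caught and pays.
#' @param step_grain model step within the continuous phases, in seconds.
#' @param seed integer seed for the training/recording trial stream.
#' @return An object of class `td_config`.
#' @export
td_config <- function(alpha = 0.1, n_train = 10000L, convergence_tol = 1e-8,
                      n_record = 200L, hit_prob = 1, step_grain = 0.25,
                      seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop_tdbold("alpha must be in (0, 1]")
  if (convergence_tol <= 0) stop_tdbold("convergence_tol must be positive")
  if (hit_prob < 0 || hit_prob > 1) stop_tdbold("hit_prob must be in [0, 1]")
  structure(list(gamma = 1, alpha = alpha, n_train = as.integer(n_train),
                 convergence_tol = convergence_tol,
                 n_record = as.integer(n_record), hit_prob = hit_prob,
                 step_grain = step_grain, seed = as.integer(seed)),
            class = "td_config")
}

other_level <- function(level) if (level == "low") "high" else "low"

#' Build the episode chain of one trial
#'
#' Discretizes a trial into a finite chain of episodes: a pre-cue context
#' state, the cue, interval steps, one step per `step_grain` of the foraging
#' patch (a step containing a target onset becomes a target episode and
#' carries the trial's reward; the others are non-target episodes with
#' reward 0), inter-trial steps, and a terminal state.  States are indexed
#' by position and reward level only, so the learner knows elapsed time but
#' not whether a given patch step will contain a target.
#'
#' Under experiment variant 2 the context state additionally encodes the
#' previous trial's reward level; with regular alternation this makes the
#' upcoming cue fully predictable and its prediction error vanishes after
#' learning.  Under variant 3 targets are regular, so the whole chain is
#' deterministic.
#'
#' @param trial one element of `generate_schedule()$trials`.
#' @param config the [task_config()] the trial came from.
#' @param experiment experiment variant, 1, 2 or 3.
#' @param step_grain model step in seconds.
#' @param prev_level previous trial's reward level (variant 2 only).
#' @param hit_prob probability each target pays; 1 keeps the chain
#'   deterministic given the trial.
#' @param seed seed for hit draws when `hit_prob < 1`.
#' @return An `episode_chain`: a data frame with columns `state`, `kind`
#'   (`context`, `cue`, `interval`, `target`, `non_target`, `iti`,
#'   `terminal`), `reward` (cents) and `time` (seconds from trial start),
#'   with the trial's level as attribute `level`.
#' @export
build_episode_chain <- function(trial, config, experiment = 1,
                                step_grain = 0.25, prev_level = NULL,
                                hit_prob = 1, seed = 1L) {
  if (!experiment %in% 1:3) stop_tdbold("unknown experiment variant: ", experiment)
  lv <- trial$reward_level
  ctx <- if (experiment == 2) {
    if (is.null(prev_level)) prev_level <- other_level(lv)
    paste0("ctx_", prev_level)
  } else "ctx"
  n_int <- max(1L, round(config$interval_duration / step_grain))
  n_patch <- max(1L, round(config$patch_duration / step_grain))
  n_iti <- max(1L, round(config$iti_duration / step_grain))
  # patch step i covers ((i-1), i] * step_grain after patch onset
  rel <- trial$targets$onset - trial$patch_onset
  target_step <- unique(pmin(pmax(ceiling(rel / step_grain), 1L), n_patch))
  hit <- rep(TRUE, length(target_step))
  if (hit_prob < 1 && length(target_step))
    hit <- with_seed(seed, stats::runif(length(target_step)) < hit_prob)
  patch_kind <- rep("non_target", n_patch)
  patch_kind[target_step] <- "target"
  patch_reward <- numeric(n_patch)
  patch_reward[target_step[hit]] <- trial$reward

  t_cue <- config$cue_duration
  t_int <- config$interval_duration
  t_patch0 <- t_cue + t_int
  state <- c(ctx, paste0("cue_", lv),
             paste0("int_", lv, "_", seq_len(n_int)),
             paste0("patch_", lv, "_", seq_len(n_patch)),
             paste0("iti_", seq_len(n_iti)), "terminal")
  kind <- c("context", "cue", rep("interval", n_int), patch_kind,
            rep("iti", n_iti), "terminal")
  reward <- c(0, 0, numeric(n_int), patch_reward, numeric(n_iti), 0)
  time <- c(-step_grain, 0,
            t_cue + step_grain * (seq_len(n_int) - 1),
            t_patch0 + step_grain * (seq_len(n_patch) - 1),
            t_patch0 + config$patch_duration + step_grain * (seq_len(n_iti) - 1),
            t_patch0 + config$patch_duration + config$iti_duration)
  chain <- structure(list(state = state, kind = kind, reward = reward,
                          time = time),
                     row.names = c(NA_integer_, -length(state)),
                     level = lv, context_state = ctx,
                     class = c("episode_chain", "data.frame"))
  chain
}

#' Stream of training/recording chains for an experiment variant
#'
#' Returns a function of a trial index producing a freshly sampled episode
#' chain: reward levels are drawn uniformly (variants 1 and 3) or alternate
#' deterministically (variant 2), and target onsets are resampled per trial
#' from the task's interval distribution (variants 1 and 2) or placed
#' regularly (variant 3).
#'
#' @param config a [task_config()]; its `target_mode` is overridden to match
#'   the variant (irregular for 1-2, regular for 3).
#' @param experiment variant 1, 2 or 3.
#' @param td a [td_config()] supplying step grain, hit probability and seed.
#' @return A function `f(i)` returning an `episode_chain`.
#' @export
chain_generator <- function(config = task_config(), experiment = 1,
                            td = td_config()) {
  config$target_mode <- if (experiment == 3) "regular" else "irregular"
  rate <- if (config$target_mode == "irregular")
    calibrate_truncexp_rate(config$interval_mean, config$interval_bounds)
  else NULL
  trial_template <- function(level, i) {
    tg <- sample_patch_targets(config, seed = derive_seed(td$seed, 7901L + i),
                               rate = rate)
    patch_onset <- config$cue_duration + config$interval_duration
    list(index = i, reward_level = level,
         reward = if (level == "high") config$reward_high else config$reward_low,
         cue_onset = 0, interval_onset = config$cue_duration,
         patch_onset = patch_onset,
         iti_onset = patch_onset + config$patch_duration,
         targets = list(onset = patch_onset + tg$onset_ms / 1000,
                        side = tg$side))
  }
  function(i) {
    if (experiment == 2) {
      lv <- if (i %% 2L == 1L) config$start_level else other_level(config$start_level)
      prev <- other_level(lv)
    } else {
      lv <- with_seed(derive_seed(td$seed, 3307L + i),
                      sample(c("low", "high"), 1L))
      prev <- NULL
    }
    tr <- trial_template(lv, i)
    build_episode_chain(tr, config, experiment = experiment,
                        step_grain = td$step_grain, prev_level = prev,
                        hit_prob = td$hit_prob,
                        seed = derive_seed(td$seed, 5501L + i))
  }
}

# shared tabular-value machinery: states are interned into an environment
# so chains can be processed as integer index vectors
new_value_table <- function() {
  list(index = new.env(parent = emptyenv()), values = numeric(0))
}

intern_states <- function(tab, states) {
  idx <- integer(length(states))
  for (j in seq_along(states)) {
    s <- states[j]
    k <- tab$index[[s]]
    if (is.null(k)) {
      k <- length(tab$values) + 1L
      tab$index[[s]] <- k
      tab$values[k] <- 0
      names(tab$values)[k] <- s
    }
    idx[j] <- k
  }
  list(tab = tab, idx = idx)
}

#' Learn state values by TD(0)
#'
#' Runs the one-step tabular update \eqn{V(s_t) \leftarrow V(s_t) +
#' \alpha\,[V(s_{t+1}) - V(s_t) + r_t]} over episodes drawn from a chain
#' generator.  The terminal state's value is pinned to 0.  Training stops
#' when the largest update within a trial drops below `convergence_tol`
#' (deterministic chains) or after `n_train` trials (stochastic chains,
#' flagged unconverged).
#'
#' @param gen a [chain_generator()] (or any `function(i)` returning an
#'   `episode_chain`).
#' @param td a [td_config()].
#' @return An object of class `value_table`: named numeric `values`,
#'   logical `converged`, integer `sweeps_used`.
#' @export
train_values <- function(gen, td = td_config()) {
  tab <- new_value_table()
  converged <- FALSE
  sweeps <- 0L
  upd_hist <- numeric(td$n_train)
  for (i in seq_len(td$n_train)) {
    chain <- gen(i)
    res <- intern_states(tab, chain$state)
    tab <- res$tab
    idx <- res$idx
    v <- tab$values
    r <- chain$reward
    n <- length(idx)
    term <- idx[n]
    max_upd <- 0
    for (t in seq_len(n - 1L)) {
      a <- idx[t]; b <- idx[t + 1L]
      upd <- td$alpha * (v[b] - v[a] + r[t])
      v[a] <- v[a] + upd
      if (abs(upd) > max_upd) max_upd <- abs(upd)
    }
    v[term] <- 0  # terminal value pinned
    tab$values <- v
    sweeps <- i
    upd_hist[i] <- max_upd
    if (max_upd < td$convergence_tol) { converged <- TRUE; break }
  }
  structure(list(values = tab$values, index = tab$index,
                 converged = converged, sweeps_used = sweeps,
                 update_history = upd_hist[seq_len(sweeps)]),
            class = "value_table")
}

state_values <- function(values, states) {
  out <- numeric(length(states))
  for (j in seq_along(states)) {
    k <- values$index[[states[j]]]
    out[j] <- if (is.null(k)) 0 else values$values[k]
  }
  out
}

#' Record prediction-error and reward traces
#'
#' Simulates `n_record` fresh trials with learning switched off and records,
#' for every transition \eqn{s_t \to s_{t+1}}, the prediction error
#' \eqn{\delta(s_t) = V(s_{t+1}) - V(s_t) + r_t}, the delivered reward, the
#' current state's value and kind, the kind of the state being entered, and
#' the transition's clock time within the trial.
#'
#' @param values a trained [train_values()] table.
#' @param gen the chain generator used for recording.
#' @param td a [td_config()].
#' @return A `td_trace` data frame with columns `trial`, `step`, `level`,
#'   `kind` (of \eqn{s_t}), `kind_entered` (of \eqn{s_{t+1}}), `delta`,
#'   `reward`, `value`, `time` (clock time of the transition, i.e. of the
#'   entered state).
#' @export
record_trace <- function(values, gen, td = td_config()) {
  out <- vector("list", td$n_record)
  for (i in seq_len(td$n_record)) {
    chain <- gen(td$n_train + i)
    v <- state_values(values, chain$state)
    n <- nrow(chain)
    tt <- seq_len(n - 1L)
    out[[i]] <- data.frame(
      trial = i, step = tt, level = attr(chain, "level"),
      kind = chain$kind[tt], kind_entered = chain$kind[tt + 1L],
      delta = v[tt + 1L] - v[tt] + chain$reward[tt],
      reward = chain$reward[tt], value = v[tt],
      time = chain$time[tt + 1L], stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, out)
  class(trace) <- c("td_trace", "data.frame")
  trace
}

#' Summarize prediction errors within a task phase
#'
#' Restricts a trace to a phase and summarizes its prediction errors.  For
#' the punctate appearance events (`"cue"`, `"target"` with `at = "entry"`)
#' the relevant error is the one generated by the transition that reveals
#' the event, i.e. rows whose entered state matches; for sustained phases
#' (`at = "within"`, the default) it is the errors of transitions out of
#' states inside the phase.  The phase name `"patch"` (or `"foraging"`)
#' matches both target and non-target patch steps.
#'
#' @param trace a [record_trace()] result.
#' @param phase_filter character vector of episode kinds, or `"patch"`.
#' @param at `"within"` or `"entry"` (see above).
#' @return A list with `mean`, `mean_abs`, `max_abs` and `n`; when the
#'   filter selects no rows, `n` is 0 and the summaries are `NA`.
#' @export
consistency_residual <- function(trace, phase_filter = "patch",
                                 at = c("within", "entry")) {
  at <- match.arg(at)
  kinds <- phase_filter
  if (any(kinds %in% c("patch", "foraging")))
    kinds <- unique(c(setdiff(kinds, c("patch", "foraging")),
                      "target", "non_target"))
  col <- if (at == "within") trace$kind else trace$kind_entered
  d <- trace$delta[col %in% kinds]
  if (!length(d))
    return(list(mean = NA_real_, mean_abs = NA_real_, max_abs = NA_real_, n = 0L))
  list(mean = mean(d), mean_abs = mean(abs(d)), max_abs = max(abs(d)),
       n = length(d))
}

#' Learn state-action values under the always-click policy
#'
#' On-policy one-step update of \eqn{Q(s_t, a_t)} where the policy clicks at
#' every target episode and withholds otherwise (the task's optimal policy).
#' After convergence on a deterministic chain the reward of every step obeys
#' \eqn{r_t = Q(s_t, a_t) - Q(s_{t+1}, a_{t+1})}, the state-action form of
#' the consistency condition.
#'
#' @inheritParams train_values
#' @return An object of class `q_table`: named numeric `values` keyed by
#'   `"state|action"`, plus `converged` and `sweeps_used`.
#' @export
train_q_values <- function(gen, td = td_config()) {
  tab <- new_value_table()
  converged <- FALSE
  sweeps <- 0L
  for (i in seq_len(td$n_train)) {
    chain <- gen(i)
    action <- ifelse(chain$kind == "target", "click", "no_click")
    keys <- paste(chain$state, action, sep = "|")
    res <- intern_states(tab, keys)
    tab <- res$tab
    idx <- res$idx
    v <- tab$values
    r <- chain$reward
    n <- length(idx)
    max_upd <- 0
    for (t in seq_len(n - 1L)) {
      a <- idx[t]; b <- idx[t + 1L]
      upd <- td$alpha * (r[t] + v[b] - v[a])
      v[a] <- v[a] + upd
      if (abs(upd) > max_upd) max_upd <- abs(upd)
    }
    v[idx[n]] <- 0
    tab$values <- v
    sweeps <- i
    if (max_upd < td$convergence_tol) { converged <- TRUE; break }
  }
  structure(list(values = tab$values, index = tab$index,
                 converged = converged, sweeps_used = sweeps),
            class = "q_table")
}

#' Q-values along a chain under the always-click policy
#' @param q a [train_q_values()] table.
#' @param chain an `episode_chain`.
#' @return Numeric vector of \eqn{Q(s_t, a_t)} along the chain.
#' @export
policy_q_values <- function(q, chain) {
  action <- ifelse(chain$kind == "target", "click", "no_click")
  state_values(q, paste(chain$state, action, sep = "|"))
}

#' Backward-induction state values on a fixed chain
#'
#' Dynamic-programming reference for deterministic chains: the value of each
#' state is the sum of rewards from that state to the end of the episode
#' (undiscounted), computed by a single backward pass.
#'
#' @param chain an `episode_chain`.
#' @return Named numeric vector of values along the chain.
#' @export
backward_induction_values <- function(chain) {
  n <- nrow(chain)
  v <- numeric(n)
  for (t in (n - 1L):1L) v[t] <- chain$reward[t] + v[t + 1L]
  v[n] <- 0
  stats::setNames(v, chain$state)
}

#' Smooth recorded traces into BOLD-like model curves
#'
#' Places each recorded prediction error and reward as an impulse at its
#' clock time within the trial, averages the impulse trains across trials
#' separately for low- and high-reward trials, and convolves them with the
#' canonical haemodynamic response so the curves reflect what the model
#' predicts for the BOLD signal.
#'
#' @param trace a [record_trace()] result.
#' @param config the [task_config()] providing trial timing.
#' @param hrf an [hrf_spec()]; its kernel is sampled at `dt`.
#' @param dt time grid step in seconds.
#' @return A `model_curves` list with `time` (seconds from trial start) and,
#'   per condition, smoothed `delta` and `reward` curves.
#' @export
smooth_trace_to_curves <- function(trace, config = task_config(),
                                   hrf = hrf_spec(), dt = 0.05) {
  trial_len <- config$cue_duration + config$interval_duration +
    config$patch_duration + config$iti_duration
  grid <- seq(0, trial_len, by = dt)
  kern <- canonical_hrf(hrf, tr = dt, oversampling = 1L)
  one_curve <- function(times, vals, n_trials) {
    y <- numeric(length(grid))
    keep <- times >= 0 & times <= trial_len
    bins <- pmin(floor(times[keep] / dt) + 1L, length(grid))
    for (j in seq_along(bins)) y[bins[j]] <- y[bins[j]] + vals[keep][j]
    y <- y / max(1L, n_trials)
    stats::convolve(y, rev(kern), type = "open")[seq_along(grid)]
  }
  out <- list(time = grid)
  for (lv in c("low", "high")) {
    tr <- trace[trace$level == lv, , drop = FALSE]
    n_tr <- length(unique(tr$trial))
    out[[lv]] <- list(
      delta = one_curve(tr$time, tr$delta, n_tr),
      reward = one_curve(tr$time, tr$reward, n_tr))
  }
  structure(out, class = "model_curves",
            patch_window = c(config$cue_duration + config$interval_duration,
                             config$cue_duration + config$interval_duration +
                               config$patch_duration))
}

#' Ratio of time-averaged reward curves in the foraging window
#' @param curves a [smooth_trace_to_curves()] result.
#' @return Scalar ratio high / low of the mean reward curve over the patch.
#' @export
reward_rate_ratio <- function(curves) {
  w <- attr(curves, "patch_window")
  sel <- curves$time >= w[1] & curves$time <= w[2]
  mean(curves$high$reward[sel]) / mean(curves$low$reward[sel])
}
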