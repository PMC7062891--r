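# shared fixtures, all built in code

# short task: small chain (< 50 episodes at 0.5 s grain) for DP comparisons
short_task <- function(...) {
  task_config(n_trials = 4L, cue_duration = 2, interval_duration = 1,
              patch_duration = 5, iti_duration = 2,
              regular_interval = 1250, target_mode = "regular", ...)
}

# a generator that always replays the same chain (deterministic training)
fixed_chain_gen <- function(chain) function(i) chain

# one deterministic high-reward chain from the short task
short_high_chain <- function(step_grain = 0.5) {
  cfg <- short_task()
  sch <- generate_schedule(cfg)
  tr <- Filter(function(x) x$reward_level == "high", sch$trials)[[1]]
  tr$targets$onset <- tr$targets$onset - tr$cue_onset
  tr$patch_onset <- tr$patch_onset - tr$cue_onset
  tr$cue_onset <- 0
  build_episode_chain(tr, cfg, experiment = 3, step_grain = step_grain)
}

# empty value table (V identically zero)
zero_values <- function() {
  structure(list(values = numeric(0),
                 index = new.env(parent = emptyenv()),
                 converged = TRUE, sweeps_used = 0L),
            class = "value_table")
}

# tiny featureless phantom for GLM/noise tests
tiny_phantom <- function(shape = c(6L, 6L, 6L), voxel = 3) {
  build_phantom(shape, voxel, regions = list())
}
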