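test_that("episode chains discretize trials faithfully", {
  ch <- short_high_chain()
  expect_s3_class(ch, "episode_chain")
  expect_equal(sum(ch$kind == "target"), 4)      # 4 regular targets in 5 s
  expect_equal(sum(ch$kind == "terminal"), 1)
  expect_true(all(ch$reward[ch$kind == "target"] == 20))
  expect_true(all(ch$reward[ch$kind != "target"] == 0))
  expect_true(all(diff(ch$time) > 0))
  # a trial without targets yields no target/non-target rewards
  cfg <- short_task()
  tr0 <- generate_schedule(cfg)$trials[[1]]
  tr0$targets <- tr0$targets[0, , drop = FALSE]
  ch0 <- build_episode_chain(tr0, cfg, experiment = 3)
  expect_true(all(ch0$reward == 0))
  expect_false(any(ch0$kind == "target"))
  expect_error(build_episode_chain(tr0, cfg, experiment = 9), "variant")
})

test_that("TD(0) on a fixed chain matches backward induction", {
  ch <- short_high_chain()
  gen <- fixed_chain_gen(ch)
  v <- train_values(gen, td_config(alpha = 0.5, convergence_tol = 1e-10,
                                   n_train = 5000L))
  expect_true(v$converged)
  bi <- backward_induction_values(ch)
  learned <- vapply(ch$state, function(s) {
    k <- v$index[[s]]
    if (is.null(k)) 0 else v$values[k]
  }, numeric(1))
  expect_lt(max(abs(learned - bi)), 1e-6)
  # value at the first target state = sum of remaining undiscounted rewards
  first_target <- ch$state[which(ch$kind == "target")[1]]
  expect_equal(unname(learned[first_target]), 4 * 20, tolerance = 1e-6)
  # alpha = 1 back-propagates one state per sweep: convergence within
  # chain-length sweeps
  v1 <- train_values(fixed_chain_gen(ch),
                     td_config(alpha = 1, convergence_tol = 1e-10,
                               n_train = 5000L))
  expect_true(v1$converged)
  expect_lte(v1$sweeps_used, nrow(ch) + 1L)
  # zero rewards everywhere: values stay 0
  ch_zero <- ch
  ch_zero$reward[] <- 0
  vz <- train_values(fixed_chain_gen(ch_zero), td_config(alpha = 0.5))
  expect_true(all(vz$values == 0))
})

test_that("learning on a deterministic chain contracts monotonically", {
  ch <- short_high_chain()
  v <- train_values(fixed_chain_gen(ch),
                    td_config(alpha = 0.3, convergence_tol = 1e-10,
                              n_train = 5000L))
  h <- v$update_history
  expect_true(all(diff(h) <= 1e-12))
})

test_that("recorded traces satisfy the one-step error identity", {
  cfg <- task_config(seed = 2)
  td <- td_config(n_train = 1500L, n_record = 40L, seed = 2)
  gen <- chain_generator(cfg, 1, td)
  v <- train_values(gen, td)
  tr <- record_trace(v, gen, td)
  # delta re-derivable from stored values and rewards within each trial
  for (i in unique(tr$trial)[1:5]) {
    rows <- tr[tr$trial == i, ]
    n <- nrow(rows)
    v_next <- c(rows$value[-1], 0)  # terminal value is 0
    expect_lt(max(abs(rows$delta - (v_next - rows$value + rows$reward))), 1e-10)
    # telescoping: sum of delta = total reward - V(first state)
    expect_lt(abs(sum(rows$delta) - (sum(rows$reward) - rows$value[1])), 1e-9)
  }
  # signed anticipation at unpredictable cues
  d_high <- consistency_residual(tr[tr$level == "high", ], "cue", at = "entry")
  d_low <- consistency_residual(tr[tr$level == "low", ], "cue", at = "entry")
  expect_gt(d_high$mean, 0)
  expect_lt(d_low$mean, 0)
})

test_that("untrained values make delta equal the reward at target steps", {
  td <- td_config(n_record = 5L, seed = 4)
  gen <- chain_generator(task_config(), 3, td)
  tr <- record_trace(zero_values(), gen, td)
  tg <- tr[tr$kind == "target", ]
  expect_equal(tg$delta, tg$reward)
})

test_that("predictable cues carry no prediction error after learning", {
  cfg <- task_config(alternation = "regular", seed = 3)
  td <- td_config(n_train = 4000L, n_record = 100L, seed = 3)
  gen <- chain_generator(cfg, 2, td)
  v <- train_values(gen, td)
  tr <- record_trace(v, gen, td)
  for (lv in c("low", "high")) {
    d <- consistency_residual(tr[tr$level == lv, ], "cue", at = "entry")
    # small residual fluctuation versus the ~100-cent unpredicted response
    expect_lt(abs(d$mean), 2)
  }
})

test_that("consistency summaries filter phases and flag empty selections", {
  td <- td_config(n_record = 10L, seed = 6)
  gen <- chain_generator(task_config(), 3, td)
  tr <- record_trace(zero_values(), gen, td)
  s <- consistency_residual(tr, "patch")
  expect_equal(s$n, sum(tr$kind %in% c("target", "non_target")))
  empty <- consistency_residual(tr, "no_such_phase")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("Q-learning under the always-click policy obeys the consistency condition", {
  ch <- short_high_chain()
  td <- td_config(alpha = 0.5, convergence_tol = 1e-10, n_train = 5000L)
  q <- train_q_values(fixed_chain_gen(ch), td)
  expect_true(q$converged)
  qv <- policy_q_values(q, ch)
  n <- nrow(ch)
  lhs <- ch$reward[-n]
  rhs <- qv[-n] - qv[-1]
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  # greedy state-action values equal the state values on the same chain
  v <- train_values(fixed_chain_gen(ch),
                    td_config(alpha = 0.5, convergence_tol = 1e-10,
                              n_train = 5000L))
  vv <- vapply(ch$state, function(s) {
    k <- v$index[[s]]
    if (is.null(k)) 0 else v$values[k]
  }, numeric(1))
  expect_lt(max(abs(qv - vv)), 1e-6)
  # zero-reward chain: all Q stay 0
  chz <- ch
  chz$reward[] <- 0
  qz <- train_q_values(fixed_chain_gen(chz), td)
  expect_true(all(qz$values == 0))
})

test_that("smoothed model curves separate reward rates and vanish on zero traces", {
  cfg <- task_config(seed = 8)
  td <- td_config(n_record = 60L, seed = 8)
  gen <- chain_generator(cfg, 3, td)
  tr <- record_trace(zero_values(), gen, td)
  curves <- smooth_trace_to_curves(tr, cfg)
  w <- attr(curves, "patch_window")
  sel <- curves$time >= w[1] + 3 & curves$time <= w[2]  # past HRF rise
  expect_true(all(curves$high$reward[sel] > curves$low$reward[sel]))
  expect_equal(reward_rate_ratio(curves), 20, tolerance = 1e-9)
  tr0 <- tr
  tr0$delta <- 0
  tr0$reward <- 0
  c0 <- smooth_trace_to_curves(tr0, cfg)
  expect_true(all(c0$low$delta == 0) && all(c0$high$reward == 0))
})
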