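test_that("the canonical kernel has the expected double-gamma shape", {
  tr <- 2.46
  h <- canonical_hrf(hrf_spec(), tr)
  dt <- tr / 16
  peak_t <- (which.max(h) - 1) * dt
  expect_gt(peak_t, 4.5)
  expect_lt(peak_t, 6.5)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)  # unit peak normalization
  # one sign change: positive lobe then undershoot
  signs <- sign(h[abs(h) > 1e-6])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_error(canonical_hrf(hrf_spec(), tr = 0), "TR")
})

test_that("block designs hold the four convolved task boxcars", {
  sch <- generate_schedule(task_config(seed = 2))
  d <- build_block_design(sch, tr = 2.46)
  expect_setequal(colnames(d$X),
                  c("cue_low", "cue_high", "patch_low", "patch_high",
                    "intercept"))
  expect_equal(nrow(d$X), 144)
  expect_equal(qr(d$X)$rank, ncol(d$X))
  # sustained blocks accumulate more signal than brief ones
  expect_gt(max(d$X[, "patch_high"]), max(d$X[, "cue_high"]))
  # boxcars are non-negative before convolution, so the convolved columns
  # can only go negative through the kernel's undershoot (bounded by it)
  expect_gt(min(d$X[, 1:4]), 12 * sum(pmin(canonical_hrf(hrf_spec(), 2.46), 0)))
  empty <- build_block_design(generate_schedule(task_config(n_trials = 0L)),
                              tr = 2.46, n_scans = 20)
  expect_equal(colnames(empty$X), "intercept")
})

test_that("drift basis cosines are zero-mean and counted by the cutoff", {
  B <- dct_drift_basis(144, 2.46, cutoff = 128)
  expect_equal(ncol(B), floor(2 * 144 * 2.46 / 128))
  expect_lt(max(abs(colSums(B))), 1e-9)
  d <- build_block_design(generate_schedule(task_config()), 2.46,
                          drift_cutoff = 128)
  expect_equal(sum(d$kind == "drift"), ncol(B))
  expect_equal(qr(d$X)$rank, ncol(d$X))
})

test_that("event designs carry one impulse per target", {
  sch <- generate_schedule(task_config(target_mode = "regular", seed = 1))
  d <- build_target_event_design(sch, tr = 2.46)
  expect_equal(nrow(d$targets), 12 * 11)
  # event and block regressors of the same condition are near-collinear
  db <- build_block_design(sch, tr = 2.46)
  expect_gt(cor(d$X[, "target_high"], db$X[, "patch_high"]), 0.9)
  # all-zero event column flagged when a condition has no targets
  cfg0 <- task_config(patch_duration = 0.5, target_mode = "regular")
  sch0 <- suppressWarnings(generate_schedule(cfg0))
  w <- testthat::capture_warnings(
    d0 <- build_target_event_design(sch0, tr = 2.46))
  expect_length(w, 2)  # one per empty condition
  expect_match(w, "all-zero", all = TRUE)
  expect_true(all(d0$X[, "target_low"] == 0))
})

test_that("polynomial time modulators are orthogonal to lower degrees", {
  sch <- generate_schedule(task_config(seed = 4))
  d <- add_polynomial_time_modulators(build_target_event_design(sch, 2.46), 4)
  for (lv in c("low", "high")) {
    cols <- paste0("target_", lv, "_t", 1:4)
    expect_true(all(cols %in% colnames(d$X)))
    lower <- d$X[, paste0("target_", lv), drop = FALSE]
    for (cn in cols) {
      expect_lt(max(abs(crossprod(d$X[, cn], lower))), 1e-8)
      lower <- cbind(lower, d$X[, cn])
    }
  }
  expect_equal(qr(d$X)$rank, ncol(d$X))
  expect_error(add_polynomial_time_modulators(
    build_target_event_design(sch, 2.46), 0), "degree")
})

test_that("re-orthogonalizing an orthogonalized set changes nothing", {
  sch <- generate_schedule(task_config(seed = 4))
  d <- add_polynomial_time_modulators(build_target_event_design(sch, 2.46), 3)
  cols <- grep("_t[0-9]$", colnames(d$X))
  X1 <- d$X[, cols]
  X2 <- X1
  prev <- d$X[, "target_low", drop = FALSE]
  for (j in seq_along(cols)) {
    X2[, j] <- tdbold:::residualize(X2[, j], prev)
    prev <- cbind(prev, X2[, j])
  }
  # low-condition columns were already orthogonal to these regressors
  low_cols <- grep("target_low_t", colnames(d$X)[cols])
  expect_lt(max(abs(X1[, low_cols] - X2[, low_cols])), 1e-10)
})

test_that("trial-number modulators need at least two cues per level", {
  sch <- generate_schedule(task_config(seed = 5))
  d <- add_trial_number_modulator(build_block_design(sch, 2.46))
  expect_true(all(c("cue_low_trial", "cue_high_trial") %in% colnames(d$X)))
  expect_equal(qr(d$X)$rank, ncol(d$X))
  sch1 <- generate_schedule(task_config(n_trials = 2L, alternation = "regular"))
  # drop the high cue: only one low cue of each type remains unbalanced
  d1 <- build_block_design(generate_schedule(
    task_config(n_trials = 2L, alternation = "regular")), 2.46)
  expect_error(add_trial_number_modulator(d1), "fewer than 2")
})

test_that("quartile modulators isolate early and late patch targets", {
  sch <- generate_schedule(task_config(target_mode = "regular", seed = 1))
  d0 <- build_target_event_design(sch, 2.46)
  d <- add_quartile_model(d0, patch_duration = 14.5)
  expect_true(all(c("target_low_q1", "target_high_q4") %in% colnames(d$X)))
  # 11 regular targets: 1.25..13.75 s; quartile boundary at 3.625 s keeps 2
  tg <- d$targets[d$targets$level == "high" & d$targets$trial ==
                    d$targets$trial[1], ]
  expect_equal(sum(tg$within < 14.5 / 4), 2)
  expect_equal(sum(tg$within > 3 * 14.5 / 4), 3)
  expect_error(add_quartile_model(d0, patch_duration = 0), "quartile")
})

test_that("convolution is linear over disjoint schedules", {
  # the design of a two-trial schedule equals the sum of each trial's
  # single-trial design on the shared scan grid
  cfg <- task_config(n_trials = 2L, alternation = "regular", seed = 9)
  sch <- generate_schedule(cfg)
  d_all <- build_block_design(sch, 2.46, n_scans = 30)
  one_trial <- function(idx) {
    s <- sch
    s$trials <- s$trials[idx]
    build_block_design(s, 2.46, n_scans = 30)
  }
  d1 <- one_trial(1)  # low trial: cue_low, patch_low
  d2 <- one_trial(2)  # high trial
  expect_lt(max(abs(d_all$X[, "cue_low"] - d1$X[, "cue_low"])), 1e-12)
  expect_lt(max(abs(d_all$X[, "patch_high"] - d2$X[, "patch_high"])), 1e-12)
})
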