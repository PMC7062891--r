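test_that("plain OLS path reproduces lm coefficients exactly", {
  set.seed(10)
  X <- cbind(a = rnorm(60), b = rnorm(60), intercept = 1)
  Y <- matrix(rnorm(60 * 5), 60, 5)
  fit <- fit_first_level(Y, X, ar = "none")
  ref <- stats::lm.fit(X, Y)$coefficients
  expect_equal(unname(fit$beta), unname(ref), tolerance = 1e-12)
  expect_equal(fit$rho, 0)
  expect_equal(fit$dof, 60 - 3)
})

test_that("prewhitening removes the lag-1 serial correlation", {
  ph <- tiny_phantom()
  d <- build_block_design(generate_schedule(task_config(seed = 1)), 2.46)
  ser <- simulate_subject(ph, d, noise_spec(sd = 1, phi = 0.3), list(),
                          seed = 2)
  fit <- fit_first_level(ser, d)
  expect_gt(fit$rho, 0.15)  # pooled estimate tracks the generating process
  wr <- whitened_residuals(ser, d, fit)
  ac <- mean(colSums(wr[-1, ] * wr[-nrow(wr), ]) / colSums(wr^2))
  expect_lt(abs(ac), 0.05)
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- cbind(a = rnorm(30), intercept = 1)
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_first_level(matrix(rnorm(30), 30, 1), X), "dup")
})

test_that("contrasts are linear and guard degenerate cases", {
  ph <- tiny_phantom()
  d <- build_block_design(generate_schedule(task_config(seed = 1)), 2.46)
  ser <- simulate_subject(ph, d, noise_spec(sd = 1), list(), seed = 3)
  fit <- fit_first_level(ser, d)
  cp <- contrast_map(fit, c(patch_high = 1, patch_low = -1))
  cm <- contrast_map(fit, c(patch_high = -1, patch_low = 1))
  expect_equal(cp$effect, -cm$effect)
  expect_equal(cp$t, -cm$t)
  expect_equal(cp$dof, fit$dof)
  z <- contrast_map(fit, c(patch_high = 0))
  expect_true(all(is.na(z$t)))
  expect_true(all(z$effect == 0))
  expect_error(contrast_map(fit, c(bogus = 1)), "unknown column")
})

test_that("pure-noise t maps follow the Student-t spread", {
  set.seed(5)
  X <- cbind(task = rep(c(0, 1), each = 30), intercept = 1)
  Y <- matrix(rnorm(60 * 4000), 60, 4000)
  fit <- fit_first_level(Y, X, ar = "none")
  tv <- contrast_map(fit, c(task = 1))$t
  expect_lt(abs(sd(tv) - sqrt(fit$dof / (fit$dof - 2))), 0.05)
})

test_that("second level equals direct t tests voxelwise", {
  set.seed(6)
  maps <- lapply(1:8, function(i) array(rnorm(27), dim = c(3, 3, 3)))
  g <- second_level(maps)
  expect_equal(g$dof, 7)
  M <- sapply(maps, as.vector)
  ref <- apply(M, 1, function(y) unname(stats::t.test(y)$statistic))
  expect_equal(as.vector(g$t), ref, tolerance = 1e-10)
  # two-sample against t.test with equal variances
  labels <- rep(c("a", "b"), each = 4)
  g2 <- second_level(maps, "two_sample", group_labels = labels)
  ref2 <- apply(M, 1, function(y)
    unname(stats::t.test(y[1:4], y[5:8], var.equal = TRUE)$statistic))
  expect_equal(as.vector(g2$t), ref2, tolerance = 1e-10)
  expect_equal(g2$dof, 6)
  # degenerate inputs
  const <- lapply(1:5, function(i) array(1, dim = c(2, 2, 2)))
  gc <- second_level(const)
  expect_true(all(is.na(gc$t)))
  expect_error(second_level(maps[1]), "at least 2")
  expect_error(second_level(maps, "two_sample", group_labels = rep("a", 8)),
               "two groups")
})

test_that("two-sample analysis recovers a planted group difference", {
  set.seed(7)
  hits <- replicate(500, {
    M <- matrix(c(rnorm(6, mean = 2), rnorm(6)), 1, 12)  # d = 2 x within-sd
    g <- second_level(M, "two_sample",
                      group_labels = rep(c("x", "y"), each = 6))
    g$t[1] > 0
  })
  expect_gt(mean(hits), 0.99)
})

test_that("fitted time courses rebuild planted condition differences", {
  cfg <- task_config(target_mode = "regular", seed = 2)
  sch <- generate_schedule(cfg)
  d <- add_polynomial_time_modulators(build_target_event_design(sch, 2.46), 4)
  cols <- colnames(d$X)
  # synthetic subject coefficients: flat patch effect, high > low
  make_beta <- function(dev) {
    b <- stats::setNames(numeric(length(cols)), cols)
    b["cue_high"] <- 0.6 + dev
    b["cue_low"] <- 0.2
    b["target_high"] <- 0.5 + dev
    b["target_low"] <- 0.1
    b
  }
  B <- do.call(rbind, lapply(c(-0.05, 0, 0.05, 0.1), make_beta))
  tc <- fitted_time_course(B, d, cfg)
  w <- c(cfg$cue_duration + cfg$interval_duration + 4,
         cfg$cue_duration + cfg$interval_duration + cfg$patch_duration)
  sel <- tc$time >= w[1] & tc$time <= w[2]
  expect_true(all(tc$high$mean[sel] > tc$low$mean[sel]))
  expect_true(all(tc$high$upper >= tc$high$mean))
  expect_true(all(tc$high$lower <= tc$high$mean))
  # zero between-subject variance collapses the band
  B0 <- do.call(rbind, lapply(c(0, 0, 0), make_beta))
  tc0 <- fitted_time_course(B0, d, cfg)
  expect_lt(max(tc0$low$upper - tc0$low$lower), 1e-10)
  expect_error(fitted_time_course(B[, 1:4], build_block_design(sch, 2.46),
                                  cfg),
               "polynomial")
})

test_that("quartile contrasts detect a within-patch ramp", {
  cfg <- task_config(target_mode = "regular", seed = 3)
  sch <- generate_schedule(cfg)
  d0 <- build_target_event_design(sch, 2.46)
  d <- add_quartile_model(d0, patch_duration = cfg$patch_duration)
  set.seed(8)
  # planted: late-patch targets respond more than early ones
  y_flat <- d$X[, "target_high"] * 0.5 + rnorm(nrow(d$X), sd = 0.01)
  y_ramp <- y_flat + d$X[, "target_high_q4"] * 0.4 -
    d$X[, "target_high_q1"] * 0.4
  fit <- fit_first_level(cbind(y_flat, y_ramp), d$X, ar = "none")
  con <- contrast_map(fit, c(target_high_q4 = 1, target_high_q1 = -1))
  expect_lt(abs(con$effect[1]), 0.05)  # flat signal: null estimate
  expect_gt(con$effect[2], 0.5)        # ramp: strongly positive
})
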