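test_that("tracking deviation accumulates exactly as defined", {
  cfg <- psa_config()
  env <- env_reset(make_tracking_env("straight", cfg))

  # robot driven exactly along the path: accumulator stays zero
  for (i in 1:5) env <- step_tracking(env, c(1, 0), 1, 1.2)
  expect_equal(env$dev_sum, 0, tolerance = 1e-9)
  expect_equal(env$pos, c(5, 0), tolerance = 1e-9)

  # unit perpendicular offset held for 5 steps adds exactly 5
  env2 <- env_reset(make_tracking_env("straight", cfg))
  env2$pos <- c(0, 1)
  for (i in 1:5) env2 <- step_tracking(env2, c(1, 0), 1, 1.2)
  expect_equal(env2$dev_sum, 5, tolerance = 1e-9)
})

test_that("doubling the speed multiplier halves the steps to traverse", {
  cfg <- psa_config()
  run_to_end <- function(mult) {
    env <- env_reset(make_tracking_env("straight", cfg))
    n <- 0
    while (!env$done && n < 200) {
      env <- step_tracking(env, c(1, 0), mult, 1.2)
      n <- n + 1
    }
    n
  }
  n1 <- run_to_end(1); n2 <- run_to_end(2)
  expect_equal(n2, ceiling(n1 / 2), tolerance = 1)
  env <- env_reset(make_tracking_env("straight", cfg))
  while (!env$done) env <- step_tracking(env, c(1, 0), 2, 1.2)
  expect_error(step_tracking(env, c(1, 0), 1, 1.2), "round over")
})

test_that("positioning locks require continuous enclosure for T seconds", {
  cfg <- psa_config()
  env <- env_reset(make_positioning_env(cfg))
  env$bullseye <- c(0, 0)  # sight already encloses the target
  env <- step_positioning(env, c(0, 0), 1, 1.2)
  expect_false(env$done)
  env <- step_positioning(env, c(0, 0), 1, 1.2)
  expect_true(env$done)           # lock_T = 2.4 s reached at t = 2.4 exactly
  expect_equal(env$t_complete, 2.4)

  # breaking the enclosure resets the lock timer
  env2 <- env_reset(make_positioning_env(cfg))
  env2$bullseye <- c(0, 0)
  env2 <- step_positioning(env2, c(0, 0), 1, 1.2)
  env2 <- step_positioning(env2, c(5, 0), 1, 1.2)   # leaves the ring
  expect_equal(env2$lock, 0)
  expect_false(env2$done)

  # seeded bullseye sequence is reproducible
  draw <- function() {
    e <- make_positioning_env(cfg)
    vapply(1:4, function(i) env_reset(e)$bullseye[1], 0)
  }
  set.seed(12); b1 <- draw()
  set.seed(12); b2 <- draw()
  expect_identical(b1, b2)
})

test_that("rewards follow the deviation/time formulas and monotonicity", {
  expect_equal(reward_tracking(2, t = 10, g = 0, offset = 0), 0.5)
  # default negative time gain: strictly decreasing in t
  r1 <- reward_tracking(3, t = 30); r2 <- reward_tracking(3, t = 50)
  expect_gt(r1, r2)
  # strictly decreasing in deviation at fixed t
  expect_gt(reward_tracking(2, 30), reward_tracking(4, 30))
  # perfect tracking stays finite via the floor
  expect_true(is.finite(reward_tracking(0, 30)))
  expect_error(reward_tracking(2, t = 0), "invalid input")

  expect_gt(reward_positioning(20), reward_positioning(40))
  expect_equal(reward_positioning(30, g = 0, offset = 0.7), 0.7)
  expect_equal(reward_positioning(2.4, g = -0.01, T_lock = 2.4, offset = 1),
               1 - 0.01 * 2.4)
  expect_error(reward_positioning(1.0, T_lock = 2.4), "invalid state")
})

test_that("operational quality mirrors the reward scale", {
  rec <- list(reward = 0.42, truncated = FALSE)
  expect_equal(as.numeric(operational_quality(rec)), 0.42)
  expect_identical(operational_quality(rec), operational_quality(rec))
  part <- operational_quality(list(reward = 0.1, truncated = TRUE))
  expect_true(isTRUE(attr(part, "partial")))
  # batch summary equals direct recomputation
  set.seed(13)
  qs <- runif(15, 0.2, 0.5)
  recs <- lapply(qs, function(q) list(reward = q, truncated = FALSE))
  vals <- vapply(recs, function(r) as.numeric(operational_quality(r)), 0)
  expect_equal(c(mean(vals), sd(vals)), c(mean(qs), sd(qs)))
})

test_that("difficulty levels order the accumulated deviation", {
  cfg <- psa_config()
  # quiet controller: geometry, not hand jitter, must drive the ordering
  pr <- operator_profile("conservative", base_noise = 0.02)
  mean_dev <- function(difficulty, seed) {
    set.seed(seed)
    env <- env_reset(make_tracking_env(difficulty, cfg))
    st <- initial_state(pr)
    n <- 0
    while (!env$done && n < 50) {
      cmd <- control_intent(st, pr, env, applied_level = 2)
      env <- step_tracking(env, cmd, 1.0, cfg$task$dt)
      n <- n + 1
    }
    env$dev_sum / n
  }
  wins <- vapply(1:20, function(s) {
    d <- c(mean_dev("straight", s), mean_dev("slope", s), mean_dev("curve", s))
    all(diff(d) > 0)
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})
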