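make_traj <- function(th, n_steps, seed, reward) {
  set.seed(seed)
  S <- matrix(rnorm(n_steps * th$sizes[1]), n_steps)
  a <- sample(0:(th$sizes[3] - 1), n_steps, replace = TRUE)
  list(states = S, actions = a, reward = reward)
}

test_that("the policy gradient obeys its closed-form degenerate cases", {
  th <- small_policy(41, c(5L, 6L, 4L))

  # advantage zero everywhere -> zero gradient
  trs <- lapply(1:3, function(i) make_traj(th, 4, i, reward = 2.5))
  g0 <- policy_gradient(trs, th, b = 2.5)
  expect_equal(max(abs(flatten_grad(g0))), 0)

  # single one-step trajectory with unit advantage -> the step's score
  tr <- make_traj(th, 1, 9, reward = 1)
  g1 <- policy_gradient(list(tr), th, b = 0)
  gs <- grad_log_prob(th, as.numeric(tr$states[1, ]), tr$actions[1])
  expect_equal(flatten_grad(g1), flatten_grad(gs), tolerance = 1e-12)

  # mirrored advantages on identical (s, a) cancel exactly
  trp <- make_traj(th, 5, 11, reward = 1)
  trm <- trp; trm$reward <- -1
  gm <- policy_gradient(list(trp, trm), th, b = 0)
  expect_lt(max(abs(flatten_grad(gm))), 1e-12)

  expect_error(policy_gradient(list(), th, 0), "empty trajectory")
})

test_that("the estimator differentiates the advantage-weighted surrogate", {
  set.seed(42)
  th <- small_policy(42, c(4L, 5L, 3L))
  trs <- list(make_traj(th, 3, 1, reward = 1.7), make_traj(th, 3, 2, reward = 0.4))
  b <- 0.9
  surrogate <- function(theta) {
    mean(vapply(trs, function(tr) {
      lp <- sum(vapply(seq_len(nrow(tr$states)), function(i)
        log(policy_forward(theta, tr$states[i, ])[tr$actions[i] + 1]), 0))
      (tr$reward - b) * lp
    }, 0))
  }
  g <- policy_gradient(trs, th, b)
  h <- 1e-5
  for (nm in c("W1", "b1", "W2", "b2")) {
    idx <- sample(length(th[[nm]]), min(3, length(th[[nm]])))
    for (i in idx) {
      tp <- th; tp[[nm]][i] <- tp[[nm]][i] + h
      tm <- th; tm[[nm]][i] <- tm[[nm]][i] - h
      fd <- (surrogate(tp) - surrogate(tm)) / (2 * h)
      expect_lt(abs(g[[nm]][i] - fd) / max(abs(fd), 1e-6), 1e-4)
    }
  }
})

test_that("adding a constant to rewards and baseline leaves the gradient unchanged", {
  th <- small_policy(43, c(4L, 5L, 3L))
  trs <- list(make_traj(th, 4, 3, reward = 0.2), make_traj(th, 4, 4, reward = 1.1))
  g1 <- policy_gradient(trs, th, b = 0.5)
  shifted <- lapply(trs, function(tr) { tr$reward <- tr$reward + 10; tr })
  g2 <- policy_gradient(shifted, th, b = 10.5)
  expect_lt(max(abs(flatten_grad(g1) - flatten_grad(g2))), 1e-10)
})

test_that("ADAM ascent steps satisfy the bias-corrected step-1 identity", {
  th <- small_policy(44, c(4L, 5L, 3L))
  g <- lapply(th[c("W1", "b1", "W2", "b2")], function(p) p * 0 + 0.37)
  cfg <- psa_config()
  up <- update_parameters(th, g, cfg)
  for (nm in c("W1", "b1", "W2", "b2"))
    expect_equal(max(abs(abs(up[[nm]] - th[[nm]]) - cfg$rl$lr)), 0,
                 tolerance = 1e-9)

  # zero gradient -> parameters unchanged
  gz <- lapply(g, function(p) p * 0)
  up0 <- update_parameters(th, gz, cfg)
  expect_identical(up0$W1, th$W1)

  # sign-flipped second step shrinks (moment cancellation)
  up2 <- update_parameters(up, lapply(g, function(p) -p), cfg)
  d1 <- abs(up$b2 - th$b2); d2 <- abs(up2$b2 - up$b2)
  expect_true(all(d2 < d1))

  gbad <- g; gbad$W1[1] <- NaN
  expect_error(update_parameters(th, gbad, cfg), "non-finite")
})

test_that("collected episodes are reproducible and carry k pairs", {
  cfg <- mini_config()
  pr <- operator_profile("conservative")
  th <- init_policy(seed = 5)
  norm <- unit_normalizer()
  env <- make_tracking_env("straight", cfg)
  st <- initial_state(pr)

  set.seed(77); ep1 <- collect_episode(env, st, pr, th, norm, cfg, FALSE)
  set.seed(77); ep2 <- collect_episode(env, st, pr, th, norm, cfg, FALSE)
  expect_identical(ep1$actions, ep2$actions)
  expect_equal(ep1$states, ep2$states)
  expect_equal(ep1$reward, ep2$reward)

  expect_equal(length(ep1$actions), cfg$task$k)
  expect_equal(nrow(ep1$states), cfg$task$k)

  # log-probability recomputes from states and actions
  lp <- sum(vapply(seq_len(cfg$task$k), function(i)
    log(policy_forward(th, ep1$states[i, ])[ep1$actions[i] + 1]), 0))
  expect_equal(ep1$log_prob, lp, tolerance = 1e-10)
})

test_that("convergence requires stable rewards and operator-consistent actions", {
  ok_actions <- replicate(6, rep(2L, 50), simplify = FALSE)
  res <- convergence_check(rep(5, 6), ok_actions, preferred = 2L)
  expect_true(res$converged)

  fluct <- convergence_check(rep(c(0, 10), 3), ok_actions, preferred = 2L)
  expect_false(fluct$converged)

  far <- replicate(6, rep(0L, 50), simplify = FALSE)
  mism <- convergence_check(rep(5, 6), far, preferred = 2L)
  expect_false(mism$converged)

  short <- convergence_check(rep(5, 3), ok_actions[1:3], preferred = 2L)
  expect_false(short$converged)
  expect_match(short$report$reason, "not enough")
})

test_that("training sessions run the protocol round structure", {
  cfg <- mini_config()
  ts <- train_session("tracking", operator_profile(), cfg, seed = 9)
  expect_equal(nrow(ts$history), cfg$protocol$train_rounds)
  expect_equal(sum(ts$history$formal),
               cfg$protocol$train_rounds - cfg$protocol$practice_rounds)
  expect_true(ts$normalizer$frozen)
  expect_true(all(is.finite(ts$history$reward)))
  # with learning disabled the policy is bit-identical after the session
  th0 <- init_policy(cfg$policy$sizes, seed = 1)
  ts0 <- train_session("tracking", operator_profile(), cfg, seed = 9,
                       theta = th0, learn = FALSE)
  expect_identical(ts0$theta$W1, th0$W1)
  expect_identical(ts0$theta$b2, th0$b2)
})
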