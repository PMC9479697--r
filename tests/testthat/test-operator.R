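test_that("latent dynamics saturate, rest, and decay as documented", {
  pr <- operator_profile()
  set.seed(51)
  st <- latent_state(fatigue = 0.1)
  f <- st$fatigue
  for (i in 1:60) {
    st <- step_latent(st, pr, character(), dt = 60)
    expect_gte(st$fatigue, f)   # monotone without rest
    f <- st$fatigue
  }
  expect_gt(st$fatigue, 0.9)    # approaches 1 over a long horizon

  rested <- step_latent(st, pr, "rest", dt = 60)
  expect_lt(rested$fatigue, st$fatigue)

  # nervous prompt: stress jumps, then decays below its peak within ~2 min
  st2 <- latent_state(stress = 0.1)
  jumped <- step_latent(st2, pr, "nervous", dt = 1)
  expect_gt(jumped$stress, st2$stress)
  decayed <- step_latent(jumped, pr, character(), dt = 120)
  expect_lt(decayed$stress, jumped$stress)

  # all dimensions bounded in [0, 1] under extreme inputs
  stx <- latent_state(arousal = 1, valence = 0, fatigue = 0.99, stress = 1)
  for (i in 1:20) stx <- step_latent(stx, pr, c("nervous", "negative"), dt = 600)
  expect_true(all(unlist(stx[c("arousal", "valence", "fatigue", "stress")]) >= 0))
  expect_true(all(unlist(stx[c("arousal", "valence", "fatigue", "stress")]) <= 1))
})

test_that("signal emission is reproducible under a fixed seed", {
  pr <- operator_profile()
  st <- latent_state()
  set.seed(52); r1 <- emit_signals(st, pr, duration = 3)
  set.seed(52); r2 <- emit_signals(st, pr, duration = 3)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$channel_labels, psa_montage())
  expect_equal(nrow(r1$samples), 3000)
})

# Mean per-channel band-averaged DE through the full implemented pipeline.
channel_de <- function(state, seed, n_windows = 40L) {
  cfg <- psa_config(preprocess = list(n_windows = n_windows))
  set.seed(seed)
  dur <- 2 + (n_windows - 1) * 1.2 + 1
  rec <- emit_signals(state, operator_profile(), duration = dur)
  Fm <- features_from_windows(preprocess_recording(rec, cfg), "DE", cfg)
  de <- colMeans(Fm[, 1:150])
  # average the five bands within each channel
  vapply(seq_len(30), function(ci) mean(de[(ci - 1) * 5 + 1:5]), 0)
}

test_that("fatigue lowers DE in every channel, most over the focal regions", {
  fresh <- channel_de(latent_state(fatigue = 0.1), seed = 53)
  tired <- channel_de(latent_state(fatigue = 0.9), seed = 54)
  drop <- fresh - tired
  expect_true(all(drop > 0))   # all 30 channels
  region <- psasim:::channel_region(psa_montage()[1:30])
  expect_gt(mean(drop[region == "fatigue_focus"]),
            mean(drop[region != "fatigue_focus"]))
})

test_that("stress raises temporal-channel DE", {
  calm <- channel_de(latent_state(stress = 0.1), seed = 55)
  stressed <- channel_de(latent_state(stress = 0.9), seed = 56)
  region <- psasim:::channel_region(psa_montage()[1:30])
  delta <- stressed - calm
  expect_gt(mean(delta[region == "temporal"]), 0)
  expect_gt(mean(delta[region == "temporal"]),
            mean(delta[region == "other"]))
})

test_that("low arousal raises the EOG power ratio", {
  cfg <- psa_config(preprocess = list(n_windows = 30L))
  pr_at <- function(arousal, seed) {
    set.seed(seed)
    rec <- emit_signals(latent_state(arousal = arousal), operator_profile(),
                        duration = 2 + 29 * 1.2 + 1)
    Fm <- features_from_windows(preprocess_recording(rec, cfg), "DE", cfg)
    mean(Fm[, 151:152])
  }
  expect_gt(pr_at(0.1, 57), pr_at(0.9, 58))
})

test_that("control intent follows the task and penalizes speed mismatch", {
  cfg <- psa_config()
  pr <- operator_profile("conservative")  # preferred level 2 when fresh
  st <- initial_state(pr)
  env <- env_reset(make_tracking_env("straight", cfg))

  # noise scale rises strictly with level mismatch
  spread_at <- function(level) {
    set.seed(59)
    sds <- replicate(400, control_intent(st, pr, env, level))
    sd(sds[2, ])   # perpendicular component is pure noise
  }
  s_match <- spread_at(2); s_one <- spread_at(1); s_far <- spread_at(0)
  expect_lt(s_match, s_one)
  expect_lt(s_one, s_far)

  # intent points along the path on average
  set.seed(60)
  mean_dx <- mean(replicate(200, control_intent(st, pr, env, 2)[1]))
  expect_gt(mean_dx, 0)
})

test_that("the four-class emulator is balanced, seeded and separable", {
  ds1 <- make_deap_like_dataset(12, seed = 61)
  expect_equal(dim(ds1$X), c(48, 152))
  expect_equal(as.numeric(table(ds1$y)), rep(12, 4))
  ds2 <- make_deap_like_dataset(12, seed = 61)
  expect_identical(ds1$X, ds2$X)

  # linear classifier on held-out data clears chance comfortably
  skip_if_not_installed("MASS")
  ds <- make_deap_like_dataset(30, seed = 62)
  set.seed(63)
  pc <- prcomp(ds$X, rank. = 12)
  idx <- unlist(lapply(0:3, function(c4) which(ds$y == c4)[1:20]))
  fit <- MASS::lda(pc$x[idx, ], grouping = ds$y[idx])
  pred <- predict(fit, pc$x[-idx, ])$class
  acc <- mean(pred == ds$y[-idx])
  expect_gte(acc, 0.6)
})
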