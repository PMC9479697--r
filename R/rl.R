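#' Collect one episode (task round) under the current policy
#'
#' Runs one round of the task: the operator's signals for the round buffer
#' are emitted and preprocessed into `k` windowed mental-state vectors; at
#' each windowed step the policy samples a speed action, the operator's
#' (state- and mismatch-dependent) control intent is applied at that speed,
#' and the environment advances. Once the task completes, the remaining
#' windows of the round buffer still contribute (state, action) pairs while
#' the robot holds position, so every episode carries `k` pairs (50 by
#' default). The episodic reward is computed from accumulated deviation
#' and/or completion time; episodes that never complete within the round
#' are flagged truncated and scored on elapsed time.
#'
#' @param env a `psa_env` (reset internally).
#' @param op_state operator [latent_state()].
#' @param profile an [operator_profile()].
#' @param theta a `psa_policy`.
#' @param normalizer feature normalizer state (running min-max).
#' @param config a [psa_config()] list.
#' @param update_normalizer_stats accumulate this episode's raw features
#'   into the normalizer (training session) or keep it frozen.
#' @param action_fn optional controller override: a function taking the
#'   normalized state vector and returning an action level in `0..3`
#'   (used for the conventional warning-threshold arm). When supplied the
#'   policy is bypassed and `log_prob` is `NA`.
#' @return list: `states` (k x 152), `actions` (k, 0-based), `reward`,
#'   `quality`, `t`, `deviation`, `truncated`, `log_prob`, `preferred`,
#'   `normalizer`, `env`.
#' @export
collect_episode <- function(env, op_state, profile, theta, normalizer,
                            config = psa_config(),
                            update_normalizer_stats = TRUE,
                            action_fn = NULL) {
  pp <- config$preprocess
  k <- config$task$k
  # round buffer spans the k windowed steps at the control cadence
  # (defaults: 2 s window + 49 * 1.2 s strides ~ the 60 s round minute)
  dur <- pp$window_ms / 1000 + (pp$n_windows - 1) * config$task$dt
  rec <- emit_signals(op_state, profile, duration = dur, fs = pp$fs_raw)
  prep <- preprocess_recording(rec, config)
  Fraw <- features_from_windows(prep, config$features$eeg_feature, config)
  if (update_normalizer_stats) normalizer <- update_normalizer(normalizer, Fraw)
  S <- apply_normalizer(normalizer, Fraw)

  env <- env_reset(env)
  mults <- config$policy$multipliers
  actions <- integer(k)
  velocities <- matrix(NA_real_, k, 2)   # applied displacement per active step
  logp <- 0
  pref <- preferred_level(op_state, profile)
  fb <- if (is.null(action_fn)) policy_forward_batch(theta, S) else NULL
  if (!is.null(action_fn)) logp <- NA_real_
  for (i in seq_len(k)) {
    if (is.null(action_fn)) {
      p <- fb$P[i, ]
      act <- sample_action(p, mults)
      logp <- logp + log(p[act$level + 1L])
    } else {
      lev <- action_fn(S[i, ])
      act <- list(level = lev, multiplier = mults[lev + 1L])
    }
    actions[i] <- act$level
    if (!env$done) {
      # the operator corrects their hand `substeps` times per policy step
      ns <- config$task$substeps
      dt_sub <- config$task$dt / ns
      pos0 <- env$pos
      for (ss in seq_len(ns)) {
        if (env$done) break
        cmd <- control_intent(op_state, profile, env, act$level, mults,
                              frac = 1 / ns)
        env <- if (env$task == "tracking")
          step_tracking(env, cmd, act$multiplier, dt_sub)
        else
          step_positioning(env, cmd, act$multiplier, dt_sub)
      }
      velocities[i, ] <- (env$pos - pos0) / config$task$dt
    }
  }
  er <- episode_reward(env)
  list(states = S, actions = actions, reward = er$reward,
       quality = as.numeric(operational_quality(list(reward = er$reward,
                                                     truncated = er$truncated))),
       t = er$t, deviation = if (env$task == "tracking") env$dev_sum else NA_real_,
       truncated = er$truncated, log_prob = logp, preferred = pref,
       velocities = velocities, normalizer = normalizer, env = env)
}

#' Baseline-corrected Monte-Carlo policy gradient
#'
#' Mean over episodes of `(R(tau) - b)` times the summed per-step score
#' gradients of the log action probabilities - the REINFORCE estimator with
#' a reward baseline. Computed batched per trajectory.
#'
#' @param trajectories list of episodes (each with `states`, `actions`,
#'   `reward`).
#' @param theta a `psa_policy`.
#' @param b scalar reward baseline.
#' @return gradient list shaped like the policy parameters.
#' @export
policy_gradient <- function(trajectories, theta, b = 0) {
  if (length(trajectories) == 0) stop("invalid input: empty trajectory list")
  da <- theta$sizes[3]
  grad <- list(W1 = theta$W1 * 0, b1 = theta$b1 * 0,
               W2 = theta$W2 * 0, b2 = theta$b2 * 0)
  for (tr in trajectories) {
    S <- rbind(tr$states)
    adv <- tr$reward - b
    if (adv == 0) next
    fb <- policy_forward_batch(theta, S)
    onehot <- matrix(0, nrow(S), da)
    onehot[cbind(seq_len(nrow(S)), tr$actions + 1L)] <- 1
    dz <- (onehot - fb$P) * adv
    dH <- (dz %*% t(theta$W2)) * (1 - fb$H^2)
    grad$W1 <- grad$W1 + crossprod(S, dH)
    grad$b1 <- grad$b1 + colSums(dH)
    grad$W2 <- grad$W2 + crossprod(fb$H, dz)
    grad$b2 <- grad$b2 + colSums(dz)
  }
  lapply(grad, function(g) g / length(trajectories))
}

#' Apply one ADAM ascent step to the policy
#'
#' Realizes the parameter update `theta <- theta + grad(R)` through
#' bias-corrected ADAM with the standard moment decay rates
#' (`beta1 = 0.9`, `beta2 = 0.999`) and learning rate 0.001.
#'
#' @param theta a `psa_policy`.
#' @param grad gradient of the maximized objective, shaped like `theta`.
#' @param config a [psa_config()] list (rl section used).
#' @return the updated policy.
#' @export
update_parameters <- function(theta, grad, config = psa_config()) {
  if (!all(vapply(grad, function(g) all(is.finite(g)), TRUE)))
    stop("update rejected: non-finite gradient")
  rl <- config$rl
  adam_step(theta, grad, rl$lr, rl$beta1, rl$beta2, rl$adam_eps, direction = 1)
}

#' Convergence check for personalized speed adaptation training
#'
#' Declares convergence when, over the last `W` episodes, (a) the
#' fluctuation of the reward is small (coefficient of variation below
#' `eps_r`) and (b) the chosen speed levels agree with the operator: the
#' fraction of steps whose action lies within one level of the operator's
#' preferred level is at least `match_frac` in every inspected episode.
#' Criterion (b) is the simulated stand-in for the operator's subjective
#' evaluation.
#'
#' @param rewards numeric vector of episode rewards so far.
#' @param actions list of per-episode action vectors (0-based levels).
#' @param preferred per-episode preferred level (vector, recycled scalar ok).
#' @param W inspection window (default 5 episodes).
#' @param eps_r maximum reward coefficient of variation (default 0.15).
#' @param match_frac minimum per-episode fraction of steps within one
#'   level of the preference (default 0.8).
#' @return list: `converged` (logical) and `report` (per-criterion detail).
#' @export
convergence_check <- function(rewards, actions, preferred, W = 5L,
                              eps_r = 0.15, match_frac = 0.8) {
  n <- length(rewards)
  if (n < W)
    return(list(converged = FALSE,
                report = list(reason = "not enough episodes", n = n, W = W)))
  idx <- (n - W + 1L):n
  rw <- rewards[idx]
  cv <- stats::sd(rw) / max(abs(mean(rw)), 1e-12)
  preferred <- rep_len(preferred, n)
  match_ok <- vapply(idx, function(i)
    mean(abs(actions[[i]] - preferred[i]) <= 1) >= match_frac, TRUE)
  converged <- (cv < eps_r) && all(match_ok)
  list(converged = converged,
       report = list(reward_cv = cv, eps_r = eps_r,
                     episodes_matching = sum(match_ok), W = W))
}

# Stimulation events for one round: timed prompts that perturb the latent
# state, plus the scheduled rest break after every 5 formal rounds.
round_events <- function(round_idx, practice_rounds, formal_idx) {
  ev <- character()
  if (runif(1) < 0.15) ev <- c(ev, "nervous")
  if (runif(1) < 0.2) ev <- c(ev, sample(c("positive", "negative"), 1))
  if (!is.na(formal_idx) && formal_idx > 0 && formal_idx %% 5 == 0)
    ev <- c(ev, "rest")
  ev
}

#' Run one training session of the PSA protocol
#'
#' Runs the full training session: optional supervised pretraining on the
#' synthetic four-class valence/arousal set, then 18 rounds (first 3 are
#' practice: they accumulate feature-normalization statistics and update
#' nothing) of collect-episode / policy-gradient / ADAM-update with the
#' running-mean reward baseline. With `learn = FALSE` (or `lr = 0`) the
#' policy is never updated, giving the null control.
#'
#' @param task `"tracking"` or `"positioning"`.
#' @param profile an [operator_profile()].
#' @param config a [psa_config()] list.
#' @param seed master seed; named substreams derive from it.
#' @param theta optional starting policy (default: fresh init, pretrained
#'   when `config$pretrain$enabled`).
#' @param learn perform parameter updates (default `TRUE`).
#' @param normalizer optional starting normalizer state.
#' @param op_state optional starting latent state.
#' @return a trainer state list: `theta`, `baseline`, `history` (one row
#'   per round with rewards, quality, times, action stats), `normalizer`,
#'   `op_state`, `convergence`, `trajectories` count.
#' @export
train_session <- function(task = c("tracking", "positioning"),
                          profile = operator_profile(),
                          config = psa_config(), seed = 1L,
                          theta = NULL, learn = TRUE,
                          normalizer = NULL, op_state = NULL) {
  task <- match.arg(task)
  pr <- config$protocol
  if (is.null(theta)) {
    theta <- init_policy(config$policy$sizes, config$policy$init_scale,
                         seed = substream_seed(seed, "init"))
    if (config$pretrain$enabled) {
      ds <- make_deap_like_dataset(config$pretrain$n_per_class, profile, config,
                                   seed = substream_seed(seed, "pretrain"))
      set.seed(substream_seed(seed, "pretrain-sgd"))
      pt <- pretrain(theta, ds$X, ds$y, config$pretrain$epochs,
                     config$pretrain$batch_size, config$rl$lr,
                     config$rl$beta1, config$rl$beta2)
      theta <- pt$theta
      # fresh optimizer state for the new (policy-gradient) objective
      theta$m <- lapply(theta$m, function(p) p * 0)
      theta$v <- lapply(theta$v, function(p) p * 0)
      theta$step <- 0L
      if (is.null(normalizer)) normalizer <- ds$normalizer
    }
  }
  if (is.null(normalizer)) normalizer <- make_normalizer(config$policy$sizes[1])
  if (is.null(op_state)) op_state <- initial_state(profile)
  env <- if (task == "tracking") make_tracking_env(config$task$difficulty, config)
         else make_positioning_env(config)

  n_rounds <- pr$train_rounds
  n_practice <- pr$practice_rounds
  rewards <- numeric(0); baseline <- NA_real_
  hist <- list(); action_log <- list()
  pr_indicator <- numeric(0)  # per-step mean normalized EOG PR, practice rounds
  eog_dims <- (config$policy$sizes[1] - 1):config$policy$sizes[1]
  set.seed(substream_seed(seed, "session"))
  for (r in seq_len(n_rounds)) {
    formal_idx <- if (r > n_practice) r - n_practice else NA_integer_
    ep <- collect_episode(env, op_state, profile, theta, normalizer, config,
                          update_normalizer_stats = TRUE)
    normalizer <- ep$normalizer
    is_formal <- r > n_practice
    if (!is_formal)
      pr_indicator <- c(pr_indicator, rowMeans(ep$states[, eog_dims, drop = FALSE]))
    if (is_formal) {
      if (is.na(baseline)) baseline <- ep$reward
      grad <- policy_gradient(list(ep), theta, baseline)
      if (learn && config$rl$lr > 0)
        theta <- update_parameters(theta, grad, config)
      rewards <- c(rewards, ep$reward)
      baseline <- mean(rewards)
    }
    action_log[[r]] <- ep$actions
    hist[[r]] <- data.frame(
      round = r, formal = is_formal, reward = ep$reward, quality = ep$quality,
      t = ep$t, deviation = ep$deviation, truncated = ep$truncated,
      modal_action = as.integer(names(which.max(table(ep$actions)))),
      preferred = ep$preferred,
      match_frac = mean(abs(ep$actions - ep$preferred) <= 1))
    ev <- round_events(r, n_practice, formal_idx)
    op_state <- step_latent(op_state, profile, ev,
                            dt = config$task$dt * config$task$k +
                              if ("rest" %in% ev) 60 else 0)
  }
  history <- do.call(rbind, hist)
  formal <- history[history$formal, ]
  conv <- convergence_check(formal$reward,
                            action_log[(n_practice + 1):n_rounds],
                            formal$preferred,
                            W = config$rl$conv_window,
                            eps_r = config$rl$conv_eps_r,
                            match_frac = config$rl$conv_match)
  normalizer$frozen <- TRUE
  list(theta = theta, baseline = baseline, history = history,
       actions = action_log, normalizer = normalizer, op_state = op_state,
       convergence = conv, task = task, profile = profile, seed = seed,
       pr_indicator = pr_indicator)
}
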