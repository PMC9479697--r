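#' Conventional warning-threshold speed controller
#'
#' The non-personalized baseline: when the scalar mental-state indicator
#' exceeds the warning threshold the speed is reduced to a fixed lower
#' level; when it returns to or below the threshold the normal level is
#' restored. Stateless (no hysteresis) and identical for every operator.
#' The indicator used by the protocol is the normalized mean EOG power
#' ratio of the current window, a low-arousal/fatigue proxy.
#'
#' @param indicator finite scalar mental-state indicator.
#' @param threshold warning threshold.
#' @param reduced_level,normal_level the two fixed speed levels (0-based).
#' @return integer action level.
#' @export
conventional_controller <- function(indicator, threshold,
                                    reduced_level = 3L, normal_level = 1L) {
  if (!is.finite(indicator)) stop("indicator must be finite")
  if (indicator > threshold) as.integer(reduced_level) else as.integer(normal_level)
}

# One evaluation session (testing or control): fixed policy or external
# controller, frozen normalizer, per-round reseeding so both arms face
# identically seeded operator signal streams.
run_eval_session <- function(task, profile, theta, normalizer, config, seed,
                             n_rounds, action_fn = NULL, label = "eval") {
  env <- if (task == "tracking") make_tracking_env(config$task$difficulty, config)
         else make_positioning_env(config)
  op_state <- initial_state(profile)
  hist <- list(); action_log <- list(); vel_log <- list()
  for (r in seq_len(n_rounds)) {
    set.seed(substream_seed(seed, paste0(label, "-round-", r)))
    ep <- collect_episode(env, op_state, profile, theta, normalizer, config,
                          update_normalizer_stats = FALSE, action_fn = action_fn)
    action_log[[r]] <- ep$actions
    vel_log[[r]] <- ep$velocities
    hist[[r]] <- data.frame(
      round = r, reward = ep$reward, quality = ep$quality, t = ep$t,
      deviation = ep$deviation, truncated = ep$truncated,
      modal_action = as.integer(names(which.max(table(ep$actions)))),
      preferred = ep$preferred,
      match_frac = mean(abs(ep$actions - ep$preferred) <= 1))
    set.seed(substream_seed(seed, paste0(label, "-latent-", r)))
    # the protocol's rest break after every 5 rounds applies to every session
    ev <- if (r %% 5 == 0) "rest" else character()
    op_state <- step_latent(op_state, profile, ev,
                            dt = config$task$dt * config$task$k +
                              if (length(ev)) 60 else 0)
  }
  list(history = do.call(rbind, hist), actions = action_log,
       velocities = do.call(rbind, vel_log), theta = theta)
}

#' Run the full three-session PSA protocol
#'
#' Training session (18 rounds, first 3 practice, learning on) produces the
#' frozen policy and feature-normalization statistics; the testing session
#' (15 rounds, learning off) imports those parameters; the control session
#' (15 rounds) runs the conventional warning-threshold controller whose
#' threshold defaults to the median practice-round indicator. Testing and
#' control rounds are seeded identically so both arms face the same
#' operator signal streams.
#'
#' @param task `"tracking"` or `"positioning"`.
#' @param profile an [operator_profile()].
#' @param config a [psa_config()] list.
#' @param seed master seed for all substreams.
#' @param threshold optional override for the warning threshold.
#' @return a protocol report: `training`, `testing`, `control` session
#'   results, `threshold`, and `comparison` ([compare_sessions()] output).
#' @export
run_protocol <- function(task = c("tracking", "positioning"),
                         profile = operator_profile(),
                         config = psa_config(), seed = 1L,
                         threshold = NULL) {
  task <- match.arg(task)
  pr <- config$protocol
  training <- train_session(task, profile, config, seed = seed)
  if (is.null(threshold))
    threshold <- stats::median(training$pr_indicator)
  testing <- run_eval_session(task, profile, training$theta,
                              training$normalizer, config, seed,
                              pr$test_rounds, label = "eval")
  ctrl_fn <- function(s) {
    nd <- length(s)
    conventional_controller(mean(s[(nd - 1):nd]), threshold,
                            pr$control_reduced_level, pr$control_normal_level)
  }
  control <- run_eval_session(task, profile, training$theta,
                              training$normalizer, config, seed,
                              pr$control_rounds, action_fn = ctrl_fn,
                              label = "eval")
  list(training = training, testing = testing, control = control,
       threshold = threshold,
       comparison = compare_sessions(testing$history, control$history),
       early_late = early_late_contrast(training$history))
}

#' Compare testing (PSA) and control (conventional) sessions
#'
#' Means, standard deviations, and paired plus two-sample t statistics of
#' per-round operational quality. The t-tests describe simulation output;
#' no human-subject claim is attached to them.
#'
#' @param testing,control session history data frames with a `quality`
#'   column and equal round counts.
#' @return list of summary statistics.
#' @export
compare_sessions <- function(testing, control) {
  if (nrow(testing) != nrow(control))
    stop("invalid input: sessions have different round counts")
  qt <- testing$quality; qc <- control$quality
  two <- stats::t.test(qt, qc, var.equal = TRUE)
  paired <- if (stats::sd(qt - qc) > 0) stats::t.test(qt, qc, paired = TRUE) else NULL
  list(mean_psa = mean(qt), sd_psa = stats::sd(qt),
       mean_conventional = mean(qc), sd_conventional = stats::sd(qc),
       mean_diff = mean(qt) - mean(qc),
       t_two_sample = unname(two$statistic), p_two_sample = two$p.value,
       t_paired = if (is.null(paired)) 0 else unname(paired$statistic),
       psa_wins = mean(qt) > mean(qc))
}

#' Early-versus-late training contrast
#'
#' Compares mean operational quality of the first three and last three
#' formal training rounds - the within-training learning signature.
#'
#' @param history a training-session history data frame.
#' @return list with `early_mean`, `late_mean`, `improved`.
#' @export
early_late_contrast <- function(history) {
  formal <- history[history$formal, ]
  early <- head(formal$quality, 3)
  late <- tail(formal$quality, 3)
  list(early_mean = mean(early), late_mean = mean(late),
       improved = mean(late) > mean(early))
}
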