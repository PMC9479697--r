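# Simulated teleoperation tasks on a continuous 2-D plane (dimensionless
# units). The robot's applied displacement per control step is the
# operator's intent times the current speed multiplier; deviation and
# elapsed time feed the operational-quality reward.

# Piecewise-linear preset trajectories for the three tracking difficulty
# levels. All have total arc length ~ `length`.
tracking_path <- function(difficulty = c("straight", "slope", "curve"),
                          length = 40, n_pts = 200L) {
  difficulty <- match.arg(difficulty)
  s <- seq(0, 1, length.out = n_pts)
  pts <- switch(difficulty,
    straight = cbind(s * length, 0),
    slope = {  # ramp with one corner at midpoint
      x <- s * length * cos(pi / 8)
      y <- ifelse(s < 0.5, s, 1 - s) * length * sin(pi / 8) * 2
      cbind(x, y * 0.5)
    },
    curve = cbind(s * length * 0.9,
                  4 * sin(2 * pi * s * 1.5)))
  unname(pts)
}

# Distance from point p to the polyline, plus arc-length of the nearest
# projection (for progress tracking).
polyline_project <- function(path, p) {
  A <- path[-nrow(path), , drop = FALSE]
  B <- path[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  tpar <- pmin(pmax(((p[1] - A[, 1]) * AB[, 1] + (p[2] - A[, 2]) * AB[, 2]) / len2, 0), 1)
  proj <- A + AB * tpar
  d2 <- (p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2
  i <- which.min(d2)
  seg_len <- sqrt(len2)
  arc <- c(0, cumsum(seg_len))
  list(dist = sqrt(d2[i]), arc = arc[i] + tpar[i] * seg_len[i],
       point = proj[i, ])
}

path_point_at_arc <- function(path, arc_target) {
  seg_len <- sqrt(rowSums(diff(path)^2))
  arc <- c(0, cumsum(seg_len))
  total <- arc[length(arc)]
  a <- min(max(arc_target, 0), total)
  i <- findInterval(a, arc, rightmost.closed = TRUE)
  i <- min(i, length(seg_len))
  frac <- if (seg_len[i] > 0) (a - arc[i]) / seg_len[i] else 0
  path[i, ] + frac * (path[i + 1, ] - path[i, ])
}

#' Create a trajectory-tracking task environment
#'
#' The robot starts at the first waypoint of a preset polyline trajectory
#' (three difficulty levels: `straight`, `slope`, `curve`) and must reach
#' its endpoint. Every control step accumulates the perpendicular distance
#' between robot and trajectory; the reward combines inverse accumulated
#' deviation with a time term.
#'
#' @param difficulty tracking difficulty level.
#' @param config a [psa_config()] list (task section used).
#' @return a `psa_env` state list (functional: stepping returns a new one).
#' @export
make_tracking_env <- function(difficulty = "curve", config = psa_config()) {
  tk <- config$task
  path <- tracking_path(difficulty, tk$track_length)
  structure(list(task = "tracking", path = path, difficulty = difficulty,
                 total_arc = sum(sqrt(rowSums(diff(path)^2))),
                 pos = path[1, ], t = 0, dev_sum = 0, n_steps = 0L,
                 done = FALSE, t_complete = NA_real_, config = tk),
            class = "psa_env")
}

#' Create a target-positioning task environment
#'
#' The sight starts at the origin; a bullseye is placed at a random
#' direction and distance (re-randomized each round via `env_reset`). The
#' round succeeds once the sight frame fully encloses the bullseye ring
#' continuously for the lock duration `T`; leaving the enclosure resets the
#' lock timer.
#'
#' @inheritParams make_tracking_env
#' @export
make_positioning_env <- function(config = psa_config()) {
  tk <- config$task
  structure(list(task = "positioning", pos = c(0, 0), bullseye = c(tk$pos_dist[2], 0),
                 t = 0, lock = 0, n_steps = 0L, done = FALSE,
                 t_complete = NA_real_, config = tk),
            class = "psa_env")
}

#' Reset an environment to the start of a round
#'
#' Restores position, clocks and accumulators; for the positioning task the
#' bullseye is redrawn from the global RNG stream (seed it for reproducible
#' bullseye sequences).
#'
#' @param env a `psa_env`.
#' @return the reset environment.
#' @export
env_reset <- function(env) {
  env$t <- 0; env$n_steps <- 0L; env$done <- FALSE; env$t_complete <- NA_real_
  if (env$task == "tracking") {
    env$pos <- env$path[1, ]
    env$dev_sum <- 0
  } else {
    env$pos <- c(0, 0)
    env$lock <- 0
    d <- runif(1, env$config$pos_dist[1], env$config$pos_dist[2])
    ang <- runif(1, 0, 2 * pi)
    env$bullseye <- d * c(cos(ang), sin(ang))
  }
  env
}

apply_command <- function(env, command, speed_multiplier) {
  disp <- command * speed_multiplier
  mag <- sqrt(sum(disp^2))
  cap <- env$config$max_disp
  if (mag > cap) disp <- disp * cap / mag
  env$pos + disp
}

#' Advance the tracking task by one control step
#'
#' @param env a tracking `psa_env` with an active round.
#' @param command operator 2-D displacement intent.
#' @param speed_multiplier current speed factor (from the policy's action).
#' @param dt step duration in seconds.
#' @return the updated environment; `done` becomes `TRUE` at the endpoint.
#' @export
step_tracking <- function(env, command, speed_multiplier, dt) {
  if (env$done) stop("round over: cannot step a completed round")
  env$pos <- apply_command(env, command, speed_multiplier)
  pr <- polyline_project(env$path, env$pos)
  # deviation integrates over time, in policy-step units, so that control
  # sub-ticks shorter than the policy cadence contribute proportionally
  env$dev_sum <- env$dev_sum + pr$dist * dt / env$config$dt
  env$t <- env$t + dt
  env$n_steps <- env$n_steps + 1L
  if (pr$arc >= env$total_arc - 1e-6 ||
      sqrt(sum((env$pos - env$path[nrow(env$path), ])^2)) < 0.5) {
    env$done <- TRUE
    env$t_complete <- env$t
  }
  env
}

#' Advance the positioning task by one control step
#'
#' @inheritParams step_tracking
#' @export
step_positioning <- function(env, command, speed_multiplier, dt) {
  if (env$done) stop("round over: cannot step a completed round")
  env$pos <- apply_command(env, command, speed_multiplier)
  env$t <- env$t + dt
  env$n_steps <- env$n_steps + 1L
  if (sqrt(sum((env$pos - env$bullseye)^2)) <= env$config$enclose_radius) {
    env$lock <- env$lock + dt
  } else {
    env$lock <- 0
  }
  if (env$lock >= env$config$lock_T) {
    env$done <- TRUE
    env$t_complete <- env$t
  }
  env
}

#' Operational-quality rewards
#'
#' Tracking: `R_t = 1 / (sum |Y_m - O_m| + eps) + g * t + offset`;
#' positioning: `R_p = g * t + offset` on success. The time-gain
#' coefficient `g` defaults to a negative value so that, consistent with
#' the tasks' goal, shorter completion times score higher; a positive
#' offset keeps reported qualities positive. Setting `g > 0` and
#' `offset = 0` recovers the raw literal form.
#'
#' @param deviation_sum accumulated trajectory deviation (nonnegative).
#' @param t round completion time in seconds (positive).
#' @param g time-gain coefficient.
#' @param offset additive reporting offset.
#' @param eps floor avoiding division by zero for perfect tracking.
#' @return scalar reward.
#' @export
reward_tracking <- function(deviation_sum, t, g = -0.002, offset = 0.3, eps = 1e-6) {
  if (t <= 0) stop("invalid input: t must be positive")
  if (deviation_sum < 0) stop("invalid input: deviation_sum must be nonnegative")
  1 / max(deviation_sum, eps) + g * t + offset
}

#' @rdname reward_tracking
#' @param T_lock required continuous lock duration (success precondition).
#' @export
reward_positioning <- function(t, g = -0.01, T_lock = 2.4, offset = 1.0) {
  if (is.na(t) || t < T_lock)
    stop("invalid state: positioning reward requires a successful round (t >= T)")
  g * t + offset
}

episode_reward <- function(env) {
  tk <- env$config
  truncated <- !env$done
  t <- if (env$done) env$t_complete else env$t
  r <- if (env$task == "tracking") {
    reward_tracking(env$dev_sum, max(t, tk$dt), tk$g, tk$offset_track, tk$dev_eps)
  } else {
    if (env$done) reward_positioning(t, tk$g_pos, tk$lock_T, tk$offset_pos)
    else tk$g_pos * t + tk$offset_pos   # timed out: worst-case time score
  }
  list(reward = r, t = t, truncated = truncated)
}

#' Operational quality of a completed round
#'
#' Maps a round record to the positive reporting scale used in session
#' summaries (identical to the episodic reward under the positive-offset
#' convention). Incomplete rounds are flagged.
#'
#' @param record a round record with `reward` and `truncated` fields.
#' @return scalar quality with attribute `partial` when truncated.
#' @export
operational_quality <- function(record) {
  q <- record$reward
  if (isTRUE(record$truncated)) attr(q, "partial") <- TRUE
  q
}
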