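# Synthetic operator: latent mental-state dynamics, state-dependent EEG/EOG
# generation, and state-dependent control noise. Every encoded link follows
# a direction the mental-state literature asserts for real operators:
# fatigue lowers broadband EEG variance (hence differential entropy), most
# strongly over occipital/parietal/prefrontal sites; stress raises
# temporal-lobe variance; low arousal raises the EOG low/high power ratio.
# Effect sizes are simulator calibration knobs, not empirical claims.

#' Create a synthetic operator profile
#'
#' @param style `"aggressive"` (prefers high speed levels, wider intent
#'   spread) or `"conservative"`.
#' @param base_pref preferred speed level in `0..3` (0 = fastest) when
#'   rested; defaults to 0 for aggressive, 2 for conservative operators.
#' @param base_noise control-noise floor (displacement units per step).
#' @param mismatch_gain slope of the noise penalty in squared level
#'   mismatch between applied and preferred speed.
#' @param gains named list of signal-generation gains (state -> band
#'   amplitude modulation coefficients).
#' @return an `psa_operator_profile` list.
#' @export
operator_profile <- function(style = c("conservative", "aggressive"),
                             base_pref = NULL, base_noise = 0.08,
                             mismatch_gain = 4.0, gains = list()) {
  style <- match.arg(style)
  if (is.null(base_pref)) base_pref <- if (style == "aggressive") 0L else 2L
  g <- list(fatigue_amp = 0.5, fatigue_focus = 1.0, fatigue_other = 0.4,
            stress_amp = 0.6, arousal_beta = 0.6, arousal_alpha = 0.6,
            valence_front = 0.4, eog_low_arousal = 4.0)
  g[names(gains)] <- gains
  aggressive <- style == "aggressive"
  structure(list(style = style, base_pref = as.integer(base_pref),
                 base_noise = base_noise, mismatch_gain = mismatch_gain,
                 intent_spread = if (aggressive) 1.25 else 1.0,
                 # trait set-points of the latent dynamics: aggressive
                 # operators run "hotter" (sensation-seeking), conservative
                 # ones calmer - this is what the policy personalizes to
                 trait_arousal = if (aggressive) 0.85 else 0.75,
                 trait_valence = if (aggressive) 0.75 else 0.35,
                 gains = g),
            class = "psa_operator_profile")
}

#' The simulated six-operator cohort
#'
#' Six operator profiles mirroring the study cohort composition: operators
#' 1 and 5 aggressive, the remaining four conservative, with small
#' individual differences in control precision and mismatch sensitivity.
#'
#' @return named list of six [operator_profile()] objects.
#' @export
operator_cohort <- function() {
  list(
    op1 = operator_profile("aggressive", base_noise = 0.075),
    op2 = operator_profile("conservative", base_noise = 0.085),
    op3 = operator_profile("conservative", base_noise = 0.080, mismatch_gain = 4.5),
    op4 = operator_profile("conservative", base_noise = 0.070, mismatch_gain = 3.2),
    op5 = operator_profile("aggressive", base_noise = 0.090),
    op6 = operator_profile("conservative", base_noise = 0.090))
}

#' Initial latent mental state
#'
#' @param arousal,valence,fatigue,stress values in `[0, 1]`.
#' @return latent-state list with a `time_on_task` clock (seconds).
#' @export
latent_state <- function(arousal = 0.8, valence = 0.6, fatigue = 0.1,
                         stress = 0.1) {
  list(arousal = arousal, valence = valence, fatigue = fatigue,
       stress = stress, time_on_task = 0)
}

#' @rdname latent_state
#' @param profile an [operator_profile()]; the session-start state sits at
#'   the profile's trait set-points.
#' @export
initial_state <- function(profile) {
  latent_state(arousal = profile$trait_arousal, valence = profile$trait_valence)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Advance the latent mental state
#'
#' First-order saturating update: fatigue grows with time on task and
#' decreases on rest events; stress jumps on nervous events and decays
#' exponentially (half-life ~80 s); valence responds to positive/negative
#' prompts and drifts back to neutral; arousal relaxes toward a
#' fatigue-dependent setpoint. All dimensions stay in `[0, 1]`.
#'
#' @param state a [latent_state()].
#' @param profile an [operator_profile()].
#' @param events character vector among `"rest"`, `"nervous"`,
#'   `"positive"`, `"negative"`.
#' @param dt elapsed time in seconds (positive).
#' @param noise_sd bounded perturbation scale (uniform, +/- 2 sd).
#' @return the updated latent state.
#' @export
step_latent <- function(state, profile, events = character(), dt,
                        noise_sd = 0.01) {
  if (dt <= 0) stop("dt must be positive")
  jitter <- function() runif(1, -2 * noise_sd, 2 * noise_sd)
  state$time_on_task <- state$time_on_task + dt
  state$fatigue <- state$fatigue + (1 - state$fatigue) * (1 - exp(-dt * 0.0007))
  if ("rest" %in% events) state$fatigue <- state$fatigue * 0.5
  state$stress <- state$stress * exp(-dt / 115)
  if ("nervous" %in% events) state$stress <- state$stress + 0.5 * (1 - state$stress)
  state$valence <- state$valence + (profile$trait_valence - state$valence) *
    (1 - exp(-dt / 400))
  if ("positive" %in% events) state$valence <- state$valence + 0.2 * (1 - state$valence)
  if ("negative" %in% events) state$valence <- state$valence - 0.2 * state$valence
  target_arousal <- profile$trait_arousal - 0.65 * state$fatigue
  state$arousal <- state$arousal + (target_arousal - state$arousal) *
    (1 - exp(-dt / 90)) + jitter()
  for (nm in c("arousal", "valence", "fatigue", "stress"))
    state[[nm]] <- clamp01(state[[nm]])
  state
}

# Channel groups by 10-20 label prefix.
channel_region <- function(labels) {
  ifelse(grepl("^(Fp|O|P)", labels), "fatigue_focus",
         ifelse(grepl("^(T|FT|TP)", labels), "temporal", "other"))
}

# Contiguous synthesis bands (Hz) used to color the EEG noise.
synth_bands <- function() {
  list(delta = c(0.5, 3.5), theta = c(3.5, 7.5), alpha = c(7.5, 15.5),
       beta = c(15.5, 31.5), gamma = c(31.5, 44))
}

#' Emit a mental-state-dependent multichannel EEG/EOG recording
#'
#' EEG channels are sums of band-limited noise (delta..gamma) whose
#' amplitudes are modulated by the latent state: fatigue suppresses
#' broadband amplitude (most over occipital/parietal/prefrontal channels,
#' lowering differential entropy there), stress amplifies temporal-channel
#' amplitude, arousal shifts the alpha/beta balance and valence modulates
#' frontal beta. EOG channels carry a slow component whose power grows as
#' arousal falls plus a fixed high-frequency component, so the low/high
#' power ratio is inversely tied to arousal. Reproducible under a fixed
#' RNG seed.
#'
#' @param state a [latent_state()].
#' @param profile an [operator_profile()].
#' @param duration recording length in seconds (>= 2).
#' @param fs sampling rate in Hz (default 1000, the acquisition rate).
#' @return a `psa_recording` with the standard 30 EEG + 2 EOG montage.
#' @export
emit_signals <- function(state, profile, duration = 62, fs = 1000) {
  if (duration < 2) stop("duration must be >= 2 s")
  n <- round(duration * fs)
  labels <- psa_montage()
  modality <- psa_modality()
  eeg_labels <- labels[modality == "EEG"]
  region <- channel_region(eeg_labels)
  g <- profile$gains
  bands <- synth_bands()
  base_amp <- c(delta = 8, theta = 6, alpha = 10, beta = 4, gamma = 2)

  # broadband state modulation per channel
  fatigue_w <- ifelse(region == "fatigue_focus", g$fatigue_focus, g$fatigue_other)
  ch_mult <- (1 - g$fatigue_amp * state$fatigue * fatigue_w) *
    (1 + ifelse(region == "temporal", g$stress_amp * state$stress, 0))
  # band-specific modulation (rows: bands, cols: channels)
  frontal <- grepl("^F", eeg_labels)
  band_mult <- matrix(1, 5, length(eeg_labels),
                      dimnames = list(names(bands), eeg_labels))
  band_mult["alpha", ] <- 1 + g$arousal_alpha * (0.5 - state$arousal)
  band_mult["beta", ] <- 1 + g$arousal_beta * (state$arousal - 0.5)
  band_mult["beta", frontal] <- band_mult["beta", frontal] *
    (1 + g$valence_front * (state$valence - 0.5))

  white <- matrix(rnorm(n * length(labels)), n)
  # 7 colored-noise components: 5 EEG rhythm bands + EOG slow/fast
  band_filters <- c(lapply(bands, function(e)
    signal::butter(2, pmin(e, fs / 2 * 0.99) / (fs / 2), type = "pass")),
    list(eog_low = signal::butter(2, c(0.1, 1.5) / (fs / 2), type = "pass"),
         eog_high = signal::butter(2, c(1.5, 30) / (fs / 2), type = "pass")))
  amps <- matrix(0, 7, length(labels))
  n_eeg <- length(eeg_labels)
  for (bi in 1:5)
    amps[bi, seq_len(n_eeg)] <- base_amp[bi] * ch_mult * band_mult[bi, ]
  amp_lo <- 20 * (1 + g$eog_low_arousal * (1 - state$arousal))
  amps[6, n_eeg + 1:2] <- amp_lo
  amps[7, n_eeg + 1:2] <- 15
  X <- cpp_mix_bands(white, lapply(band_filters, `[[`, "b"),
                     lapply(band_filters, `[[`, "a"), amps)
  new_recording(X, fs, labels, modality)
}

#' Preferred speed level of an operator in a given state
#'
#' Aggressive profiles prefer fast levels (low indices), conservative ones
#' moderate speeds; marked fatigue shifts the preference one level slower.
#'
#' @inheritParams step_latent
#' @return integer level in `0..3` (0 = fastest).
#' @export
preferred_level <- function(state, profile) {
  lev <- profile$base_pref
  if (state$fatigue > 0.65) lev <- lev + 1L
  max(min(lev, 3L), 0L)
}

#' Operator control intent for the current step
#'
#' Intent points along the task (toward a look-ahead point on the tracking
#' path, or toward the bullseye), compensated for the currently applied
#' speed multiplier, plus Gaussian noise whose scale grows with the squared
#' mismatch between applied and preferred speed level and with
#' fatigue/stress. The mismatch-dependent noise is what makes speed
#' adaptation matter: a robot speed that suits the operator's state yields
#' precise control.
#'
#' @param state a [latent_state()].
#' @param profile an [operator_profile()].
#' @param env a `psa_env` with an active round.
#' @param applied_level speed level currently applied (0-based).
#' @param multipliers level-to-multiplier map.
#' @param frac fraction of a full policy step this correction covers
#'   (1 for a whole step; `1/substeps` for a hand-correction sub-tick).
#'   Jitter scales with `sqrt(frac)` as white control noise should.
#' @return 2-D intent vector (a `ControlCommand`).
#' @export
control_intent <- function(state, profile, env, applied_level,
                           multipliers = c(2.0, 1.5, 1.0, 0.5), frac = 1) {
  mult <- multipliers[applied_level + 1L]
  base_step <- env$config$step_base * profile$intent_spread
  if (env$task == "tracking") {
    pr <- polyline_project(env$path, env$pos)
    ahead <- path_point_at_arc(env$path, pr$arc + base_step * mult * 1.5)
    delta <- ahead - env$pos
  } else {
    delta <- env$bullseye - env$pos
  }
  dist <- sqrt(sum(delta^2))
  dir <- if (dist > 1e-12) delta / dist else c(0, 0)
  step_mag <- min(base_step * frac, dist / mult)
  mismatch <- abs(applied_level - preferred_level(state, profile))
  sdv <- profile$base_noise * (1 + profile$mismatch_gain * mismatch^2) *
    (1 + 0.4 * state$fatigue + 0.3 * state$stress)
  # hand jitter lives in screen space: divide by the multiplier so the
  # robot-side noise magnitude does not shrink just because speed is low
  dir * step_mag + rnorm(2, 0, sdv * sqrt(frac)) / mult
}

#' Synthetic four-class valence/arousal feature set
#'
#' Emulates a DEAP-style pretraining table: the operator model emits
#' signals at the four (valence, arousal) corner states - high/high,
#' high/low, low/high, low/low, labeled 0..3 in that order - and each
#' emission runs through the real preprocessing and feature pipeline.
#' Classes are balanced.
#'
#' @param n_per_class windows per class.
#' @param profile operator profile used for emission.
#' @param config a [psa_config()] list.
#' @param seed optional RNG seed.
#' @return list: `X` (feature matrix, `4 * n_per_class` rows x 152),
#'   `y` (integer labels 0..3), `normalizer` (min-max stats of `X`).
#' @export
make_deap_like_dataset <- function(n_per_class = 40L, profile = operator_profile(),
                                   config = psa_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  corners <- list(c(v = 0.85, a = 0.85), c(v = 0.85, a = 0.15),
                  c(v = 0.15, a = 0.85), c(v = 0.15, a = 0.15))
  pp <- config$preprocess
  stride_s <- 1.183  # matches the 60 s / 50-window tiling cadence
  dur <- pp$window_ms / 1000 + (n_per_class - 1) * stride_s + 1
  Xs <- vector("list", 4)
  for (cls in 1:4) {
    st <- latent_state(arousal = corners[[cls]]["a"],
                       valence = corners[[cls]]["v"],
                       fatigue = 0.2, stress = 0.15)
    rec <- emit_signals(st, profile, duration = dur, fs = pp$fs_raw)
    cfg_cls <- config
    cfg_cls$preprocess$n_windows <- n_per_class
    prep <- preprocess_recording(rec, cfg_cls)
    Xs[[cls]] <- features_from_windows(prep, config$features$eeg_feature, config)
  }
  X <- do.call(rbind, Xs)
  y <- rep(0:3, each = n_per_class)
  norm <- update_normalizer(make_normalizer(ncol(X)), X)
  list(X = apply_normalizer(norm, X), y = y, normalizer = norm)
}
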