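---
title: "Personalized speed adaptation from EEG/EOG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized speed adaptation from EEG/EOG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psasim)
```

# The problem

Teleoperators differ: a robot speed that one operator finds comfortable
makes another imprecise or bored, and the same operator's sweet spot moves
as they fatigue or get stressed. `psasim` implements a closed-loop
*personalized speed adaptation* (PSA) system: the operator's mental state
is decoded continuously from EEG and EOG, a small policy network maps the
decoded state to one of four robot speed levels, and the policy is trained
online by policy-gradient reinforcement learning with the round's
*operational quality* as reward. Because humans cannot sit inside a test
suite, the package pairs the method with a synthetic operator whose latent
arousal/valence/fatigue/stress dynamics drive both its signals and its
control precision; everything from raw microvolts to the trained policy
runs exactly as it would on real recordings.

# Signal path

## Preprocessing

Raw recordings are 30 EEG + 2 EOG channels at 1000 Hz. Each round buffers
one minute of signal and applies three steps, in this order:

1. **Baseline removal** — a least-squares polynomial trend (degree 1 by
   default, configurable) is fitted per channel and subtracted.
2. **Band-pass filtering** — 4th-order Butterworth, 0.5–45 Hz for EEG and
   0.1–30 Hz for EOG. Filtering is zero-phase (forward–backward) by
   default because the pipeline operates on buffered round data, where the
   squared-magnitude response costs nothing and group delay would smear
   features across windows; a causal single pass is available
   (`zero_phase = FALSE`) for streaming-style use.
3. **Downsampling** — EEG to 256 Hz, EOG to 128 Hz, by a Kaiser-windowed
   sinc polyphase interpolator whose cutoff sits at the output Nyquist
   rate (the preceding band-pass already guarantees band-limitation). An
   FFT-domain resampler is available as an alternative.

The minute is then cut into 50 windows of 2000 ms. The stride is
`floor((L - W) / 49)` samples, the unique uniform tiling that produces
exactly 50 windows — the source material states the window count and
duration but not the stride. Windows never span round boundaries; each
round's buffer is windowed independently.

## Rhythm bands

Each 512-sample EEG window is decomposed with a 5-level periodized
discrete wavelet transform using the Daubechies basis with five vanishing
moments (db5). At 256 Hz the dyadic levels map onto the canonical rhythm
bands: A5 is delta (0–4 Hz), D5 theta (4–8 Hz), D4 alpha (8–16 Hz), D3
beta (16–32 Hz). Gamma is taken as D1 + D2 (32–128 Hz): the gamma band is
defined open-endedly ("above 32 Hz"), and keeping D1 preserves exact
perfect reconstruction — the five band series sum back to the window to
machine precision, which the test suite asserts for arbitrary inputs.
After the 45 Hz low-pass, D1 carries essentially no energy, so this choice
does not move any feature.

The batch feature path never reconstructs the bands explicitly: for an
orthonormal transform the sum of squares of a band's reconstruction equals
that of its coefficients (Parseval), detail reconstructions have exactly
zero mean, and the approximation carries the window mean. Band variances —
all that DE/BP/BE need — therefore come straight from the analysis
coefficients; the tests verify this path agrees with explicit
reconstruction to 1e-10.

## Mental-state features

Per channel and band, four candidate features are implemented:

* **Differential entropy (DE)** — `0.5 * log(2 * pi * e * sigma^2)` with
  `sigma^2` the mean squared mean-removed amplitude: the Gaussian
  closed form of continuous entropy. This is the default state feature.
* **Sample entropy (SE)** — `-ln(B^(v+1)/B^v)` with template length
  `v = 2` and tolerance `0.2 * sd`, Chebyshev distance, self-matches
  excluded (the Richman–Moorman convention; the source's wording of the
  count definition is garbled, so the standard convention is adopted).
* **Band power / band energy (BP/BE)** — time-domain mean square and sum
  of squares of the band series (the original definitions are delegated
  to citations; the time-domain reading is the simplest consistent one,
  and the functions are exported and replaceable).

The two EOG channels contribute one **power ratio (PR)** each: integrated
Welch power (1 s Hann segments, 50% overlap) over 0–1.5 Hz divided by
1.5–30 Hz, with a 1e-12 floor on the denominator. PR rises when arousal
falls. The state vector is 30 channels x 5 bands of the selected EEG
feature plus the 2 PR values — 152 dimensions, channels in montage order,
bands delta..gamma within each channel, EOG last.

Features are normalized per dimension to [0, 1] by running min–max
statistics accumulated during the training session (including practice
rounds and the pretraining corpus) and frozen for testing/control
sessions, where out-of-range values clip. The source says only
"normalized"; running min–max is the only choice that works online without
a second pass over data that does not exist yet.

**Feature ranking.** `rank_features()` scores any candidate table by
plug-in mutual information (natural log; continuous features binned into 8
equal-frequency bins, configurable) against discrete labels. One caveat
discovered during design and worth stating plainly: on the package's
Gaussian synthetic signals, DE and BP are monotone transforms of one
another within a band, so equal-frequency binning gives them *identical*
MI — the DE-versus-BP gap reported for real EEG reflects non-Gaussian
structure the generator does not emulate. The ranking machinery is
therefore validated on constructed feature tables, and the DE default is
adopted as the established conclusion rather than re-derived from
synthetic data.

# The policy and its training

## Network

The state-to-action mapping network is 152–80–4: tanh hidden layer,
softmax output, one output neuron per speed level. Weights initialize
uniform, scaled by `1/sqrt(fan_in)`; gradients of `log p(a|s)` are exact
analytic backpropagation (finite-difference agreement to 1e-4 relative is
an acceptance property, which is why no autodiff framework is involved).

**Speed levels are enumerated fast to slow**: level 0 applies multiplier
2.0, level 3 applies 0.5. The reason is the pretraining contract below —
the four affect classes are ordered from high-valence/high-arousal to
low/low, and mapping class index directly to action index then encodes
"alert and positive operators get full speed, drowsy and negative ones get
slow" — the only orientation under which the warm start helps rather than
fights the subsequent adaptation. The map is a config entry
(`policy$multipliers`) and can be reversed to taste.

## Pretraining

Before closed-loop training, the network is fitted by minibatch ADAM
(batch 50) on a labeled four-class set — high/low valence x high/low
arousal, class index = action index — minimizing softmax cross-entropy
(the standard pairing with a softmax output; the source names only a loss
value). The default corpus is synthetic: `make_deap_like_dataset()` emits
signals at the four corner states through the *real* preprocessing and
feature pipeline, so pretraining sees exactly the feature distribution the
controller will see. An external DEAP-style feature/label table can be
substituted; nothing in the package requires the actual dataset. The
protocol default is 400 samples x 120 epochs — enough to separate the
quadrants while keeping the output distribution soft; a near-saturated
softmax would freeze the policy, since 15 episodes of ADAM at learning
rate 0.001 can move each logit by roughly
`lr * (hidden_width * E|h| + 1) * episodes ~ 0.7`, not the 3+ needed to
overturn a confident prior. ADAM's moment accumulators are reset when the
objective switches from cross-entropy to the policy gradient.

## REINFORCE with baseline

Each round is one episode: 50 (state, action) pairs sharing the single
episodic reward (no per-step reward exists — credit assignment is
uniform). The update is the Monte-Carlo policy gradient with a baseline,

`grad = (1/N) * sum_n sum_i (R(tau_n) - b) * grad log p(a_i | s_i)`,

applied through ADAM ascent (beta1 = 0.9, beta2 = 0.999, lr = 0.001) once
per episode (N = 1; batched variants remain a config option). The baseline
is the running mean of all formal-episode rewards, initialized to the
first episode's reward — the simplest estimator of `E[R]`, and the tests
assert the gradient is invariant to shifting rewards and baseline
together. Rewards are used raw; the baseline handles scale. The first 3
of 18 training rounds are practice: they accumulate normalization
statistics and update nothing.

## Convergence

Human-in-the-loop training has no fixed optimum, so convergence is
declared from two observables over the last `W = 5` episodes: the reward's
coefficient of variation stays below 0.15, and in at least 80% of each
episode's steps the chosen level lies within one level of the operator's
preferred level (the simulated satisfaction proxy standing in for the
operator's subjective evaluation). The numerical thresholds quantify
criteria the source states only qualitatively.

# Tasks and rewards

Both tasks live on a continuous dimensionless 2-D plane with a control
step of `dt = 1.2` s, tying one episode to the 50-window cadence
(50 x 1.2 s + 2 s window = the one-minute buffer).

* **Trajectory tracking** — the robot follows a preset polyline (arc
  length 40) at one of three difficulty levels: straight, slope (one
  corner) and curve (sinusoid). Deviation accumulates each step as the
  perpendicular distance to the nearest segment. Reward:
  `R_t = 1/(sum|Y - O| + 1e-6) + g*t + offset` with `g = -0.002` and
  offset 0.3.
* **Target positioning** — the sight must fully enclose a re-randomized
  bullseye (enclosure radius 0.45) continuously for `T = 2.4` s; leaving
  the ring resets the lock timer. Reward: `R_p = g*t + offset` on success
  (`g = -0.01`, offset 1.0), with `t >= T` read as the success condition.

As printed, the literal time term would *reward* slow completion while the
task descriptions state the opposite; `g` therefore defaults negative with
a positive offset keeping reported qualities positive, and the literal
form is recoverable by `g > 0, offset = 0`. Tasks that never complete
within the round keep collecting (state, action) pairs — the mental-state
buffer covers the whole minute — and are scored on elapsed time with a
truncation flag, so every episode carries exactly 50 pairs.

# The synthetic operator

The operator model is invented plumbing: its role is to make the paper's
premise — mental state degrades operational quality, and the right speed
mitigates it — simulable. Every encoded link is a direction asserted for
real operators; all gains are calibration knobs in config, not claims.

* **Latent dynamics.** Fatigue grows saturatingly with time on task (time
  constant ~24 min) and halves on rest breaks (scheduled after every 5
  rounds in every session, so a session shows a roughly stationary fatigue
  sawtooth rather than a monotone trend that would confound early-late
  contrasts); stress jumps on "nervous" prompts and decays (~2 min);
  valence responds to positive/negative prompts and relaxes to a trait
  set-point; arousal relaxes toward `trait - 0.65 * fatigue`. The timed
  prompts of the experimental protocol are implemented as latent-state
  perturbations rather than UI text, since their experimental function was
  to diversify mental states.
* **Signals.** Each EEG channel is a sum of five band-limited noise
  processes (Butterworth-colored white noise) whose amplitudes the state
  modulates: fatigue suppresses broadband amplitude, with full weight over
  occipital/parietal/prefrontal channels (10–20 prefixes O/P/Fp) and 0.4
  elsewhere, so DE drops most where it should; stress amplifies temporal
  channels (T/FT/TP) by up to 60%; arousal tilts the alpha/beta balance;
  valence modulates frontal beta. EOG mixes a slow component whose
  amplitude grows as arousal falls with a fixed faster component, giving
  the PR its inverse-arousal link. The tests verify every link *through
  the full implemented pipeline*, not on generator internals.
* **Control.** The hand corrects 4 times per policy step (a 0.3 s motor
  cadence against the 1.2 s adaptation cadence). Intent points along the
  task (with a look-ahead on curves) and is speed-compensated; hand jitter
  is Gaussian in screen space with standard deviation
  `base * (1 + gain * mismatch^2) * (1 + 0.4*fatigue + 0.3*stress)`
  per policy step (sub-ticks scale it by `sqrt(1/4)`), where `mismatch`
  is the level distance between applied and preferred speed. This
  mismatch penalty is the minimal mechanism under which personalized
  speed adaptation can improve quality at all, and its slope (default 4)
  is set so the operational-quality gap between adjacent speed levels
  (~0.07) clearly exceeds the round-to-round noise at the preferred level
  (~0.03) - the condition under which fifteen baseline-corrected
  policy-gradient updates carry a detectable learning signature rather
  than a random walk. Preferred level: 0 (2.0x) for aggressive profiles,
  2 (1.0x) for conservative, one level slower under marked fatigue.
* **Styles.** Aggressive operators have wider intent magnitudes and trait
  set-points in the high-valence/high-arousal quadrant; conservative
  operators sit in the low-valence/high-arousal quadrant. Each style thus
  inhabits one corner of the pretraining class set, which is also what
  makes the warm start informative. The six-profile cohort
  (`operator_cohort()`) mirrors the study composition: operators 1 and 5
  aggressive, four conservative, with individual differences in control
  precision (base noise 0.07–0.09) and mismatch sensitivity (1.4–2.0).

What the generator does **not** emulate: non-Gaussian EEG morphology
(spindles, transients, blinks, saccade waveforms), volume conduction,
electrode artifacts, or any quantitative effect size. Passing tests
therefore show the *method* behaves as designed under the stated
state-to-signal links — not that it would reach any particular accuracy
on human recordings.

# Experimental protocol

`run_protocol()` runs the three sessions: training (18 rounds, first 3
practice, learning on), testing (15 rounds, trained parameters imported,
learning off), control (15 rounds, conventional method). Testing and
control rounds are seeded identically, so both arms face the same operator
signal streams. The conventional arm is the warning-threshold method: a
scalar mental-state indicator — here the normalized mean EOG power ratio
of the current window, a low-arousal proxy — against a fixed threshold
(default: the median over the practice rounds); above the threshold the
speed drops to a fixed slow fallback (level 3, 0.5x), otherwise a fixed
mid-range cruise (level 1, 1.5x) applies. Those two preset levels are what
a non-personalizing designer ships; the indicator and threshold are
documented defaults, not reconstructions. Comparisons report means,
standard deviations and paired/two-sample t statistics of per-round
quality — descriptive statistics of simulation output, with no
human-subject claim attached.

# Numerical choices and degenerate inputs

* Perfect-tracking rounds hit a 1e-6 floor instead of dividing by zero;
  saturated EOG ratios and sample entropies with zero (v+1)-matches return
  capped/infinite values flagged `saturated`.
* Zero-variance windows make DE a hard error rather than `-Inf`.
* Non-dyadic window lengths are zero-padded to a multiple of `2^levels`
  before the DWT and trimmed after reconstruction, which preserves the
  sum-to-window identity on the original support.
* All randomness flows from one master seed through named substreams;
  every run record carries its seed, and episode collection is bit-exactly
  reproducible.
* Problem sizes used by the verification suites: 20 seeds for the
  stochastic learning studies, 200 episodes for the bandit degenerate
  case, 6 operator profiles for the cohort comparison, and 40–100 windows
  per condition for the state-to-feature link checks — small enough to run
  routinely, large enough that the majority votes are stable.

# Known limitations

* The learning-rate ceiling is real: with ADAM at 0.001 and one update per
  episode, 15 formal episodes can only *tilt* the pretrained policy, which
  is why the warm start's orientation matters so much. Faster adaptation
  (more episodes, batched updates, entropy regularization) is out of scope
  here.
* The DE-vs-BP mutual-information ranking cannot be reproduced on Gaussian
  synthetic signals (see above); the package adopts DE as the default
  feature on the strength of the published conclusion.
* The EDF writer quantizes to 16 bits over each channel's observed range;
  round-trips are exact only to that quantization.
* The conventional baseline's strength depends on how well its two preset
  levels happen to fit an operator; the package's defaults deliberately
  model a generic, non-personalized preset.

```{r example, eval = FALSE}
# One full protocol on a conservative operator:
rp <- run_protocol("tracking", operator_profile("conservative"), seed = 1)
rp$comparison$mean_psa        # personalized arm, mean operational quality
rp$comparison$mean_conventional
rp$early_late                 # first-3 vs last-3 training rounds
```
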