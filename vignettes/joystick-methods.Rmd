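---
title: "Models and methods behind joykin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind joykin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(joykin)
```

`joykin` simulates and analyzes head-fixed mouse joystick behavior: two
task engines (an auditory-motor 2AFC and a two-armed bandit value task), a
joystick signal-processing chain, a trajectory-kinematics suite, a
movement-bout/vigor analysis, and a forgetting-Q-learning toolkit. This
vignette is the package's account of the underlying models, the tunable
parameters, the numerical choices, and what the synthetic generators do
and — just as importantly — do not emulate.

## The signal chain

Joystick position arrives either calibrated (mm) or as raw 10-bit ADC
codes, 0 (0 V) to 1023 (5 V) per axis, resting near the middle of the code
range. `adc_to_mm()` applies the per-box linear map
`x = slope_x (code − center) + offset`. We take the center code to be 512,
the midpoint of the code range (hardware rests "near the middle"; the exact
resting code varies by box and is overridable in `calibration()`).

Real-time controllers smooth the position with a trailing (causal) moving
average — `moving_average()` reproduces this with a default 20 ms window,
the value used to suppress single-sample electrical glitches at 1 kHz
sampling. A causal window was chosen deliberately over a centered one: it
is what a controller can compute online, and it keeps choice-detection
latencies honest (a centered filter would use future samples).

Baselines drift; `rebaseline()` re-estimates the rest position from the
first 50 ms after joystick extension and returns displacement from it.
Choices are anteroposterior displacements *strictly* greater than the
threshold (3 mm in the value task); `detect_choice()` registers the first
strict crossing in either direction and ignores everything after it. The
auditory task's displacement threshold is rig-specific and is therefore a
required parameter rather than a package default.

All simulated times are integer milliseconds at 1 kHz unless configured
otherwise. The coordinate convention — +x anterior (push), −x posterior
(pull), +y up — is used by every module.

## Task engines

Both engines are pure functions of (agent, config, seed): the same triple
reproduces a session bit for bit, which the test suite asserts.

**Auditory-motor 2AFC.** Each trial: a 2–5 s uniform pretrial interval, a
500 ms cue (12 kHz → push, 5 kHz → pull, each with five overtones), a 5 s
response window. Correct responses trigger reward after 200 ms (~10 µl);
wrong or missing displacements are omissions followed by 5 s of white
noise and a fresh intertrial interval. Sessions stop at 100 rewards or
30 min of simulated time. A "daily run" (`run_auditory_day()`) executes
the two single-association phases (low → pull, high → push) back to back
with the order alternating by day parity; a perfect agent therefore
completes 200 correct trials and collects 2 ml of water. One conflict in
the source material is worth noting: the omission-noise duration appears
both as 5 s and as 5 ms in different places; the package defaults to 5 s
and exposes `noise_on_omission_s`.

**Two-armed bandit.** After joystick extension and a 100 ms wait, a GO cue
opens a 10 s response window. The four trial outcomes partition every
session: rewarded and unrewarded trials are followed by a uniform 2.5–8 s
intertrial interval; omissions and premature responses by white noise and
a 15 s time-out. Reward is Bernoulli — 80% on the current high side, 20%
on the low side. Blocks last 17 rewarded trials plus a Geometric(0.4)
extension, after which the high side reverses without any cue. The
geometric variable is taken on support {0, 1, 2, …} so the printed
17-reward minimum is attainable (the alternative support {1, 2, …} would
make the minimum 18); its mean block length is 17 + 0.6/0.4 = 18.5
rewarded trials. In the changing-volume phase the reward volume is redrawn
uniformly from {2, 4, 8} µl at each reversal; the volume schedule within
the phase is not specified in the source material, and a uniform per-block
draw is the simplest schedule that exercises all three volumes. The plain
reversal phase uses a fixed 4 µl (the middle of the set; the source states
no value for this phase).

**Cue tones.** `synthesize_tone()` sums harmonics `k = 1..n_overtones+1`
of the fundamental with amplitudes `1/k` — a standard harmonic-decay law;
the source specifies the overtone count but not the amplitude law, so the
law is configurable. Harmonics at or above Nyquist are dropped with a
warning (at 96 kHz, the 12 kHz cue keeps three of its five overtones).
Tones can be exported as 16-bit PCM WAV.

## Virtual agents

The forgetting Q-learning agent is the package's reference behavior model
and the single source of truth shared with the fitting code:

* chosen action: `Q ← Q + α (r − Q)`;
* unchosen action: `Q ← (1 − α) Q` — decay toward zero at the *same* rate,
  the standard reading of "nondifferential" forgetting in this model
  family;
* choice rule: `P(push) = 1 / (1 + exp(−β (Q_push − Q_pull)))`, no bias
  term (the model has exactly two free parameters).

With rewards in {0, 1} and initial values in [0, 1], values stay in
[0, 1] — a tested invariant. WSLS, oracle (always the current high side —
a validation agent with privileged knowledge, not a behavior model),
random, fixed-choice and silent agents complete the set.

**Vigor coupling.** `vigor_gain` and `latency_gain` couple the agent's
total value `Q_push + Q_pull` to its synthetic traces: decisive-bout
displacement grows and pre-choice idle time shrinks with total value. This
is a minimal generative mechanism to reproduce the
higher-value-faster-and-larger phenotype in synthetic data — a modeling
device, not a claim about mice.

## Synthetic trajectories

`generate_trajectory_2d()` produces out-and-back 2D reaches controlled by
a learning `stage` in [0, 1]: lateral jitter and low-frequency meander
scale with `1 − stage`, speed with `0.4 + 0.6 stage`. Pushes head
downward–forward, pulls upward–backward, and the return leg stops 60% of
the way home so first-to-last chords (hence tortuosity) stay well defined.
Batches of increasing stage reproduce the qualitative learning trends —
falling tortuosity, falling pairwise Fréchet distance, shrinking explored
area, rising velocity — which the test suite checks end to end.

`generate_ap_trace()` builds 1D anteroposterior traces from explicit bout
specifications with half-sine velocity profiles (`displacement =
2 · peak · duration / π`), plus Gaussian baseline noise. It is the
closed-loop fixture for bout segmentation: programmed bout counts,
directions and boundaries are recovered by `segment_bouts()` across
randomized specifications.

What the generators do **not** emulate: biomechanics (no limb model, no
inertia), session-scale fatigue or satiety, lick behavior, paw slips,
sensor dropout, or any fitted correspondence to real mouse traces. Tests
passing on synthetic data validate the *analysis code* and the stated
orderings, not claims about animal behavior.

## Kinematics suite

Preprocessing removes consecutive duplicate coordinate pairs and centers
each trajectory on its median x and y. Then:

* **Tortuosity** — total path length over the first-to-last chord, ≥ 1 by
  the triangle inequality. The ratio is undefined for closed paths, so
  trajectories with net displacement < 0.5 mm are excluded with a reason
  rather than producing an unstable number; both the full-path and
  outbound-only variants are provided because the source describes the
  trajectory as running "to the point of maximum displacement and back"
  while defining the ratio on first-to-last points.
* **Discrete Fréchet distance** — exact dynamic programming over the
  coupling lattice. The discrete (not continuous) variant is used: traces
  are sampled polylines, and at 1 kHz sampling the discrete and continuous
  versions order trajectory pairs identically for all practical purposes.
  The DP is verified against a memoized naive recursion on hundreds of
  random short pairs. Session-level similarity is the mean over all
  unordered pairs; `resample_n` optionally resamples polylines
  (arc-length-uniform) first, since the all-pairs DP is quadratic in both
  trajectory count and length.
* **Movement velocity** — distance from the first point to the point of
  maximum displacement, divided by the elapsed time.
* **Explored area** — 1 mm² occupancy bins over a workspace spanning the
  global coordinate extrema; bins are half-open `[k, k+1)` with minima at
  bin edges and the top edge closing the last bin (the convention of
  standard 2D histogram routines). Area is the count of visited bins; the
  grid doubles as a heatmap (`plot_occupancy()`).
* **Angular deviation** — `s = sqrt(2 (1 − R̄))` with `R̄` the mean
  resultant length; 0 for identical angles, √2 for balanced ones. The
  session statistic pools inter-sample displacement directions by the
  occupancy bin of each segment's start, computes `s` per bin (≥ 2 angles)
  and averages over bins. The source does not state the bin partition nor
  whether angles are displacement directions or point angles; inter-sample
  displacement directions over the 1 mm² occupancy grid is the
  implementation, documented here as a choice.

## Movement bouts and vigor

Bout criteria: movement in one direction; initiation speed > 7.5 mm/s;
speed maintained > 2.5 mm/s for > 50 ms; bout ends on a velocity sign
change or joystick retraction. Implementation details that matter:

* velocity is the central finite difference of the 20 ms-smoothed,
  re-baselined trace — smoothing-before-differentiation is fixed so the
  thresholds remain meaningful at 1 kHz;
* all thresholds are strict, matching the printed ">" inequalities;
* a sign change closes the current bout and immediately opens an opposite
  bout when the new speed already exceeds the initiation threshold;
* the decisive bout is the bout whose span contains the threshold
  crossing; when smoothing shifts the crossing outside every bout, the
  nearest preceding bout is used and flagged (`decisive_fallback`), never
  silently.

Per-trial readouts: peak displacement (max |x|), bout count, directional
consistency (`n(bouts in most frequent direction)/n(all bouts)` — in
[0.5, 1] whenever bouts exist), decisive-bout mean velocity (absolute, not
signed: the downstream contrasts compare magnitudes), path length
(`Σ|Δx|`), and choice latency. `path_length ≥ peak_displacement` holds for
every trace.

## Value-model analysis

`fit_q_model()` maximizes the likelihood of a completed-choice series
(omissions and prematures are dropped before fitting but kept in session
logs) over a coarse grid — α in {0.025, …, 0.975} by 0.025, β in
{0, …, 20} by 0.25 — followed by Nelder-Mead refinement from the grid
optimum. The grid is evaluated exactly but factorized: the Q recursion
depends only on α, so one forward pass per α serves every β; a regression
test confirms equality with the naive double loop. The log-likelihood is
accumulated in a `log1p(exp())` form, so extreme `β·ΔQ` never underflows.
Rewards enter the model as 0/1 regardless of volume — volume effects are
analyzed through kinematics — with a config switch left off by default
because the source does not state whether its model scaled rewards.

Parameter recovery is the headline property: across α ∈ {0.2, 0.5, 0.8} ×
β ∈ {1, 3, 10} at n = 5,000 trials and 20 replicate seeds, the median
|α̂ − α| stays ≤ 0.1 (asserted in the test suite). Two caveats are worth
recording. First, on null (random-agent) data the likelihood has a shallow
ridge along α → 0 where β̂ can drift upward while improving the fit by
only a few nats over a coin-flip model; the tests therefore bound the
median β̂ over replicates and the likelihood gain, not a single draw.
Second, all-one-choice series put the optimum on the parameter boundary
and are flagged with a warning.

`uncertainty_split()` partitions trials at the median |ΔQ| (the source
says only "high" vs "low"); the split is sign-invariant and degenerates
gracefully (constant |ΔQ| → all trials low-uncertainty, with a warning).

`wsls_stats()` conditions stay/switch on the previous trial's outcome.
`repeat_choice_regression()` predicts repetition of the previous choice
from per-lag rewarded/unrewarded indicators. Because every completed trial
is one or the other, each indicator pair sums to one and an intercept
would be perfectly collinear; the model is therefore fit without one, so
each weight is directly the log-odds of repeating after that outcome. The
primary fit is binomial IRLS (`glm`); perfect separation (e.g. exact WSLS
data) or rank deficiency (pairs at lags ≥ 2 are mutually collinear) routes
to a ridge-stabilized IRLS (penalty 1e-4, convergence at relative
likelihood change < 1e-8, ≤ 100 iterations), always flagged.

`vigor_by_value_summary()` reports per-volume medians with a
Jonckheere-style ordered-trend statistic (explicit rank sums over ordered
group pairs) and low/high-|ΔQ| rank-sum contrasts, both with
label-permutation p-values (seeded, default 2,000 replicates here; set
`reps` to taste, 0 disables p-values). Permutation nulls were chosen over
parametric tests because the trial-level readouts are skewed and
integer-valued, and the source does not specify its tests. Groups with
fewer than 3 trials are excluded and named in the output.

## Problem sizes and determinism

Simulations in the examples and tests use session sizes a desk-scale study
would: 150–500-trial bandit sessions for kinematics, 2,000–10,000 trials
for probability checks, 5,000 trials per recovery replicate, batches of 30
trajectories per learning stage with all-pairs Fréchet on 40-point
resampled polylines. Every stochastic path is seeded: engines take a
`seed`, `run_experiment()` derives per-session seeds from a master seed
and records them in its manifest, and re-running a manifest reproduces
every CSV byte for byte.

## Known limitations

* The synthetic agents and trajectory generators are validation
  scaffolding; none of their parameters are fitted to animal data.
* The bout segmenter is strictly 1D (anteroposterior), matching the value
  task's hardware constraint; 2D bout analysis is out of scope.
* Only the two-parameter forgetting model is implemented — no model
  comparison across RL variants, and no hierarchical/population fitting.
* The auditory engine models choice and timing, not psychoacoustics: cue
  tones are synthesized for export, but the simulated agent maps cue
  identity to action directly.
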