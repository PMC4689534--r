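---
title: "Models and methods: phasic, tonic and quasi-tonic dopamine signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: phasic, tonic and quasi-tonic dopamine signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramplab)
```

This vignette is the package's own account of the science it implements:
the three models, the assumptions and parameter choices baked into their
defaults, the numerical decisions that were genuinely open, and what the
simulations do and do not establish about real dopamine recordings.

## The measurement model

All three accounts produce a time-varying "dopaminergic activity" signal;
what voltammetry measures is extracellular concentration. The package
converts between the two with a fixed impulse response, the alpha function
`f(t) = (t/ξ) exp(1 − t/ξ)`, which rises to a unit peak `ξ` seconds after a
punctate event and decays with the same time constant. The default
`ξ = 0.7` s matches the concentration transient evoked by brief electrical
stimulation of the midbrain. Three conventions matter:

* **Area scaling.** `convolve_drf()` multiplies the discrete convolution by
  the grid step, so a transient of a given *area* produces the same
  concentration response at any grid resolution. Punctate TD errors are
  therefore represented as one-sample impulses of height `area / dt`.
* **Asymmetry before convolution.** Negative prediction errors appear to be
  carried by pauses in firing and reach the concentration signal
  attenuated; `rectify_errors()` scales negative samples by `d = 1/6`
  *before* convolution, the order in which scaling is physiologically
  interpretable (it acts on activity, not on concentration).
* **Kernel truncation.** The kernel is cut at `10ξ`, where the tail is
  below `e^{-9}` of the peak; the bias is negligible and the cost bounded.
* **Grid step.** No single grid step is canonical for the convolutions; it
  is exposed everywhere as `dt` with default 0.01 s, the step used by the
  decision-process simulations.

Event-aligned averages (`aligned_average()`) use the `n − 1` standard
deviation over trials divided by `sqrt(n)`, the conventional error bar, and
exclude (with a warning) trials whose traces do not cover the window.

## Account 1: action-timing uncertainty in an actor-critic

The cued lever press is a semi-Markov decision process: cue (state 1),
preparedness to press signalled by efference copy at time `T` (state 2),
press completion `τ_post = 0.5` s later (state 3, reward `r` net of the
hyperbolic vigour cost `a/T + b`), then a fixed inter-trial interval
`τ_I = 30` s. Default utilities `a = −1, b = 0, r = 1`. The critic learns
*relative* values: rewards are measured against the average reward rate
`ρ`, computed as the renewal-reward ratio `E[u(T)] / E[T + τ_post + τ_I]`
by numerical quadrature.

Microstate values within state 1 satisfy the probability-weighted
consistency condition driven by the hazard of `T`. Numerically we solve the
equivalent *deficit* recursion `w(t) = P(stay) w(t+dt) + ρ dt` backward
from the grid horizon, where `w(t) = V(2) − V({1,t})`; this is linear,
exact to machine precision, and separates cleanly from the anchoring of
the value scale. Choices a maintainer should know about:

* **Anchor.** Relative values are defined only up to an additive constant;
  we anchor `V(3) = 0`. Only value *differences* enter TD errors, so
  nothing observable depends on this.
* **Horizon.** The grid must cover the timing distribution's mass; the
  default horizon is the `1 − 10^{-10}` gamma quantile (indirect mode) or
  the `0.999` quantile of the latency prior stretched by the timing noise
  (direct mode). The backward recursion sets `w = 0` at the horizon
  ("transition imminent"), so values within the plotted range are
  insensitive to it; tests check flatness and orderings away from the
  boundary.
* **Cost truncation.** `E[a/T]` diverges for gamma timing with shape ≤ 1,
  so the cost is evaluated as `a / max(T, cost_floor)` with
  `cost_floor = dt` by default. The truncation level is a real modelling
  parameter: with the default utilities the cycle's expected net utility
  sits very close to zero, so the *sign* of `ρ` (and with it the sign of
  the small cue and efference transients) can depend on the floor. The
  press-time utility surprise, which dominates the simulated signals, does
  not.
* **Where utility is "paid".** The trial utility `u(T) = r + a/T + b` is
  delivered as a lump at press completion, and the preparedness state
  carries a single, choice-independent value using the policy-expected
  utility. The residual surprise `u(T) − E[u]` therefore appears as a
  reward-time prediction error. This keeps the error signal event-locked
  and gives the press-proximal transients their strong growth with latency
  in the direct regime.
* **Direct signal delay.** The direct regime needs a delay `ε` between cue
  and the critic's receipt of the chosen latency; no value is printed
  anywhere, so `ε = 0.1` s is a package default, config-exposed.
* **Direct-signal ordering depends on `ρ > 0`.** The direct-signal
  transient equals `−ρ (E[T|τ] − E[T])`: slower choices are devalued in
  proportion to the opportunity cost of time. At the default utilities `ρ`
  is within numerical distance of zero, so the property test for this
  ordering runs at `r = 2`, where the cycle is clearly profitable and the
  premise of the prediction holds.
* **Timing noise.** The conditional timing distribution `N(τ, (kτ)²)` is
  truncated to `T > 0` and renormalised (a Gaussian wait can otherwise be
  negative); `k = 0.1`.
* **Latency classes and peak windows.** Trials split at a press time of
  5 s. Per-trial peak concentrations are measured in a cue window
  `[0, 5 + ξ)` and a press window `press + ξ ± 2.5` s: the kernel delays
  every response by about `ξ`, so windows anchored on events are shifted
  by the same lag. With these windows, short-latency trials measure the
  same ramp twice (no difference by construction of the task), while
  long-latency trials separate the modest cue response from the large
  press-proximal response.

## Account 2: gain control of a drift-diffusion decision

Evidence accumulates as `dx = g(t)[A dt + c √dt ε]` to a symmetric
threshold `±z`; the gain `g(t)` *is* the modelled dopamine concentration.

* **Tonic fluctuations** follow a discrete-time Ornstein-Uhlenbeck (AR(1))
  update, `g ← g + κ(θ − g) + σ ε`, once per 0.01 s step, with
  `θ = 1, κ = 0.01, σ = 0.1`. `κ` and `σ` are *per-step* quantities: the
  stationary variance is `σ²/(2κ − κ²) ≈ 0.5` and the correlation time
  about one second. We adopted the per-step reading (rather than scaling
  the update by `dt`) because it is the one under which the stated
  parameters produce gain fluctuations that matter on trial timescales —
  with `dt`-scaled updates the same numbers give a 100 s correlation time
  and essentially deterministic single-trial gains, abolishing both the
  reported strength of the latency correlation and any measurable
  stationarity on practical path lengths.
* **Phasic events** add `h · f(t − t_event)` to the gain, `h ~ N(4, 1)`.
  The default onset is `t_event = 1` s into the trial, the convention used
  when the phasic transient is illustrated; it is config-exposed.
* **Positivity.** The gain is floored at `10^{-6}` (a concentration cannot
  be negative, and a negative gain would invert the meaning of evidence);
  floor hits are counted and logged.
* **First-passage detection.** Sampling the path only at grid points
  misses intra-step excursions and biases latencies upward by roughly
  `0.5826 c √dt` in threshold units. Crossings are therefore detected with
  a per-step Brownian-bridge test in addition to the sampled-point test,
  and sampled-point crossings are refined by linear interpolation. With
  this, ensemble mean decision times match the closed-form constant-gain
  oracle within Monte-Carlo error at `dt = 0.01` s.
* **Censoring.** Trials are cut at 60 s; non-crossing trials are excluded
  from aligned averages and correlations with their count reported. The
  correlation is Pearson's, on crossing trials only.

## Coupling to motivational state

Reinterpreting tonic dopamine as the average utility rate `ρ` links it to
vigour: the softmax latency policy `P(τ) ∝ exp(β Q(1,τ))` with
`Q(1,τ) = a/τ + b + r − ρτ + V(2)` both shapes and is shaped by `ρ`. The
fixed point is solved by damped alternation (damping 0.5, tolerance
`10^{-10}`, `ρ` initialised at 0; tests confirm the answer is independent
of the initialisation). The latency grid is 200 log-spaced points on
[0.1, 20] s, covering the latencies a hyperbolic cost of `a = −0.05` with
unit-order rewards can produce. In the sweep over reward utility the "cue
TD error" is defined as the policy-expected net utility of the announced
trial — the value step from an unvalued between-trials baseline. (The
within-cycle value step `ρ τ_I` is the alternative definition; with the
sweep's `τ_I = 0` it is identically zero, which is why the episodic
definition is the meaningful one here.) All three reported relations —
`ρ` rising with `r`, the cue error rising with `ρ`, latency falling as the
cue error rises — are properties of the solved fixed points, checked in
the tests.

## Account 3: discounted vigour and the quasi-tonic signal

With per-second discount `γ`, the value of acting at latency `τ` is
`Q(τ) = a/τ + γ^τ v_next`. The per-second convention (rather than
per-step) is forced by the seconds-scale trajectories the model is applied
to; `γ = 0.98` per second is the default.

* **Optimal latency.** `Q` always increases again toward 0 as `τ → ∞`
  (waiting forever costs nothing), so the meaningful optimum is the first
  interior stationary maximum, found by a coarse log-grid bracket refined
  with golden-section search to `10^{-4}` s, ties broken toward the
  smaller latency. It exists exactly when `a ≥ a_min(γ) = 4/(e² ln γ)`;
  the brute-force oracle in the tests checks both the location and the
  existence boundary.
* **Terminating vs continuing.** The terminating chain folds the reward
  into `v_next = 1`. The continuing chain prices the next opportunity:
  `V = max_τ [a/τ + γ^τ (r + γ^{τ_I} V)]`, solved by damped fixed-point
  iteration to a Bellman residual below `10^{-10}`.
* **Quasi-tonic signal.** Along a trajectory with goal proximity `p(t)`
  measured in seconds of remaining travel, `V(t) = γ^{p(t)} r`, with the
  goal reward encoded as the goal-state value (no separate reward stream).
  The quasi-tonic signal is `(1 − γ) V(s_{t+1})` with the successor state
  taken one second ahead — the bookkeeping step at which `γ` is the
  per-step discount — and the undiscounted error is
  `δ_A(t) = V(s_{t+1}) − V(s_t)`. On goal-directed (unit-speed) segments
  `δ_A` equals the quasi-tonic signal sample by sample, which is the
  discrete form of the statement that the undiscounted error averages to
  the quasi-tonic target; the identity test uses pure approach
  trajectories, where it holds to machine precision. Pauses and retreats
  break the pointwise identity — deliberately: they are the cases where
  the signal visibly tracks proximity instead.
* **Concentration trace.** The quasi-tonic signal is smooth and sustained,
  so its convolution with the response kernel is normalised by the kernel
  area: a sustained signal keeps its own scale and `da` is a smoothed,
  delayed copy (peak no higher, no earlier).
* **Continuity.** On a three-state deterministic reward cycle the exact
  discounted values satisfy `(1 − γ) V(s) → ρ` as `γ → 1`; the test
  tracks the gap shrinking over `γ ∈ {0.9, 0.99, 0.999}`.

## The trajectory generator

`synth_trajectory()` emulates the structure of maze runs: a monotone type
approaching the goal at exactly one second of proximity per second (time
standing in for distance), and a pause-and-retreat type inserting a
stationary segment and a retreat before resuming. These are idealisations:
real runs have variable speed, turns that slow the animal, and measurement
noise; none of that is modelled. Passing tests therefore establish the
*model's* properties (peak invariance, reward scaling, proximity
tracking), not that real recordings arise this way.

## Problem sizes and determinism

Simulation-based checks use 1000-trial ensembles for the decision-process
and lever-press sessions (the size at which the aligned averages and the
latency correlation were reported), `10^4` trials for the closed-form
decision-time oracle, and `10^5`-step paths for OU stationarity. All
stochastic entry points take explicit seeds and are bitwise reproducible
under them; experiment products embed a parameter hash in their manifest.

## Known limitations

* The actor never learns: policies and values are solved, not acquired by
  TD updates; only converged behaviour is simulated.
* Occupancy times `τ_post` and `τ_I` are deterministic; uncertainty in
  them is not modelled.
* The latency prior is a single gamma; empirical press-time distributions
  are heavier-tailed.
* The response kernel is linear and spatially homogeneous; reuptake
  kinetics, release heterogeneity and nonlinear DRF structure are out of
  scope.
* Threshold modulation as an alternative locus of dopaminergic gain
  control, and network-level basal-ganglia implementations, are not
  implemented.
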