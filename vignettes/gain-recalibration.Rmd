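---
title: "Bump attractors, distributed integration gain, and how landmarks recalibrate it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bump attractors, distributed integration gain, and how landmarks recalibrate it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringrecal)
```

This vignette is the package's account of the science it implements: the
models, the assumptions behind them, the parameters that matter, the
numerical choices, and what the simulations do and do not show.

## 1. The full network model

The central ring obeys leaky firing-rate dynamics with rectified-linear
activation,

$$\tau_c \, \partial_t r_c(t,\psi) = -r_c + \sigma\!\big(W_{cc}
\circledast r_c + I_{\mathrm{ext}}\big),$$

where $\psi \in [0, 2\pi)$ is the neuron's angle, $W_{cc}$ is an
even-symmetric local-excitation/global-inhibition kernel
(wrapped-Gaussian lobe of width `excit_width = 0.55` rad on a constant
inhibitory floor), and $\circledast$ is circular convolution. This
connectivity makes a single activity bump the stable pattern; its
location on the ring is free and encodes track position. Clockwise and
counter-clockwise rotation rings conjoin the bump position (topographic
central input, weight `g_c_rot`) with running speed (velocity neurons
with push–pull tuning $u_{cw,0} - \alpha_{cw} v$ and
$u_{ccw,0} + \alpha_{ccw} v$, per-neuron weights $W_{v\text{-}cw}(\psi)$,
$W_{v\text{-}ccw}(\psi)$), and project back to the central ring
one-to-one with opposite angular offsets $\pm b$. Motion imbalances the
two rotation rings, and the offset push–pull shifts the bump: path
integration.

Assumptions worth stating explicitly:

* **Rotation rings are fast.** They follow their inputs instantaneously
  (quasi-steady state), which is the discrete counterpart of the ansatz
  that their activity is an algebraic function of the central bump and
  the velocity.
* **Balanced inputs at rest.** Global inhibition on each rotation ring is
  set to cancel its own baseline velocity drive plus a margin
  (`i_margin`), so at rest the rings fire only under the central bump's
  footprint and the bump does not drift, whatever the spatial profile of
  the velocity weights. The margin also keeps velocity modulation from
  igniting ring-wide background activity; it must exceed the largest
  modulation $\max(W_v)\,\alpha\,|v|$ used in an experiment.
* **Amplitude stabilization.** A rectified-linear attractor is positively
  homogeneous, so no arrangement of excitatory loops alone yields a
  finite stable amplitude. The model therefore feeds back a spatially
  uniform inhibition proportional to total rotation-ring activity
  (`gamma_inh`) plus a small tonic drive (`I_tonic`). Uniform terms exert
  no push and do not enter the gain expression; they only pin the
  amplitude. For the *isolated* central ring the kernel is normalized
  (by power iteration on the rectified convolution operator) so the bump
  is an exact equilibrium ray with neutral amplitude, which is what the
  fixed-point and bump-emergence demonstrations use.

Defaults: `n = 256` neurons per ring, `tau_c = 10` ms, explicit Euler
with `dt = tau_c/20`; the integrator rejects `dt > tau_c/10`. The offset
is `b_bins = 5` grid bins. With `n = 256` the discretization error in
the measured gain is below 1%; coarser rings (the plastic model uses
`n = 96`) trade a little accuracy for speed.

## 2. The distributed integration gain

Reducing the network to one dimension (projecting the dynamics onto the
bump's translation mode) gives $d\theta/dt = k(\theta)\,v$ with

$$k(\theta) = \frac{-b}{\tau_c\,\|\partial_\psi r_c^*\|^2} \int_0^{2\pi}
\partial^2_\psi r_c^*(\psi - \theta) \sum_{i \in \{cw,\,ccw\}} \alpha_i\,
W_{i\text{-}c}(\psi)\, W_{v\text{-}i}(\psi)\,
\mathrm{sign}\, r_i^*(\psi, \theta, 0)\, d\psi,$$

implemented in `compute_pi_gain_profile()` with central differences on
the ring grid, bin-width-weighted sums for the integrals, the squared L2
norm of the bump gradient in the denominator, and
$\mathrm{sign}\,r_i^*$ as the 0/1 indicator of rotation-ring activity at
rest. Because the velocity weights may vary over the ring, the gain is a
*distributed* quantity; uniform weights give a constant $k$, a
$\pm 40\%$ sinusoidal modulation gives a gain profile spanning roughly
0.6–1.4.

Two validation subtleties, both handled by `measure_gain_profile()`:

* **Transport lag.** A moving bump trails its quasi-static speed because
  the network's non-translation modes relax over a finite time; a
  one-directional profile estimate is therefore shifted along the travel
  direction. The lag is odd in the probe velocity, so probing both
  directions and averaging at matched $\theta$ cancels it to first
  order.
* **Time weighting.** A displacement-per-time gain estimate
  (`estimate_pi_gain()`) weights each location by the time spent there,
  i.e. it measures a harmonic-type mean, biased toward low-gain regions
  when the profile is strongly inhomogeneous. When the arithmetic
  spatial average $k_0$ is wanted, average the *local* gains uniformly
  over $\theta$. For near-homogeneous profiles (the plastic protocols)
  the two coincide.

`network_params()` calibrates the scale of the velocity weights so the
analytic $k_0$ equals `target_gain` (default 1); the weight *profile* is
untouched.

## 3. The reduced model and gain-update rules

`simulate_reduced()` integrates

$$\frac{d\theta^*}{dt} = k^* v, \qquad
\frac{d\theta}{dt} = \beta(\theta^* - \theta) + (k_0 +
k_{ac}(\theta))\,v, \qquad \frac{dk_0}{dt} = g_0(k_0, \tilde\theta, v),$$

with $\tilde\theta = \theta^* - \theta$ wrapped to $(-\pi, \pi]$, the
landmark term dropped while landmarks are off, and
$\beta(x) = 0.66 \sin x$ as the canonical smooth sign-preserving
feedback. The integrator is fixed-step RK4 (Euler available for parity
with the full network); angles are integrated on the real line and
wrapped on output, so the flow itself is never differentiated across a
seam. `error_dynamics_step()` integrates the same flow in error
coordinates ($\tilde\theta$, $\tilde k = k^* - k_0$); the two are
cross-checked to 1e-9 in the tests.

The update rules and their classification:

| rule | $g_0$ | necessary (complete) | sufficient slope |
|---|---|---|---|
| linear | $\mu \tilde\theta v$ | yes | yes ($\mu$) |
| velocity-biased | $\mu(\eta k_0 v^2 + \tilde\theta v)$ | no (zero at $\tilde\theta = -\eta k_0 v$) | yes ($\mu$) |
| cubic | $\mu (\tilde\theta v)^3$ | yes | no (slope 0) |
| sign-flipped | $-\mu \tilde\theta v$ | no | no |

`check_necessary_condition()` probes the sign identity on a grid
(default $\pm 0.5$ rad around the steady-state error, 21 points, the
grid excluding the steady state itself and $v = 0$);
`check_sufficient_condition()` estimates the slope by a central
difference (step 1e-4 rad, positivity tolerance 1e-8 per second) at the
rule's zero, found by root bracketing. The generalized necessary
condition is derived under constant velocity, so `check_gain_rule()`
evaluates it at the probe velocity and at the steady-state gain reached
in a reference simulation; the steady-state error itself is estimated as
the circular mean over the trailing 10% of that run.

A design note on the velocity-biased rule: its zero sits at
$\tilde\theta = -\eta k_0 v$, so under constant velocity the positional
error settles exactly there and the gain error stays nonzero — partial
recalibration, with the magnitude of the settled error proportional to
$\eta |v|$ (scaled by the recalibrated gain). The tests assert that
relationship as the rule's defining steady state.

## 4. The plastic network

The modified attractor removes the direct visual-to-central drive and
adds:

1. an **association ring** with weak hardwired central input
   (`g_ca = 0.1`) and a plastic visual weight matrix;
2. **offset inhibitory** association-to-rotation connections
   (`o_bins = 10`, i.e. ~0.65 rad, CCW offset onto the CCW ring and CW
   onto the CW ring), making each rotation ring's mean rate monotone in
   the positional error over roughly $\pm 0.45$ rad — the error-rate
   code;
3. **plastic velocity weights** updated by a covariance Hebbian rule:
   presynaptic deviation of the velocity neurons from baseline times
   postsynaptic deviation of the rotation rates from their
   aligned-at-rest baseline, with decay and clipping to
   `[0, w_max * initial]`.

Design choices that were genuinely open, and how they were resolved:

* **Divergent inhibition (`ar_spread = 0.5` rad).** With sharp,
  bump-shaped inhibition the spatial redistribution of rotation-ring
  activity under an error opposes the mean-rate change, and the net push
  moves the bump *away* from the landmarks. Spreading the inhibition
  makes it act as a graded level across the ring's footprint — the same
  geometry as the velocity input — and the push becomes corrective. The
  offset must also exceed the inflection point of the bump–inhibition
  correlation (hence ~0.65 rad rather than a few bins); smaller offsets
  put the wiring on the anti-corrective side of that correlation.
* **Homeostatic decay of the velocity weights.** The rotation rings are
  modulated by velocity as well as by error, so the raw Hebbian update
  carries a $v^2$ potentiation bias even under veridical landmarks. The
  decay rate is calibrated at construction so that the veridical
  condition (running at `v_ref = 0.3` rad/s with `k* = 1`) is
  stationary; recalibration is then driven by the deviation of the
  operating error from its veridical value. This is also why
  recalibration is imperfect: the error code saturates outside
  ~$\pm 0.45$ rad, and the protocols run at 0.3 rad/s so that all
  operating points for $k^* \in [0.7, 1.5]$ stay inside the monotone
  range.
* **Association training as a turnover equilibrium.** The
  visual-to-association band is learned by pairing the central bump with
  the veridical visual bump at positions swept repeatedly across the
  track (`train_association()`: 8 shuffled sweeps of 48 sites, 0.25 s
  each). Potentiation (covariance form, postsynaptic mean subtracted)
  balances weight decay, so the learned band is the steady state of the
  pairing statistics rather than a cumulative record — a single slow
  pass leaves early positions erased by decay, and a budgetted
  cumulative fill is biased toward whichever positions were paired last.
  Each association neuron's total visual weight is capped at the
  trained-band budget (synaptic scaling); saturated neurons stop
  potentiating.
* **Probing.** The gain is measured with landmark-extinction probes
  (landmarks off, plasticity frozen, constant probe speed over a full
  lap); probes covering less than a lap are flagged as biased. No error
  signal exists without landmarks, so freezing plasticity during probes
  is forced as well as convenient.

With these pieces, `run_recalibration_protocol()` reproduces the
experimental phenomenology: the measured gain moves in the direction of
$k^* - 1$, final gains are strictly increasing in $k^*$, and for
$k^* = 1.5$ the network settles well short of 1.5 — imperfect but
stable recalibration. `run_error_correction_protocol()` shows the same
wiring eliminating an abrupt positional error through differential
rotation-ring rates (a virtual velocity signal).

## 5. What the synthetic inputs do and do not emulate

Velocity profiles live on a unit-circumference circular track (position
maps 1:1 to angle; rad/s units). `pause_resume` reproduces the
structure of a track session — steady running with 30 s pauses at
minutes 5 and 20 of a 30-minute run, mean speed 1 rad/s (one lap per
~6 s) — and `smoothed_random` adds low-pass Ornstein–Uhlenbeck speed
fluctuations with occasional stops. These are fixtures with the right
gross statistics (pauses, smooth accelerations, strictly nonnegative
speed), not a behavioural model: no lap-to-lap stereotypy, no
deceleration before landmarks, no reward structure. Passing tests on
them shows the dynamics and the recalibration logic behave as derived;
it does not certify parameter values against real rodent kinematics.
All generators are deterministic given their seed.

## 6. Numerical choices and problem sizes

* Reduced-model runs use RK4 with `dt = 10` ms; the 30-minute reference
  session takes a few seconds and matches an adaptive-step solver
  (`deSolve::lsoda`) to ~1e-12.
* Full-network validation uses `n = 256` and `dt = 0.5` ms; gain-profile
  validation probes at 0.5–0.6 rad/s in both directions over a bit more
  than a lap each way.
* Plastic-network protocols use `n = 96`, `dt = 1` ms, 150 s of
  recalibration per visual gain, association training of ~96 s of
  simulated pairing. These sizes keep a complete recalibration sweep
  (five visual gains plus a 1.5 run) within a few minutes of CPU time
  while leaving the qualitative results unchanged at finer settings.
* Degenerate inputs: flat bump templates are rejected when computing the
  gain profile; all-zero rate vectors cannot be decoded (`no bump`
  error); velocities beyond the velocity neurons' linear range rectify
  a velocity neuron to zero and warn (or error, configurable).
* Bump emergence is declared when the circularly smoothed rate vector
  has exactly one local maximum above 20% of its peak and the
  peak-to-trough amplitude dominates the field; the 20% floor ignores
  sub-percent transient ripples that are not competing bumps.

## 7. Known limitations

* The error-rate code is monotone over ~$\pm 0.45$ rad; protocols that
  push the operating error beyond that range (fast running, extreme
  $k^*$) leave the recalibration direction undefined. The defaults keep
  all standard conditions inside the range.
* The homeostatic decay calibration is done at one reference speed;
  strongly time-varying speed profiles shift the veridical operating
  point and introduce a small gain drift.
* The displacement-based gain probe is exact only for near-homogeneous
  gain profiles (see section 2).
* Angles are discretized to whole bins when shifting templates
  (`2*pi/n` quantization, 0.065 rad at `n = 96`); sub-bin effects show
  up as small ripples in decoded trajectories, and are averaged out by
  the measurement windows used in the validation protocols.
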