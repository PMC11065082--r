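# ringrecal

Ring attractor networks with path-integration gain recalibration.

## The problem

Continuous bump attractor networks are the standard model for how neural
circuits hold and update representations of continuous variables — a rat's
position on a circular track, head direction, accumulated evidence. A ring
attractor maintains a persistent bump of activity whose location `theta`
encodes the variable; velocity inputs shift the bump (path integration),
and a landmark-driven visual input pulls it toward the true position
`theta_star` (error correction). The reduced dynamics of the bump location
are

```
d theta*/dt = k* v
d theta /dt = beta(theta* - theta) + k(theta) v
```

where `v` is the running speed, `k*` the experimentally imposed visual
gain (how fast landmarks move relative to the animal; `k* = 1` means
stationary landmarks), `beta` the landmark correction (same sign as its
argument near zero), and `k(theta)` the network's path-integration (PI)
gain — a *spatially distributed* quantity determined by the network's
synaptic weights, with spatial average `k0`.

Experiments show that prolonged landmark–self-motion conflict does more
than correct errors: it *recalibrates* `k0` toward `k*`. This package
implements, as tested simulation and analysis code:

* the full three-ring firing-rate network (central ring with
  local-excitation/global-inhibition recurrence, CW/CCW rotation rings,
  push–pull velocity neurons, bump-shaped visual drive), and the analytic
  expression for its distributed gain `k(theta)` from the converged bump
  shape and the velocity-pathway weights;
* the reduced bump-location model above, plus adaptive gain-update rules
  `d k0/dt = g0(k0, theta* - theta, v)` and numerical checkers for the
  *necessary* sign condition (`sign g0 = sign((theta_tilde -
  theta_tilde_inf) v)`) and the *sufficient* slope condition
  (`d g0 / d(theta_tilde v) > 0` at the rule's zero) for recalibration;
* a modified plastic ring attractor in which an association ring learns
  the landmark-to-position mapping by Hebbian plasticity, offset
  inhibitory connections make the rotation rings fire as a monotonic
  *rate code of the positional error*, and covariance-style Hebbian
  plasticity of the velocity-to-rotation weights recalibrates the gain —
  imperfectly but stably, and monotonically in `k*`;
* generators for synthetic velocity profiles and landmark protocols,
  trajectory I/O, and reproducible experiment drivers.

## Worked example

The canonical landmark-conflict session: gain starts at 1, landmarks move
with visual gain 1.5, the animal runs 30 minutes with two pauses, and the
simplest rule that satisfies the sufficient condition
(`g0 = mu * theta_tilde * v`) recalibrates the gain completely.

```r
library(ringrecal)

vp <- make_velocity_profile("pause_resume", duration = 1800, mean_v = 1)
traj <- simulate_reduced(
  reduced_state(theta = 0, theta_star = 0, k0 = 1),
  vp, k_star = 1.5, beta = beta_sinusoidal(0.66),
  rule = gain_rule_linear(0.02),
  duration = 1800, dt = 0.01)

summarize_trajectory(traj)[c("k0_final", "abs_k_tilde_final",
                             "theta_tilde_steady")]
#> $k0_final
#> [1] 1.5
#> $abs_k_tilde_final
#> [1] 3.507039e-11
#> $theta_tilde_steady
#> [1] -9.160596e-13
```

The gain error `k* - k0` decays from 0.5 to ~1e-11: complete
recalibration, with the positional error converging to zero alongside.
Classifying the canonical update rules:

```r
check_gain_rule(gain_rule_cubic(0.02))
#> <condition_report> rule: cubic
#>   necessary (complete, tt_inf = 0):      PASS
#>   necessary (generalized, tt_inf = 0.1173): fail
#>   sufficient slope: fail (slope = 2e-10 /s at zero 0.0000)
```

The cubic rule `mu * (theta_tilde * v)^3` has the right sign but zero
slope at the origin — necessary condition only, so convergence is not
guaranteed at useful rates. The full plastic network:

```r
p <- plastic_params()             # calibrated so the initial PI gain is 1
rr <- run_recalibration_protocol(p, k_star = 1.3, duration = 150)
c(rr$initial_gain, rr$final_gain)
#> [1] 1.000000 1.084863
```

The measured gain (landmark-extinction probes) moves toward `k*` but does
not reach it: imperfect recalibration, because the rotation rings' error
code is also modulated by velocity.

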