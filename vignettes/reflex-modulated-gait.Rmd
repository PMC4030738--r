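---
title: "Spindle feedback, reflex modulation and hemiparetic gait: the models behind reflexgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spindle feedback, reflex modulation and hemiparetic gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

reflexgait simulates how hyperexcitable muscle-spindle feedback — the
neural substrate of spasticity — and altered gait-phase reflex modulation
change joint kinematics during walking. This vignette explains the models,
the numerical machinery and the design choices, in enough detail that a
user can judge what a result does and does not show.

## The neural control model

Each modeled muscle group $m$ (soleus, gastrocnemius, vasti, rectus
femoris; bilaterally) is driven by

$$u_{tot,m} = u_{b,m} + u_{l,m} + u_{v,m}, \qquad
  y_m = \min(1, \max(0, u_{tot,m})),$$

where $u_{b,m}$ is the base excitation (central drive plus all unmodeled
pathways) and the two feedback excitations obey first-order filters

$$\tau_{l,m}\,\dot u_{l,m} = -u_{l,m} + k_m\,g_{l,m}\,\tilde l_m
  \quad (\tilde v_m > 0;\ \text{pure decay otherwise}),$$
$$\tau_{v,m}\,\dot u_{v,m} = -u_{v,m} + k_m\,g_{v,m}\,\max(0, \tilde v_m).$$

Both pathways are gated by lengthening: a shortening muscle produces no
stretch-related afference, and its feedback excitations relax to zero with
their own time constants. The modulation factor $k_m \in [0,1]$ is a
periodic function of gait-cycle position representing phase-dependent
pre-synaptic control of reflex gain.

Assumptions worth stating plainly: the spindle is reduced to two linear
filters on normalized fiber kinematics (no fusimotor drive, no intrafusal
dynamics); Golgi-tendon (force) and cutaneous feedback are absent; the
lower clamp of the saturation is a choice — the excitation law only defines
outputs for non-negative totals, and negative totals (possible when a
negative base excitation outweighs feedback) are clamped to zero because
physiological excitations cannot be negative.

Default parameters per group (`default_spindle_params()`): $\tau_l$ = 75 ms
(plantarflexors) / 50 ms (quadriceps), $\tau_v$ = 40 ms, $g_l$ = 0.1,
$g_v$ = 0.59 / 0.77 / 0.37 / 0.82. The "stroke" profile carries the
printed three-fold gains (note it is the *rounded* product: 3 × 0.77
prints as 2.30). `scale_gains()` applies arbitrary multipliers; both ×3
and ×6 are conventional hyperexcitability levels, and the worked examples
use ×3.

### Normalization convention

The source models never pin down the numeric normalization of
$\tilde l_m, \tilde v_m$. reflexgait defines, with a rigid tendon and no
pennation,

$$\tilde l = \frac{L_{MTU} - L_{slack}}{l_{opt}}, \qquad
  \tilde v = \frac{\dot L_{MTU}}{10\, l_{opt}/\text{s}}$$

(positive while lengthening). This places gait-cycle fiber lengths in the
0.6–1.2 range and velocities within a few tenths, the standard ranges of
Hill-model states, and makes the fiber state a deterministic function of
joint state — which the open-loop protocol requires.

## Identifying the base excitations

The reference condition must reproduce the reference motion *with* its
reference feedback active. reflexgait therefore first computes tracking
excitations $u_{CMC,m}$ for the reference trajectory (below), integrates
the feedback filters along the reference fiber states under reference
gains and modulation, and sets point-wise

$$u_b = u_{CMC} - u_l - u_v .$$

The decomposition is exact by construction; where feedback exceeds the
tracking excitation the base excitation goes negative, which is kept (so
the identity holds) and reported as a diagnostic. All hemiparetic
conditions reuse the same $u_b$ — only gains and modulation change — so
kinematic differences are attributable to the feedback manipulation alone.

## The tracking controller

A full computed-muscle-control stage is out of scope; `compute_tracking_excitations()`
is a per-sample inverse-dynamics static optimization. At each control-grid
sample of the reference cycle it computes the generalized forces the
reference accelerations require (with contact evaluated on the reference
state), and solves, per leg, a bounded ridge least-squares problem

$$\min_{0 \le u \le 1} \|A u - b\|^2 + \lambda \|u\|^2$$

($A$ maps excitations to joint torques through the Hill force at the
reference fiber state; $\lambda$ = 1e-3 makes the solution unique). The PD
gains of `tracking_config()` shape the target acceleration but vanish on
the reference itself. Three kinds of residual are recorded and replayed
with the excitations: pelvis forces (no muscle spans those coordinates),
joint-torque shortfalls (reported when above 5 N m), and — after the
excitation series is compensated for the activation filter lag by inverse
filtering — a *discrete residual-reduction pass*: the stored reserves are
recomputed so that the integrator's own step, taken from a reference state
with the replayed activations, lands exactly on the next reference
velocity. This is what lets a segmented open-loop replay track the
reference to ~0.02° RMS per interval; without it, activation-lag clipping
and interpolation error accumulate to degrees.

## Skeleton, muscles and contact

The skeleton is planar with 9 DOF: pelvis translation and pitch plus
bilateral hip, knee and ankle flexion. Segment masses, lengths, centers
and inertias follow standard anthropometric fractions scaled to the
subject (54.4 kg, 1.68 m by default). Mediolateral and transverse effects
are not modeled; the reported outcomes are sagittal only.

Eight muscle groups per leg actuate the joints through constant moment
arms (`default_muscles()`): the four feedback groups plus tibialis
anterior, hamstrings, iliopsoas and gluteals so that gait is drivable.
Parameters are adapted from standard gait-model tables; with constant
arms, the moment arm equals $-\partial L/\partial q$ exactly, which the
geometry tests exploit. The Hill model uses a Gaussian active
force–length curve (width 0.45), a hyperbolic force–velocity law (zero at
maximal shortening, 1.5 on the lengthening asymptote, continuous slope at
zero) and an exponential passive element engaging beyond optimal length
(capped at $\tilde l = 2$ to bound the exponential; the passive energy
function matches the capped curve so energy accounting stays exact).
Excitation-to-activation is first order with 10/40 ms time constants.

Foot–ground contact uses three spheres per foot (heel 30 mm, forefoot
2 × 15 mm; locations from the shipped table, carried in the calcaneus
frame) against the treadmill plane, with normal force

$$f_n = \sigma \pi r\, \delta \,\max(0,\ 1 + c\,\dot\delta),$$

$\sigma$ the tabulated stiffness (1.86 MPa/m) and $\delta$ the
penetration. The tabulated dissipation (1000 s/m) is read on a mm/s
penetration-rate scale, i.e. an effective 1.0 s per m/s: taken literally
in SI it would scale gait-level penetration rates (~0.05 m/s) into
fifty-fold force spikes, which is inconsistent with any plausible walking
ground reaction force; the chosen reading recovers the standard
Hunt–Crossley damping magnitude while the parameter table keeps the
printed number. Friction is tanh-regularized Coulomb with a
stiction/dynamic transition at a 1 mm/s reference slip speed plus a
viscous term, opposing slip relative to the belt (1 km/h by default).
Note the shipped static coefficient (0.101) is *below* the dynamic one
(0.2); the table is shipped verbatim and the friction magnitude is bounded
by the larger of the two. Sphere locations can be re-optimized against
the kinematic tracking error (`optimize_sphere_locations()`, Nelder–Mead
on box-clamped in-plane offsets, best-visited point returned so the
objective never increases); stiffness, dissipation and friction are
exposed but deliberately not fitted.

## Integration

The production integrator is fixed-step semi-implicit Euler at 0.5 ms —
chosen for bit-reproducibility over adaptive schemes — with one essential
refinement: all stiff velocity-dependent forces (contact damping and
friction slopes, muscle force–velocity damping, joint damping) enter a
linearized implicit velocity solve $(M + \Delta t\,D)\,\Delta\dot q =
\Delta t\,Q$. Contact damping alone has slopes of order $10^5$ N s/m,
far beyond the explicit stability limit at any practical step; the
implicit treatment is unconditionally stable for those terms and adds no
cost beyond the 9 × 9 solve the step already needs. The spindle and
activation filters use exact exponential updates with sample-and-hold
drives (unconditionally stable, exact for piecewise-constant inputs); the
spindle integrator additionally refuses steps above half the smallest
time constant. An explicit RK4 option exists for high-accuracy checks;
the passive-dynamics energy test conserves energy to ~1e-11 relative with
it, and to ~1% with the production scheme over 0.3 s.

## The segmented protocol

Open-loop forward simulation of a full cycle is dynamically unstable, so
the experiment uses twenty 5% intervals (~0.11 s). Each interval starts
1% early on the *reference kinematics* (positions, velocities,
activations), with spindle states carried over from the end of the
previous interval — they cannot be re-initialized instantaneously — and
the lead-in is discarded. The first interval (and any standalone
`run_interval()` call) starts from the periodic steady state of the
filters under that run's own gains and modulation. Differences are taken
against a *re-simulated* reference run of the same protocol, not the raw
reference data, isolating the feedback manipulation from protocol
artifacts; the null condition (×1 gains, unchanged modulation) is
bit-identical to the reference run, and the suite asserts exactly zero
difference. Per-phase means are classified into arrows at a configurable
threshold (1° single, 3° double — the directional table has no canonical
numeric rule, so the threshold is explicit everywhere).

Hemiparesis is unilateral, so a condition applies its gain multipliers
and modulation switch to one side (right by default); feedback itself is
modeled bilaterally.

## The synthetic reference gait

`generate_reference_gait()` produces the study conditions: a 2.2 s cycle
(slow treadmill walking at 1 km/h; cycle time is configurable), sagittal
joint angles as order-6 Fourier series through physiological template
knots (hip ≈ −8…25°, knee ≈ 5…60° peaking at ~75% of the cycle, ankle ≈
−18…10°), analytic derivatives, and a pelvis height derived so the lowest
contact sphere keeps a ~3 mm stance penetration — which makes the
kinematics *compatible with the contact model*, the synthetic analogue of
dynamic consistency. Excitation bursts and a double-bump per-leg vertical
GRF (impulse normalized to body weight × cycle time) complete the fixture.
What the generator does **not** emulate: measurement noise, marker
artifacts, inter-stride variability, EMG content, 3-D kinematics. Passing
tests on this fixture therefore demonstrate correctness of the machinery
and the qualitative causal chain (gain ↑ → lengthening-gated excitation ↑
→ phase-specific joint deviations), not subject-specific prediction.
Because the skeleton is reduced and its muscle parameters generic, only
directional, phase-resolved statements are claimed — magnitudes depend on
the fixture.

## Reflex processing

Modulation curves come from stimulus-locked recordings: peak-to-peak
amplitude in a configurable 25–50 ms post-stimulus window (a standard
lower-limb H-reflex latency; the recordings the pipeline is designed for
are clean synthetic traces, so no artifact rejection or wave
discrimination is included), averaging in 16 gait-cycle bins (bins with
fewer than ten trials are flagged), normalization by the *maximum* bin
mean — chosen over min–max so that absent suppression shows up as values
near 1 rather than being rescaled away — and periodic cubic-spline
interpolation with post-hoc clipping to [0, 1]. Degenerate input
(all-equal bins) yields the constant curve 1; empty bins are filled by
periodic linear interpolation before splining. The shipped quadriceps
presets are hand-specified shapes consistent with published descriptions
(tendon-jerk modulation), not digitized data, and are flagged as such.

## Problem sizes

The shipped configuration integrates 4 400 steps per protocol run
(20 intervals × 264 steps at 0.5 ms), solves 400 per-leg excitation
problems on a 0.25% control grid, and runs the full three-condition
experiment in about half a minute on one core; the test suite sizes its
simulations accordingly (e.g. two intervals and ~25 evaluations for the
sphere-location optimizer).

## Known limitations

* No force (Ib) or cutaneous feedback; no fusimotor control.
* Rigid tendon and constant moment arms: fiber-state trajectories differ
  quantitatively from musculoskeletal models with compliant tendons and
  posture-dependent arms; the phase structure (e.g. plantarflexor
  lengthening through stance and swing) is what carries over.
* Base excitations are frozen across conditions: compensatory strategies
  and altered central drive are outside the model by design.
* Sagittal plane only; single synthetic subject; no statistics across
  subjects.
* The contact parameter table is shipped verbatim although its printed
  units are unusual (see above) and its static/dynamic friction ordering
  is inverted relative to the usual convention.
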