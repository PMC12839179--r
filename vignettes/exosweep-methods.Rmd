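---
title: "Models and methods behind the exosweep pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the exosweep pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the pipeline computes

A passive ankle exoskeleton — a foot bracket and a posterior shank bracket
hinged at the ankle, joined by an exchangeable spring behind the joint —
stores elastic energy while the ankle dorsiflexes over the planted foot and
returns it in parallel with the calf muscles during push-off.  Two design
parameters govern how much it helps: the spring stiffness `k` and the
actuation timing `tau`, the percent of stance at which a delay device first
allows the spring to load.  `exosweep` simulates stance-phase walking of a
single subject under every combination of 25 stiffnesses (5.5–17.5 kN/m in
0.5 kN/m steps) and 10 timings (15–60 % of stance in 5 % steps), estimates
whole-leg muscle metabolic energy for each of 10 foot contacts, and maps
the percent change in energy relative to walking without the device.

The pipeline is deliberately desk-scale.  It replaces a full
musculoskeletal tool-chain with four transparent stages, each exposed as
package functions:

1. **Synthetic gait** (`generate_trial()`, `generate_cohort()`): sagittal
   joint angles and net moments for the stance phase, drawn from fixed
   normative waveform shapes with seeded trial-to-trial variability.
2. **Spring mechanics** (`spring_length()`, `resting_length_for_timing()`,
   `spring_force()`, `spring_ankle_torque()`): attachment-point
   trigonometry converts the ankle angle into spring length, the requested
   timing into a resting length, and tension into plantarflexion torque.
3. **Muscle redundancy** (`solve_trial()`): at every time step the required
   joint moments — net moments minus spring torque, plus bracket-mass
   adjustments — are distributed over an eight-muscle-per-leg Hill-type
   sagittal set by static optimization (minimum summed squared activation).
4. **Energetics** (`metabolic_rate()`, `trial_energy()`): an
   Umberger-style heat-plus-work model turns each muscle's activation and
   fiber state into metabolic power, integrated over the simulation window
   and normalized to body mass (J/kg).

The simulation window runs from 15 % of stance (foot flat) to the maximum
plantarflexion angle after toe-off, in one stance-fraction coordinate (0 =
heel strike, 1 = toe off, tail to ~1.12).  Only muscles ipsilateral to the
foot contact are summed, so the contralateral swing leg never contaminates
the energy comparison.

## The synthetic gait generator

The generator emulates what a single-subject overground collection
provides: 10 foot contacts (5 left, 5 right), sampled at the equivalent of
100 Hz, for a subject of 87.6 kg and 1.86 m.  Waveforms are sums of a few
Gaussian bumps and logistic ramps with landmarks at normative positions:
an ankle plantarflexion dip after heel strike, knee flexion waves in
loading response and swing, hip flexion-to-extension progression, an
early-stance knee extension moment, and a single-peaked ankle
plantarflexion moment (peak 1.45 N·m/kg at 72 % of stance over a 0.20
N·m/kg mid-stance shoulder).  Net moments scale linearly with body mass
and walking speed; walking speed (1.25 m/s) and stance duration (0.65 s)
are package defaults, exposed in the configuration, because the study
conditions they emulate do not pin them down.

One feature is deliberately stylized rather than normative: the
dorsiflexion progression is concentrated into a brisk second-rocker rise
just after foot flat (logistic ramp centered at 17.5 % of stance, width
0.012 in stance fraction), after which dorsiflexion holds a gently
receding plateau (about 20 % decline from 62 % of stance) until push-off.
This front-loads the ankle excursion available to a stance-phase spring
and is the kinematic mechanism by which actuation timing discriminates in
this model: a spring engaged at 15 % of stance harvests almost the whole
excursion, while engagements at or after 25 % find most of it already
spent and store almost nothing — the behaviour reported for the physical
device class this pipeline studies, where later actuation leaves both less
stretch and less time for energy loading.  In real subjects the same
competition between early engagement and excursion already spent is spread
over a broader window; concentrating it sharpens the timing contrast at
the 5 %-of-stance grid resolution without changing its direction.  A
consequence worth knowing: at timings of roughly 40 % and later the spring
never engages at all on the default subject, so those grid cells reproduce
the worn-but-unactuated condition exactly.

Trial-to-trial variability is a per-channel multiplicative amplitude
factor `~ Normal(1, noise_sd)` and phase shift `~ Normal(0, noise_sd *
stance_duration / 10)`.  The default `noise_sd = 0.005` produces
per-contact energy standard deviations of roughly 0.15 % of the mean —
tight, as befits smoothed, filtered sagittal kinematics of one healthy
adult at fixed speed, and small enough that the unpaired one-way ANOVA
across four conditions at n = 10 retains power for the ~1 % condition
contrasts the pipeline produces.  The generator does not emulate marker
noise, force-plate artefacts, fatigue drift, kinematic adaptation to the
device, or between-day variability; passing tests therefore demonstrate
internal consistency of the model chain, not fidelity to any individual's
gait.

## Spring, timing and added mass

The bracket hinge is constrained to the ankle angle, so the straight-line
spring length follows the law of cosines on the two attachment arms
(defaults: shank arm 0.30 m, foot arm 0.15 m, included angle 1.75 rad at
neutral, placing the spring posterior to the hinge with a moment arm of
roughly 0.12 m throughout stance; the source device is described only
qualitatively, so these are declared package constants).  The actuation
timing is realized exactly as in the physical device's computational
abstraction: the resting length `L0` is the spring length at the first
sample at or past `tau`, and the spring force is zero before that sample
(the delay device physically blocks loading) and `k·(L − L0)` when taut
afterwards — a cable cannot push, so ties at `L0` give zero force.

Wearing the unactuated device must cost energy (the bracket-mass
penalty).  The added-mass model is quasi-static and gravitational: the
ankle support moment carries the weight of both brackets through the
forefoot lever (0.18 m), the knee carries the shank bracket on a short
lever (0.06 m), each scaled by the cosine of the adjacent joint angle.
Inertial reaction terms were evaluated during design and rejected: in a
window-limited inverse-dynamics model they are sign-indefinite and can
spuriously assist push-off.  Bracket masses default to 1.2 kg (foot side,
including spring and delay wheel) and 0.8 kg (shank), chosen so the
worn-unactuated penalty lands near +1 % of baseline energy, the order
reported for passive ankle devices of this construction.

## Static optimization

At each sample the muscles must balance the sagittal ankle, knee and hip
moments.  With a rigid tendon (fiber length fixed by the joint angles),
muscle force is affine in activation, and the classical static
optimization problem

&nbsp;&nbsp;minimize Σ aᵢ² + w·Σ rⱼ²  subject to moment balance, 0 ≤ aᵢ ≤ 1

is a strictly convex box-constrained quadratic program; `r` are reserve
moments at each joint (weight `w = 1e3`) that guarantee feasibility on
extreme settings and flag any step whose reserve exceeds 1 N·m rather than
crashing the sweep.  The program is solved exactly by a primal active-set
method (equality solve on the free set, ratio-test clamping, worst-
multiplier release), which is finite for strictly convex objectives; tests
verify Karush-Kuhn-Tucker residuals below 1e-6 and agreement with a dense
grid-search oracle on well-conditioned two-muscle instances.  Activation
dynamics and tendon elasticity are omitted by design — the pipeline
replaces a tracking controller with per-step optimization on prescribed
kinematics, so controller transients are out of scope.

The muscle set is a literature-anchored sagittal eight per leg (soleus,
both gastrocnemii, tibialis anterior, lumped vasti, rectus femoris, lumped
hamstrings, gluteus maximus), shipped as package data with moment arms as
linear polynomials of joint angle.  Maximal isometric forces scale with
body mass, optimal fiber and tendon-slack lengths with height; muscle mass
derives from `f_max` and `l_opt` through a specific tension of 25 N/cm²
and a density of 1059.7 kg/m³.

## Energetics

Per-muscle metabolic power follows the Umberger model family: an
activation-plus-maintenance heat rate `(25 + 128·ft)·a^0.6` W per kg of
muscle (ft = fast-twitch fraction), shortening heat with coefficients
`100/v̄max,ST` and `153/v̄max,FT` scaled by `a²`, lengthening heat at 0.3
of the slow-fiber shortening coefficient scaled by `a`, an aerobic scale
of 1.5 on the heat terms, above-optimal-length scaling toward the
force–length curve, plus the positive mechanical work rate of the
contractile element.  Three variant choices are fixed and documented in
`umberger_constants()`: eccentric work is not credited against heat, the
summed rate is clamped at zero, and the basal rate is excluded.  Because
the sweep differences energies against a baseline computed with the same
model, these choices cancel to first order; absolute J/kg values should be
read as model-relative, not as calorimetry predictions.  Energy is the
trapezoidal integral of power over the simulation window.

## The sweep and its statistics

`run_sweep()` evaluates all 250 settings on each contact (2,500
simulations), deriving `L0` from each contact's own kinematics, plus two
reference conditions per contact: baseline (no device, no mass) and
worn-but-never-actuated.  The percent change `100·(E_setting −
E_baseline)/E_baseline` is computed per contact — the baseline pairing
removes most trial noise — and averaged per cell.  `find_minima()` reports
the global minimum (ties broken toward lower stiffness, then earlier
timing) and strict 4-neighbor local minima; `quadratic_fit()` regresses
the mean percent change on `(1, k, k²)` over one timing slice by ordinary
least squares.  On the default subject the global minimum sits at (5.5
kN/m, 15 % of stance), the 15 %-timing slice is quadratic in stiffness
with R² above 0.99, every 17.5 kN/m cell costs energy, and cells at
timings of 25 % and later collapse onto the bracket-mass penalty,
reproducing the stiffness-insensitivity of late timings.  One known
divergence from the physical-device literature: because late engagements
here store essentially nothing, no secondary local minimum appears at
mid-grid stiffness and mid-stance timing; the second optimal setting used
in the condition comparison (12 kN/m at 25 %) therefore coincides with the
worn-unactuated condition on the default subject.

Condition comparison mirrors a standard gait-lab analysis: Shapiro–Wilk
normality checks, one-way ANOVA over BL / EXO-NA / EXO-S1 / EXO-S2, and
Tukey honestly-significant-difference post hoc tests at α = 0.05, all
delegated to the corresponding base-R routines (`shapiro.test`,
`oneway.test`, `TukeyHSD`) with algebraic oracles in the test suite.  The
10 contacts of one subject are treated as replicates, as is conventional
for single-subject device studies; the pseudo-replication caveat applies
here as it does there.

## Numerical choices

* Engagement uses strict inequality (`length > L0`); grid-coincident ties
  produce zero force.
* The settings grid is built by integer index so endpoints (5,500; 17,500;
  15 %; 60 %) are exactly representable; a step that does not divide the
  range within 1e-9 is an error.
* Moment-balance residuals are absorbed by reserves; activation bounds are
  enforced exactly (no clipping tolerance).
* Fiber velocities come from central differences on the sampled length
  series; the default 100 samples per trial keep the trapezoidal energy
  integral within 1e-4 of a 100-fold refined one.
* All randomness descends from one configured seed through named
  substreams (one per trial), so cohort generation, the 2,500-simulation
  sweep and the statistics are bit-reproducible end to end.
* Problem sizes used throughout (10 contacts × 100 samples × 8 muscles ×
  250 settings) run in about two minutes; they are the defaults of the
  emulated study design, not tuning knobs.

## Limitations

The pipeline inherits the limits of its ingredients: prescribed kinematics
(no adaptation to assistance), rigid tendons (no series elasticity, which
matters for real plantarflexor energetics), a planar eight-muscle leg, a
quasi-static mass penalty, and a stylized dorsiflexion time course chosen
to concentrate the timing mechanism.  It is a tool for studying how the
stiffness-timing landscape behaves under a transparent model chain — and
for testing that landscape's structural features — not a subject-specific
predictor of metabolic cost.
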