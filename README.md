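# exosweep

Parametric optimization of a passive ankle exoskeleton's spring stiffness
and actuation timing, as a self-contained R simulation pipeline.

## The problem

A passive ankle exoskeleton — a foot bracket and a posterior shank bracket
hinged at the ankle, with an exchangeable spring strung behind the joint —
stores elastic energy while the shank dorsiflexes over the planted foot and
releases it in parallel with the calf muscles at push-off. Whether it
actually lowers the metabolic cost of walking depends on two design
parameters: the spring stiffness *k* and the actuation timing *τ*, the
percent of the stance phase at which a delay device first lets the spring
load. Finding good settings experimentally is slow and hard on exactly the
clinical populations that stand to benefit, which motivates sweeping the
design space in simulation first.

`exosweep` runs that sweep at desk scale for a single simulated subject:

* **synthetic stance-phase gait trials** — sagittal joint angles and net
  moments for 10 foot contacts (5 left, 5 right) with seeded trial-to-trial
  variability, exchanged as OpenSim-style `.sto`/`.mot` tables or CSV;
* **spring mechanics** — the spring length follows from attachment-point
  trigonometry (law of cosines on the two bracket arms), the requested
  timing τ becomes a resting length *L0*, and the tension-only force
  `k·(L − L0)₊` acts through the geometric moment arm as a plantarflexion
  torque;
* **muscle redundancy** — at each time step the required joint moments
  (net moments − spring torque + bracket-mass adjustments) are distributed
  over an 8-muscle-per-leg Hill-type set by static optimization,
  `min Σa² + w·Σr²` s.t. moment balance and `0 ≤ a ≤ 1`, solved exactly by
  a primal active-set QP method;
* **energetics** — an Umberger-style model (activation/maintenance heat,
  shortening/lengthening heat, positive mechanical work) integrated over
  the window from 15 % of stance to maximum plantarflexion after toe-off,
  summed over the ipsilateral muscles and normalized to J/kg;
* **the sweep** — 25 stiffnesses (5.5–17.5 kN/m) × 10 timings (15–60 % of
  stance) × 10 contacts = 2,500 simulations, reported as percent energy
  change Δ% versus walking without the device, with minima detection, an
  OLS quadratic fit of Δ% versus stiffness, and ANOVA + Tukey comparison of
  the baseline (BL), worn-unactuated (EXO-NA) and two chosen settings
  (EXO-S1, EXO-S2).

See `vignette("exosweep-methods")` for the models, their assumptions, and
every default's rationale.

## Worked example

```r
library(exosweep)

cohort <- generate_cohort()        # 10 contacts, 87.6 kg / 1.86 m subject
res    <- run_sweep(cohort, build_grid())   # ~2 min on one core
res
#> <sweep_result> 250 settings x 10 contacts = 2500 simulations
#>   baseline 1.652 +/- 0.002 J/kg; no actuation 1.674 +/- 0.002 J/kg
#>   global minimum: -0.98% at k = 5500 N/m, tau = 15% of stance

quadratic_fit(res, tau = 15)$r_squared
#> [1] 0.9992308
```

The map behaves the way a passive ankle spring should: the only energy
reductions occur at the earliest actuation timing, where a soft spring
(5.5 kN/m) saves about 1 % of baseline energy; stiffening the spring at
that timing turns assistance into antagonist co-contraction (Δ% grows to
+4.7 % at 17.5 kN/m, quadratically in *k* with R² > 0.99); and at timings
of 25 % and later the dorsiflexion excursion is already spent, so every
stiffness collapses onto the +1.3 % bracket-mass penalty.

The condition comparison (written by `cmd_report()`, here from the default
end-to-end run `cmd_all()`):

```
Energy expenditure by condition (mean +/- sd, J/kg):
  BL      n=10  1.6520 +/- 0.0023
  EXO-NA  n=10  1.6736 +/- 0.0024
  EXO-S1  n=10  1.6358 +/- 0.0020
  EXO-S2  n=10  1.6736 +/- 0.0024
One-way ANOVA: F(3, 36) = 653.089, p = 1.99e-31
Tukey HSD:
  EXO-NA - BL     diff = +0.0216  q =  30.04  p = 0  *
  EXO-S1 - BL     diff = -0.0162  q =  22.52  p = 0  *
  ...
```

Wearing the unactuated device costs energy (EXO-NA > BL), the best setting
recovers more than that penalty (EXO-S1 < BL), and both contrasts are
significant at α = 0.05. Absolute J/kg values are model-relative (basal
rate excluded, desk-scale muscle set); the signs, orderings and the shape
of the stiffness–timing map are the scientific output.

A shell entry point wraps the same functions:

```sh
inst/exec/exosweep all --outdir out --seed 1
inst/exec/exosweep generate|sweep|fit|report --config my.yaml
```

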