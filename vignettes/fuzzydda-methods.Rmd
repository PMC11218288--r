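---
title: "Methods: fuzzy difficulty mapping and closed-loop adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy difficulty mapping and closed-loop adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydda)
```

## What the engine models

Adaptive serious games for upper-limb rehabilitation face a translation
problem: clinical motor-function assessments are ordinal and qualitative
(manual muscle testing grades, staged recovery scales), while a game
needs continuous, tunable parameters (target size, speed, spawn volume).
`fuzzydda` implements the computational core of a three-layer design for
a target-shooting game aimed at mild-to-moderate post-stroke patients
(Brunnstrom stages IV–V): a *clinical* layer (therapist evaluations), a
*function* layer (parameter mapping and dynamic difficulty adjustment),
and an *engagement* layer (rewards, music pacing). Rendering, motion
capture and audio are out of scope — the engine represents them as
logged events only.

## Clinical intake

A `clinical_evaluation()` carries MMT grades per assessed muscle group,
active ROM per joint axis, the Brunnstrom stage and an optional pain
score. Three axes drive the game: shoulder horizontal
adduction/abduction ("azimuth"), shoulder flexion ("elevation") and
elbow flexion, each clinically bounded at 0–90°.

Two fixed conventions close gaps the clinical description leaves open:

* **Pooled strength.** The per-muscle-group grades are pooled into one
  continuous requirement by the arithmetic mean — the only rule
  consistent with the worked example in which grades 3, 3, 4 yield
  3.33. A single pooled value (rather than per-group requirements) is
  used because the strength axis of the parameter model is
  one-dimensional.
* **Elbow reach.** Elbow flexion is translated to a reach fraction by
  `reach(θ) = 1 − θ/180`: full extension (0°) reaches 1.0 of arm
  length, the clinical 90° flexion reaches 0.5. It is monotone, bounded
  and trivially invertible; no richer kinematic model is warranted by
  the inputs available.

The spawn region is the box `[0, azimuth requirement] × [0, elevation
requirement] × [reach(elbow requirement), 1]`, with an optional safety
margin that shrinks only the demanding (upper angular) ends.

## Initial difficulty: the strength partition

The continuous strength requirement is fuzzified over a Ruspini
partition with sets III, IV and V — unit-spaced triangles peaking at
grades 3, 4 and 5, with trapezoidal shoulders on the extreme sets so
that degrees sum to one over the whole `[0, 5]` support. The worked
example is reproduced exactly: a requirement of 3.33 belongs to III at
0.67 and IV at 0.33. The membership *shapes* are an engine decision
(only that single worked point constrains them); unit-spaced triangles
are the simplest family that honours it.

```{r}
fuzzify(aggregate_strength_requirement(c(3, 3, 4)), strength_partition())
```

Each set carries a nominal (diameter, speed) pair — defaults 0.30/0.20/
0.12 m and 0.30/0.50/0.75 m/s for III/IV/V, strictly monotone so a
stronger patient always gets smaller, faster targets. The design value
is the membership-weighted average (`weighted_defuzzify()`), e.g.
`0.67·0.30 + 0.33·0.20 ≈ 0.267` m. The nominal pairs are configuration
with documented defaults; the published description fixes the structure
but not the numbers.

## Dynamic difficulty adjustment

The controller is two-stage by design:

1. **Crisp comfort-band gate.** A per-round hit rate within
   `[0.50, 0.70]` — the Yerkes–Dodson-motivated band — produces exactly
   zero adjustment. The printed thresholds are hard constants, which
   makes them exactly testable (bisection over the implemented
   controller recovers 50% and 70% to numerical precision).
2. **Fuzzy magnitude module.** Outside the band, a Mamdani module
   decides *which* requirement moves and by how much. Its input is the
   beyond-range miss share: the fraction of misses recorded beyond 70%
   of the required range. Misses far out indicate the range requirement
   is the obstacle (rule: range gets the large negative term NL,
   strength the small NS); misses within comfortable range indicate the
   strength-linked parameters are the obstacle (the mirrored rule). The
   defuzzified amplitudes are scaled by the hit-rate deficit
   `(0.50 − h)/0.50`, so a marginal shortfall nudges and a collapse
   moves a full step. Above the band both requirements grow with
   amplitude `(h − 0.70)/0.30`, split evenly — at high hit rates there
   are too few misses to attribute the surplus to either axis.

Output terms live on `[−1, 1]` (five-term partition NL/NS/Z/PS/PL) and
are interpreted as signed fractions of a maximum step: 10° of range and
0.5 grade units of strength per adjustment by default, clamped to
`[10, 90]`° and `[0, 5]`. A round with no misses has a beyond-range
share of 0 by convention; the gate, not that value, decides at high hit
rates.

```{r, fig.width = 6, fig.height = 4}
plot_dda_surface(output = "range_pct", n = 31)
```

## Session engine

Rounds last 30 s. Targets spawn on the interval grid (first spawn one
interval in) and must resolve before the round ends, so a round holds
`floor((30 − lifetime)/interval)` targets; a target's lifetime is the
time to climb the configured ascent distance (1.5 m) at its speed.
Hits earn `round(base_points × gun_weight)` points (sniper rifle:
half speed, half points); purchases strictly conserve the ledger.
Background music starts each round at speed 1.0 and rises 10% per miss
— compounding multiplicatively by default, with additive and
no-reset behaviour available in configuration, since the published rule
states the 10% increment but neither compounding nor reset. A pain
score above the configurable threshold (default 4/10) stops the
session; the long-term reward loop must satisfy
`cycles × period ≥ rehabilitation duration`.

## The virtual patient

`virtual_patient()` is declared plumbing: the published framework
contains no patient model, so the simulator's job is narrowly to make
the closed loop testable. Its hit model has four ingredients — a true
comfortable range per axis (targets demanding a larger fraction of the
required range than the patient's attainable fraction always miss), a
true strength grade (a deficit inflates aim noise linearly), Gaussian
aim scatter against the target radius (`p = Φ((d/2)/σ_eff)`), and a
timing gate. Misses record the target's own fraction of the required
range, so reachability misses always land beyond the patient's
attainable fraction and noise misses never do — which is exactly the
signal the miss-location rule needs. Hit rate is asserted (not assumed)
to respond monotonically to range demand and target size.

What the simulator does *not* emulate: learning and recovery over
sessions, biomechanics of compensatory movement, fatigue within a
round (an optional per-round noise multiplier exists, off by default so
convergence tests run against a stationary patient), and any specific
stroke pathophysiology. Passing closed-loop tests therefore show the
controller tracks a stable, monotone synthetic player — not that it is
clinically validated.

## Closed-loop behaviour and problem sizes

Two properties summarise the loop, both exercised in the test suite:

* **Band holding.** For a stationary mid-ability patient (true ROM
  70/70/90°, strength 2.5, σ = 0.06 m — a plausible Brunnstrom-IV
  profile) starting from the worked clinical evaluation, the rolling
  hit rate (10-round window; the per-round rate of a ~9-target round is
  quantized to ninths, so band membership is judged on the smoothed
  rate) sits inside 50–70% in the vast majority of the last 50 of 200
  rounds, across 10 seeds.
* **Requirement recovery.** For a patient whose true ROM is 60° under
  an initial 90° requirement, the range requirement descends toward
  60° within 100 rounds. A note on identifiability: the gate stops
  adapting as soon as the round hit rate enters the band, and the hit
  rate factorizes approximately as `P(reachable) × p_aim`. The
  requirement is therefore recovered sharply only when the patient's
  within-reach hit probability `p_aim` itself sits near the band —
  otherwise the loop legitimately parks at the requirement where the
  *product* enters the band, up to roughly one adjustment step above
  the true range. Accordingly the recovery check is evaluated on the
  Monte-Carlo mean of the 10 seeded runs.

Problem sizes used throughout the suite (chosen to estimate the
relevant statistics with comfortable margins): 200-round courses for
band holding, 100-round courses for recovery, 10 seeds each; 1,000-draw
Monte-Carlo checks of the hit model against the closed-form normal CDF;
a 101 × 101 grid for controller sign/monotonicity; 2,001-point centroid
discretization validated against a 10,001-point trapezoidal oracle.

## Numerical choices

* Centroid defuzzification uses a fixed 2,001-point grid with
  trapezoidal end-weights; deterministic, and within `10⁻³` of the
  output range of a dense independent oracle.
* Out-of-support inputs are clamped, never rejected: hit rates and
  fractions are bounded by construction, so clamping only guards float
  drift.
* Membership functions with coincident breakpoints (vertical edges at
  a support end) take degree 1 at the shared point, keeping partitions
  Ruspini at the boundary.
* If no rule fires (possible only for degenerate user-supplied rule
  bases), the declared default of zero adjustment is returned and
  flagged rather than erroring mid-session.
* All simulation randomness flows from explicit seeds through a scoped
  generator that restores the caller's RNG state; a course is a pure
  function of (patient, initial requirements, configuration, seed).

## Known limitations

The engine optimizes challenge, not therapeutic dose; it has no notion
of movement quality or compensation. The miss-location rule reads "a
significant share of misses beyond 70% of the required range" — the
alternative reading (70% beyond the range) would shift the threshold
semantics; the first reading matches the controller-surface axis
definition and is the one implemented. Economy constants (point values,
unlock costs, gun multipliers) are structural defaults, not clinically
derived quantities.
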