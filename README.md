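# fuzzydda

Fuzzy dynamic difficulty adjustment (DDA) engine for upper-limb
rehabilitation serious games.

Adaptive rehabilitation games must translate qualitative clinical
assessments into continuous game parameters, then keep the challenge
matched to the patient as they play. `fuzzydda` implements that loop for
a VR-style target-shooting game aimed at mild-to-moderate post-stroke
patients (Brunnstrom stages IV–V): it is written for rehabilitation
engineers and serious-game researchers who need the *computational*
core — parameter mapping, controller, session rules, and a simulator to
test against — without any game client.

## The model

**Initial difficulty.** Manual muscle testing (MMT) grades are pooled
into one continuous strength requirement `s = mean(g₁…gₙ)` and
fuzzified over a Ruspini partition {III, IV, V} of the grade axis
(unit-spaced triangles peaking at 3, 4, 5 with shoulder sets at the
extremes, so Σᵢ μᵢ(s) = 1). Each set carries a nominal target
(diameter, speed); the design value is the membership-weighted average

    d(s) = Σᵢ μᵢ(s)·dᵢ / Σᵢ μᵢ(s).

The spawn region comes from the active range of motion of the shoulder
(azimuth/elevation, 0–90°) and elbow (flexion mapped to reach by
`reach(θ) = 1 − θ/180`).

**Dynamic adjustment.** A two-stage controller runs after every 30 s
round. Stage 1 is a crisp Yerkes–Dodson comfort-band gate on the hit
rate *h*: within [0.50, 0.70] nothing changes. Stage 2, outside the
band, is a Mamdani fuzzy module (min-implication, max-aggregation,
centroid defuzzification) over the *beyond-range miss share* m — the
fraction of misses recorded past 70% of the required range. High m cuts
the range requirement hard and the strength requirement gently; low m
does the reverse; amplitudes scale with `(0.50 − h)/0.50`. Above the
band both requirements rise with `(h − 0.70)/0.30`, split evenly.
Outputs are signed fractions of a maximum step (10°, 0.5 grade units by
default) applied to the motor-function requirements, which regenerate
the parameters — closing the loop.

**Session & rewards.** Seeded spawn schedules, hit/miss/BGM events
(+10% music speed per miss), a points/unlock economy with per-gun point
weights, a pain-score continuation gate, and the reward-cycle
constraint `cycles × period ≥ rehabilitation duration`.

**Virtual patient.** A declared-synthetic player model (true ROM per
axis, true strength, Gaussian aim noise, reaction budget) that makes
the closed loop testable and supports parameter-recovery experiments.

## Worked example

```r
library(fuzzydda)

ev  <- read_evaluation(system.file("extdata", "example_evaluation.yaml",
                                   package = "fuzzydda"))
req <- requirements_from_evaluation(ev)
req
#> <motor_requirements>
#>   range shoulder_azimuth      90.0 deg
#>   range shoulder_elevation    90.0 deg
#>   range elbow                 90.0 deg
#>   strength requirement    3.33 (MMT grade units)

motor_function_to_parameters(req, parameter_config())
#> <game_parameters>
#>   target diameter  0.267 m
#>   target speed     0.367 m/s (lifetime 4.09 s)
#>   round duration   30 s, spawn every 3 s
#> <spawn_region> azimuth [0, 90] deg, elevation [0, 90] deg, reach [0.500, 1.000]
```

Grades 3, 3, 4 pool to 3.33, which belongs to set III at 0.67 and set
IV at 0.33; the 0.267 m target diameter is the weighted average
`0.67·0.30 + 0.33·0.20` of the III/IV nominal sizes — a patient between
grades gets a target between the two nominal sizes.

Close the loop against a synthetic patient whose shoulder range (70°)
falls short of the initial 90° requirement:

```r
pt <- virtual_patient(true_rom = c(shoulder_azimuth = 70,
                                   shoulder_elevation = 70, elbow = 90),
                      true_strength = 2.5, aim_noise_sd = 0.06)
course <- simulate_course(pt, req, n_rounds = 60, seed = 42)
glance(course)
#> # A tibble: 1 × 9
#>   n_rounds mean_hit_rate mean_hit_rate_last50 in_band_share_last50
#> 1       60         0.510                0.515                 0.68
#>   final_range_azimuth final_range_elevation final_range_elbow final_strength
#> 1                79.9                  79.9              79.9           3.91
#>   total_points
#> 1         2460
```

The controller has pulled the range requirement down from 90° toward
the patient's ability and holds the mean hit rate near the middle of
the 50–70% comfort band. `tidy(course)` returns the per-round
trajectory and `autoplot(course)` plots it; `write_event_log()` /
`write_report()` export JSON-Lines telemetry and a therapist CSV.

A thin command-line wrapper covers the same operations
(`init`, `simulate`, `adjust`, `report`, `validate-design`):

```sh
Rscript inst/cli/fuzzydda.R simulate \
  --evaluation inst/extdata/example_evaluation.yaml \
  --patient inst/extdata/example_patient.yaml \
  --rounds 20 --seed 7 --out log.jsonl
```

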