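# gaitfes

Personalized planar neuromusculoskeletal gait models and model-based design
of functional electrical stimulation (FES) treatments for post-stroke
propulsion asymmetry.

## The problem

After a stroke, the paretic leg usually pushes off far more weakly than the
non-paretic leg. A common treatment — fast treadmill training with FES of
two ankle muscles (gastrocnemius for push-off, tibialis anterior for toe
clearance) — is prescribed the same way for every patient, and some
patients do not respond. `gaitfes` implements a model-based alternative at
planar desk scale: personalize a neuromusculoskeletal walking model to a
patient's treadmill data, check that the model can re-predict the patient's
gait without being shown it, and then solve optimal control problems that
choose which two muscles to stimulate, when, and how strongly, so that the
inter-leg difference in the anterior-posterior (AP) ground-reaction
impulse,

```
ΔJ = | ∫ F_AP,nonparetic dt − ∫ F_AP,paretic dt |       (one gait cycle)
```

is minimized. Everything runs on a fully ground-truthed *virtual patient*
(a planar 11-DOF skeleton, 9 Hill-type muscles per leg with rigid tendons,
compliant foot-ground contact, and 5 non-negative muscle synergies per leg
with the paretic plantarflexor drive scaled down), so every stage of the
pipeline is testable as a parameter-recovery problem.

The core pieces:

* **Model personalization** in four stages — joint-centre calibration from
  markers, EMG-driven muscle-tendon calibration with synergy-based
  reconstruction of muscles lacking EMG, foot-ground contact calibration by
  tracking optimal control, and neural-control (synergy) calibration — plus
  a verification problem whose only cost is joint-jerk minimization and
  which must reproduce the measured gait from the model alone.
* **Treatment optimization** — a baseline asymmetry-minimization problem
  and four stimulation problems (standard muscles with standard or free
  timing, two-muscle selection through the continuous muscle count
  `n = Σ (1 − e^(−4 A_i)) ≤ 2 + tol`, and optimization of the selected
  pair), with stimulation modelled as a smooth tanh pulse
  `a_stim(t) = A/2 [tanh c₁(t−t_on−δ₁) − tanh c₂(t−t_off−δ₂)]
  + A/2 [1 − tanh c₂(t−t_off−δ₂+t_end)]` whose shape parameters are
  calibrated against each muscle's activation dynamics.
* **A direct-collocation optimal control engine** with joint-jerk controls,
  exact elimination of the linear state defects through an orthonormal
  null-space basis, and an augmented-Lagrangian Levenberg–Marquardt solver
  with batched finite-difference Jacobians — pure R, deterministic,
  feasibility tolerance 1e-6.

See the methods vignette (`vignettes/gaitfes-methods.Rmd`) for the model
equations, assumptions, parameter defaults, and numerical design choices.

## A worked example

Build a virtual patient with a 60% paretic plantarflexor deficit, generate
its dynamically consistent reference gait, and look at the asymmetry:

```r
library(gaitfes)

patient <- make_virtual_patient(seed = 1)      # deficit = 0.4 by default
ref <- generate_reference_gait(patient)
out <- ref$outputs

metrics <- ap_impulse_metrics(out)
round(c(paretic = metrics$r$impulse, nonparetic = metrics$l$impulse,
        difference = metrics$diff), 2)
#>    paretic nonparetic difference
#>     -14.19      14.20      28.39      (N s, seed 1)
```

The paretic (right) leg shows the classic hemiparetic signature: a smaller
propulsive impulse and peak than the non-paretic leg, with braking
dominating. `synthesize_measurements()` then turns the reference cycle into
a measured trial (markers + 3 mm noise, ground reactions + 2 N noise, EMG
envelopes with 5% multiplicative noise and the iliopsoas/biceps-femoris
channels withheld), `personalize()` runs the four calibration stages plus
verification, and `design_treatment()` runs the baseline and the four
stimulation problems and emits outcome tables in the style of clinical
reports. On the seed-1 patient this build prints:

```
            problem ap_impulse_difference reduction_pct
1          baseline                  10.6            NA
2 standard_standard                  10.1           4.5
3  standard_optimal                  10.0           5.7
4   optimal_optimal                   8.3          21.0
```

the AP impulse difference (N s) for no stimulation, standard muscles with
standard and with optimized timing, and the optimized two-muscle selection,
with percent reductions relative to baseline — the same monotone
more-freedom/more-improvement pattern the clinical problem shows at full
scale. Stimulation parameters per problem (amplitude, on/off in % gait
cycle) and per-leg propulsive/braking peaks and impulses with percent
changes are reported alongside.

Small building blocks are usable on their own: `process_emg()` (zero-phase
high-pass, demean, rectify, low-pass), `extract_synergies()` /
`choose_num_synergies()` (multiplicative-update NMF with the 95%
per-muscle variance-accounted-for rule), `muscle_force()` and
`activation_dynamics()`, `element_forces()` and
`aggregate_ground_reactions()`, `stim_activation()` and
`effective_muscle_count()`, and the collocation engine
(`ocp_definition()`, `transcribe()`, `solve_ocp()`).

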