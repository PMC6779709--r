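---
title: "Methods: personalized planar gait models and FES treatment design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized planar gait models and FES treatment design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

After a stroke, one leg (the *paretic* side) typically contributes much less
forward propulsion than the other. One rehabilitation approach — fast
treadmill walking combined with functional electrical stimulation (FES) of
two ankle muscles — is usually prescribed identically for every patient:
stimulate tibialis anterior for swing-phase toe clearance and the
gastrocnemius for late-stance push-off, with timing derived from foot
switches. `gaitfes` implements, at planar desk scale, a model-based
alternative: personalize a neuromusculoskeletal walking model to a patient's
treadmill data, verify that the model re-predicts their gait without being
shown any of it, and then ask the model which two muscles should be
stimulated, when, and how strongly, so that the inter-leg difference in the
anterior-posterior (AP) ground-reaction impulse over a gait cycle becomes as
small as possible.

Everything runs on a virtual patient: a planar model whose ground truth is
known exactly, so every calibration stage can be tested as a recovery
problem rather than a plausibility argument.

## The model

**Skeleton.** An 11-degree-of-freedom sagittal-plane linkage: a pelvis+HAT
(head–arms–trunk) floating base with coordinates (x, y, tilt), and per leg a
hip, knee, ankle, and toe (metatarsophalangeal) revolute. Flexion and
dorsiflexion are positive; x is the direction of progression, y is up;
angles are radians internally and degrees in reports. Segment masses,
lengths, and inertias approximate a 75 kg adult. Toes are torque-actuated;
hips, knees, and ankles are muscle-actuated.

**Muscles.** Nine Hill-type muscles per leg (iliopsoas, glutei, hamstrings,
rectus femoris, vasti, biceps femoris short head, gastrocnemius, soleus,
tibialis anterior) with rigid tendons: fiber length follows algebraically
from muscle-tendon length, with a constant-thickness pennation model. The
active force-length curve is a three-Gaussian form, force-velocity a
log-hyperbolic form, and the passive curve exponential; all are smooth
because the optimal control solver differentiates through them, and all are
normalized so that maximal isometric force at optimal fiber length equals
`f_max` exactly. With a rigid tendon the entire muscle-tendon excursion is
taken up by the fiber, so the *effective* optimal fiber lengths are set
longer than anatomical fascicle lengths (8–14 cm); otherwise ankle fibers
would leave the force-length plateau during push-off, which compliant
tendons prevent in reality.

**Geometry.** Muscle paths are straight-line segments between points fixed
in body segments. For speed and smoothness inside the optimizer, lengths and
moment arms are replaced by polynomial *surrogates* in the spanned joint
angles (total degree 4), fitted jointly: the moment-arm rows of the fit use
the analytic derivative of the length basis, so `r = -dl/dq` holds by
construction everywhere, not just at sample points.

**Activation.** EMG envelopes are scaled by a per-muscle factor, delayed by
an electromechanical delay, passed through bilinear first-order activation
dynamics `da/dt = (u - a)(u / tau_act + (1 - u) / tau_deact)` (defaults
15 ms / 60 ms), and shaped by the exponential nonlinearity
`(exp(S a) - 1)/(exp(S) - 1)`. The cited literature leaves the exact
equations open; these choices are standard in EMG-driven modelling and
smooth enough for gradient-based optimization.

**Contact.** Each two-segment foot carries 9 compressive spring-damper
elements on a line under the sole (6 hindfoot, 3 toes — the planar
reduction of a rectangular grid). The normal force is
`(k d^3 + k_lin d) * smooth_pos(1 + c ddot)` in the penetration depth `d`;
the small linear term (`k_lin` = 3 kN/m, a few newtons at working depths)
exists purely to keep the force gradient alive at first touchdown, where a
bare cubic is flat and stalls gradient-based solvers. Friction is
tanh-smoothed Coulomb plus a viscous term in the slip velocity relative to
the belt surface. The default stiffness (1e9 N/m^3 per element) gives
roughly 8–10 mm penetration under body weight — a deliberately compliant
ground that widens the optimizer's basin of attraction; it is a calibrated
parameter, not a constant.

**Treadmill frame.** Gait is simulated in the progression (belt-fixed)
frame: the subject advances at belt speed, the belt surface is stationary,
and the pelvis forward position is periodic up to one stride per cycle.
Simulating in the lab frame with a moving belt and a stationary subject is
the same physics in different coordinates; the progression frame keeps the
contact slip term and the periodicity constraint from double-counting the
belt speed. The `belt_speed` field of the contact parameters is the belt
surface velocity *in the simulation frame* (zero here), so a lab-frame
treadmill can still be modelled directly.

**Synergies.** Each leg is driven by 5 time-varying synergy activations
through a 9-by-5 non-negative synergy-vector matrix. Five (the clinically
typical number) rather than a smaller count is a structural necessity, not a
fitting preference: with non-negative activations, the reachable set of
(hip, knee, ankle) moments is the positive cone of the synergy-to-moment
map, and fewer, broadly-tuned columns leave walking's moment loops partly
outside that cone — the moment-matching constraints then have no solution at
any motion. The default columns are dominated by knee extensors, ankle
plantarflexors, hip flexors (swing), a heel-strike flexor group, and hip
extensors, which positively span the moment space on both legs.

## The virtual patient

`make_virtual_patient()` builds the ground truth: skeleton, muscle
parameters (per-muscle EMG scales, delays, and nonlinearity shapes drawn
reproducibly from physiological ranges), contact parameters, and the
synergy structure above. The paretic-side deficit multiplies the
gastrocnemius and soleus rows of the paretic synergy matrix by the deficit
factor (default 0.4), directly emulating reduced plantarflexor drive.

The reference gait is *not* a forward simulation: `generate_reference_gait()`
solves a tracking optimal control problem on the true model — synergy
activations and joint jerks as controls, full dynamics, contact, and
periodicity as constraints — so the generated cycle is periodic and
dynamically consistent to the solver tolerance by construction. The
kinematic template it tracks is built from foot trajectories (stance foot
pinned flat with a millimetre-scale penetration bell, heel rise pivoting
about the metatarsals, swing landing flat at zero velocity, a 3 cm longer
paretic step as in hemiparetic gait) with joint angles from closed-form leg
inverse kinematics; templates built directly from joint-angle curves leave
centimetre-scale foot-ground inconsistencies that the stiff contact model
amplifies into thousands of newtons.

`synthesize_measurements()` emits markers (segment-fixed points + Gaussian
noise, default 3 mm), ground reactions (+2 N noise), and EMG envelopes with
5% multiplicative noise. Envelopes are obtained by *inverting* the
activation pipeline (nonlinearity, then the exact discrete activation
recursion, then delay and scale) so that the forward EMG-driven pipeline
with true parameters reproduces the true activations; defining envelopes as
scaled activations directly would make noiseless recovery impossible by
construction. Where the optimal-control activations decay faster than the
deactivation time constant allows, no consistent excitation exists; the
inversion clamps and the generator reports the residual instead of hiding
it. A weak rate regularizer on the synergy controls keeps such episodes
small.

What the generator does *not* emulate: 3-D kinematics (hip ab/adduction,
ankle inversion), soft-tissue marker artefact, EMG crosstalk, handlebar
support loads, stride-to-stride variability, and bony geometry differences
between subjects. Passing recovery tests here demonstrates that the
algorithms are correctly implemented and identifiable under the stated
noise, not that they would behave identically on full 3-D laboratory data.

## The optimal control engine

All personalization and treatment problems share one structure: states are
joint positions, velocities, and accelerations; the control is joint *jerk*
(so dynamics can be imposed in inverse form); algebraic controls (synergy
activations) and static parameters (contact properties, synergy vectors,
stimulation amplitude/timing) complete the unknowns.

Transcription uses a fixed mesh (default 14 intervals per cycle) with
collocation at nodes and midpoints. Because the jerk chain is linear and
jerk is piecewise linear, the state defects are eliminated *exactly*:
states everywhere are a linear map of the free variables. Two numerical
choices matter:

* the free variables are coordinates in an **orthonormal basis of the
  defect null space** computed on scaled variables — the raw
  (initial-state, jerk) parametrization is equivalent but its Jacobian
  condition number (~1e7, from t^3 accumulation) defeats Gauss-Newton
  methods in double precision;
* hard path constraints (floating-base dynamics, synergy moment matching)
  are imposed **at nodes only**, where the discretization has exactly
  enough freedom; the same residuals at midpoints enter the cost with a
  moderate weight, which damps the between-node oscillation that node-only
  collocation would otherwise admit.

The solver is an augmented-Lagrangian method: an outer loop updates
multipliers (penalty weight 10, increased tenfold when an outer iteration
fails to cut the violation by 4x), around a damped Levenberg–Marquardt
inner solver with bound constraints handled by an active-set step and
backtracking. Jacobians are forward finite differences evaluated in a
single batched call — every model quantity is computed for all perturbed
columns at once — which is what makes a pure-R implementation viable. A
solution is reported `"converged"` only when the maximum scaled constraint
violation is at or below 1e-6 (forces scaled by 750 N, moments by
100–150 N m). Identical inputs give bitwise-identical solutions.

Two transcription-level choices are worth noting. Pelvis forward
translation is periodic up to one stride (`belt_speed * t_end`). And the
fore-aft (pelvis-x) dynamics equation is additionally imposed at the
midpoints: the signed between-node residual of exactly this equation is
what would otherwise make the net fore-aft impulse of a periodic cycle
drift away from zero (momentum cannot drift in exact physics), and holding
it everywhere keeps the cycle's net anterior-posterior impulse at the
millinewton-second level. A single global zero-net-impulse row would pin
the same quantity, but in practice it steers the solver into a spurious
symmetric optimum; the local midpoint rows do not.

## Personalization stages

1. **Joint model** (`calibrate_joint_model`): outer least squares over the
   hip/knee/ankle joint-centre locations in their parent segments; inner
   loop alternates per-frame planar inverse kinematics with linear updates
   of the leg-marker local positions (pelvis markers fix the gauge —
   otherwise joint offsets and marker offsets trade off one-for-one).
   Velocities and accelerations come from Fourier-series smoothing
   differentiation (lowest 10 harmonics), which is exact for periodic
   signals and avoids the end-effects of spline differentiation on cyclic
   data.
2. **Muscle-tendon** (`calibrate_muscletendon`, per leg): nonlinear least
   squares over EMG scales, delays, time constants, shapes, optimal fiber
   lengths, tendon slack lengths, and the synergy weights of the two
   muscles without EMG (iliopsoas, biceps femoris short head). Each
   objective evaluation runs the full pipeline — scale, delay, activation
   dynamics, NMF of the measured activations (warm-started multiplicative
   updates), reconstruction of the missing muscles, Hill forces, joint
   moments — and stacks moment errors (hip errors doubly weighted, the
   standard balance against larger hip moment magnitudes), passive-moment
   errors at reference poses, and a weak pull toward the initial guesses.
   The passive reference comes from the virtual patient's own passive
   curves; with real data it would be a published table.
3. **Contact** (`calibrate_contact`): the tracking optimal control problem
   with contact stiffness, damping, and the two friction coefficients as
   static parameters, tracking joint angles (toe angles extra-weighted,
   because small toe errors produce large ground-reaction changes), ground
   reactions, and inverse-dynamics moments; then a second problem with
   contact frozen that adds jerk minimization, +/-3 degree toe-angle error
   bounds, and periodicity, producing the dynamically consistent motion the
   neural stage starts from.
4. **Neural control** (`calibrate_neural_control`): synergy vectors as
   static parameters (non-negative, unit norm at the solution), synergy
   activations as controls; tracks angles, ground reactions, moments, and
   the EMG-driven activations, subject to dynamics and moment matching.
5. **Verification** (`verify_model`): the prediction test. No tracking
   terms at all — the cost is jerk minimization (plus a small toe-actuator
   regularizer); synergy vectors are frozen; activations may deviate from
   calibrated only within a +/-0.1 band; dynamics, moment matching, and
   periodicity are enforced. The solution is compared to the withheld
   trial.

## Treatment design

The baseline problem adds the squared inter-leg AP-impulse difference to
the verification cost. Its weight follows a bracketing rule: the largest
value from a short ladder that changes the predicted joint angles by less
than 2 degrees RMSE relative to verification — large enough to matter,
small enough not to distort the gait.

Stimulation enters as the smooth three-term tanh pulse in amplitude,
on-time, and duration, whose shape parameters are calibrated once per
muscle by least squares against the muscle's own activation dynamics under
a unit step (the third term wraps stimulation across the cycle boundary).
Stimulation adds to the synergy-generated activation, and the sum is
path-constrained below one; amplitudes are bounded at 0.7 for that reason.
Four problems follow the baseline: standard muscles (gastrocnemius +
tibialis anterior) with on-times within +/-50 ms of nominal and fixed
duration; standard muscles with free timing (wrap-around allowed); a
selection problem in which all seven measured paretic muscles receive
stimulation parameters and the continuous muscle count
`sum(1 - exp(-4 A_i))` is constrained to at most 2.1, after which the two
largest-amplitude muscles are retained; and free-timing optimization of
the selected pair. Each warm-starts from its predecessor.

Outcomes are Simpson-quadrature integrals of the AP force: per-leg signed,
propulsive (positive part), and braking (negative part) impulses and
peaks, the inter-leg difference, and percent changes against baseline
(half-away-from-zero rounding, one decimal, as clinical tables print
them).

## Reporting conventions and identifiability

Fit-quality reports (joint-angle, ground-reaction, and activation RMSEs)
are evaluated at the mesh nodes, where the collocation solution is defined;
between nodes the interpolated trajectory carries transcription ringing
that is damped but not eliminated by the midpoint cost. Two calibration
stages use pinned-kinematics sub-problems for the same reason: the muscle
calibration fits joint moments at the node times (where the measured data
are most dynamically consistent), and the contact calibration anchors its
static parameters to a pre-fit against the measured ground reactions with
the motion frozen at the data — inside the free tracking problem the motion
can absorb penetration-depth changes at negligible kinematic cost, leaving
the stiffness direction almost flat. Contact stiffness is optimized in
log10. The Coulomb and viscous friction coefficients are individually
near-degenerate at stance slip speeds (both act linearly in the slip below
the smoothing velocity); their pinned-kinematics combination is what the
data determine.

The verification problem's synergy-activation deviation band defaults to
0.02: following the rule used for all such error bounds here, it is sized
to the activation-agreement scale of the calibration stage itself
(~0.02-0.05), large enough to let the prediction move, small enough to
honour the design intent of "only small changes" to the calibrated
control.

Muscle redundancy limits what one noiseless cycle can identify: optimal
fiber and tendon slack lengths of strongly recruited muscles (vasti,
tibialis anterior, iliopsoas) recover to a few percent, while weak or
synergist-paired muscles (biceps femoris short head, hamstrings, the
soleus-gastrocnemius pair) can drift 5-20% along near-null directions that
change joint moments by less than the residual data-consistency floor
(~0.5-1.5 N m). Starting the optimizer at the true parameters and watching
it drift away confirms this is an identifiability property of the data,
not an optimizer failure.

## Problem sizes and tolerances

Defaults, chosen once for desk scale: 14 mesh intervals per 1.2 s cycle
(29 collocation points), 101-sample measurement trials, feasibility
tolerance 1e-6 on scaled constraints, optimality by relative cost decrease
1e-10, NMF with 20 replicates and 1e-8 relative tolerance (single
warm-started replicates inside calibration loops), finite-difference step
1e-6 on scaled variables. The recovery and treatment test suites run the
whole chain once on a noiseless patient and reuse the results across
assertions.

## Known limitations

* The engine is a batched finite-difference augmented-Lagrangian method;
  it is robust at this scale but would not scale to 3-D models with dozens
  of muscles the way sparse exact-derivative interior-point solvers do.
* Node-only hard dynamics with soft midpoint damping leaves residual
  between-node dynamics error of a few newtons; halving the mesh width
  reduces it but roughly doubles runtime.
* With non-negative synergy drives, moment feasibility depends on the
  synergy-vector structure; badly conditioned (near-collinear) vectors can
  make the moment-matching constraints unsatisfiable, which presents as an
  honest `tolerance_not_met` status rather than a wrong answer.
* The stimulation model is the activation-level pulse only: no pulse-width
  or frequency physiology, no current spread between neighbouring muscles,
  and no model of how training changes neural control over weeks.
* Kinematic symmetry is deliberately absent from the treatment objective;
  improving propulsive symmetry does not, by itself, make the predicted
  motion symmetric.
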