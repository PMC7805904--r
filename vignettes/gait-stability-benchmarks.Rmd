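---
title: "Benchmarking gait stability from reconstructed whole-body dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gait stability from reconstructed whole-body dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbench)
```

## What the package computes

`gaitbench` turns marker-based motion capture of walking into a small set of
stability benchmarks:

* the **Instantaneous Capture Point (ICaP)**, the ground point
  $r_{icap} = r_{ref} + \dot r_{com}/\omega_0$ at which a linear inverted
  pendulum (LIPM) stepping there would come to rest, with eigenfrequency
  $\omega_0 = \sqrt{g/\ell}$;
* the **normalized orbital energy**
  $E'_{lip} = \tfrac12 \dot r'^2_{com} - \tfrac12 (r'_{com}-r'_{cop})^2
  \omega_0^2$ of the LIPM, with all position-like quantities divided by the
  subject's leg length (primes), so values are comparable across subjects;
* the **Residual Orbital Energy** $E'_{res}$: $E'_{lip}$ evaluated right
  after each heel strike, on the post-impact side of the touch-down, with
  the CoP of the landing foot — the scalar each stride leaves "in the bank"
  for forward progression; and
* the decomposition of the **whole-body angular momentum** about the COM
  into upper-body and lower-body contributions, per anatomical plane.

Between the raw markers and these numbers sit a subject-specific rigid
multibody model, a whole-chain least-squares inverse kinematics, and a
multi-phase least-squares optimal control problem (OCP) that makes the
kinematics dynamically consistent — contact constraints, impacts, torques
and all. Every stage is exercised end to end on synthetic data generated by
the package itself, so the pipeline is testable without laboratory
recordings.

## Models

Subject-specific inertial parameters come from sex-specific regression
tables (segment mass fractions, longitudinal COM positions and radii of
gyration of the adjusted Zatsiorsky–Seluyanov type, with segment lengths as
stature fractions from standard landmark ratios). The shipped table is
versioned (`bsp_table()`, revision `deleva-adjusted-1`) and pinned by the
test suite; mass fractions are renormalised to sum exactly to one so that
whole-body mass is conserved to $10^{-9}$ relative. Where a transfemoral
prosthesis is modelled, the prosthesis-side thigh, shank and foot are scaled
uniformly so that the leg-mass ratio matches the prescribed value (inertia
scales with the same factor); measured per-segment data can be injected
through overrides, in which case the unmeasured segments absorb the residual
so the ratio stays exact.

The full-body model has 16 segments and 43 DoF: a 6-DoF floating base at the
pelvis, 3-DoF ball joints at the hips, ankles, lumbo-sacral junction,
xiphoid, cervicale, shoulders and wrists, and 1-DoF knees and elbows.
Because walking moves the xiphoid and wrist joints very little, the working
model locks them, rigidly merging the upper trunk into the middle trunk and
the hands into the forearms (parallel-axis composite inertia), leaving 13
segments and 34 DoF. Each foot is a rigid triangle with contact points at
the heel, hallux and fifth metatarsal head.

Conventions the source material leaves open, fixed here and flagged as
conventions: world axes are x anterior, y lateral (left positive), z up,
with gravity $-9.81\,\mathrm{m/s^2}\,\hat z$; the floating base uses
translation followed by intrinsic yaw–roll–pitch rotations (gimbal lock at
$\pm 90^\circ$ roll, far outside walking); ball joints decompose as
flexion–adduction–axial rotation ($R_y R_x R_z$); foot geometry is scaled
from foot length (heel at $-0.25 L_f$, hallux at $0.75 L_f$, meta5 at
$0.50 L_f$ with a lateral offset, sole one ankle-height below the ankle) and
is user-overridable.

## Constrained dynamics, contacts, impacts

The dynamics engine is a spatial-algebra implementation of the standard
recursive algorithms (composite-rigid-body for the mass matrix, recursive
Newton–Euler for the nonlinear effects), with each active contact point
constraining its translations. Accelerations and contact forces solve the
mixed KKT system
$$\begin{pmatrix} H & G^T \\ G & 0 \end{pmatrix}
  \begin{pmatrix} a \\ -\lambda \end{pmatrix} =
  \begin{pmatrix} \tau - C \\ \gamma \end{pmatrix},$$
where the contact Hessian $\gamma = -\dot G v$ is evaluated as minus the
classical acceleration of the constrained points under zero generalized
acceleration. Touch-downs are perfectly inelastic: velocities reset through
$$\begin{pmatrix} H & G^T \\ G & 0 \end{pmatrix}
  \begin{pmatrix} v^+ \\ -\Lambda \end{pmatrix} =
  \begin{pmatrix} H v^- \\ 0 \end{pmatrix},$$
which conserves the momentum projection orthogonal to the constraints and
never increases kinetic energy.

A flat foot makes the raw per-point constraint rows redundant, and at zero
foot pitch the heel and forefoot x-rows coincide *exactly*, so a naive
numerical rank decision flips bases under infinitesimal configuration
changes and makes the dynamics non-differentiable precisely on the
configurations walking passes through. The package therefore retains a
*structural* row basis per foot, fixed by the active contact configuration
alone (full constraint for the first point, selected in-plane rows for the
others), falling back to a deterministic pivoted reduction for non-standard
geometries. Contact forces are reported per point by redistributing the
reduced multipliers minimum-norm over the full row set; the per-foot
resultant wrench — and hence the CoP — is independent of this gauge choice,
while the per-point split within a rigid foot is a representative, not a
measurement.

Phases are integrated with fixed-step RK4. Two drift-control modes exist:
a least-norm projection of $(q, v)$ back onto the contact manifold after
every step (default for plain simulation; keeps $|g|, |G v| < 10^{-6}$),
and projection-free integration used by the reconstruction transcription
and the synthetic fixture, where the projection's iterative, conditional
nature would corrupt derivative information. Projection-free drift stays
sub-millimetre over the longest (0.4 s) contact phase at the default step.

## Inverse kinematics

`fit_trajectory()` fits all generalized coordinates — base pose included —
to the markers of each frame by damped Gauss–Newton on the whole-chain
point Jacobian (uniform marker weights by default, per-marker weights
available), warm-starting each frame from the previous solution. Frames
with fewer than three valid markers are skipped with a warning; marker gaps
are handled by fitting the reduced set, never by interpolating marker data.
Convergence is declared at a step norm below $10^{-10}$ (at most 100
iterations). The per-frame RMS marker distance is reported as mean ± SD in
centimetres, the conventional way marker-fit quality is quoted.

## The reconstruction OCP

The stride is divided into 8 phases by its contact configuration, in the
canonical order (stride from left toe off): right flat / left swing, right
toe-only, left heel + right toe, left flat + right toe, left flat / right
swing, left toe-only, right heel + left toe, right flat + left toe. The 4
touch-downs (two heel strikes, two toe strikes) are transitions where the
velocities jump by the impact map; heel-off and toe-off change the contact
set without an impact, which is why the events container carries heel-off
times alongside the three classic event types. Phase boundary times are
fixed from the detected gait events (an interpretation of the gait-cycle
diagram; the schedule grammar is configurable).

`reconstruct_gait()` then solves
$$\min_{x(\cdot), u(\cdot)} \sum_j \tfrac12 \lVert q^{ik}_j - q(t_j)
 \rVert_2^2 + \gamma_u \lVert W u(t_j) \rVert_2^2$$
subject to the phase-wise constrained dynamics, the impact transitions, and
continuity, by direct multiple shooting: each phase is split into shooting
segments of about 80 ms with their own initial-state variables, controls
are piecewise linear on a configurable node grid, and the resulting
equality-constrained nonlinear least-squares problem is solved by
Gauss–Newton on a KKT system with a backtracking line search, Levenberg
damping and a trust-region cap. Jacobians come from state-transition
matrices propagated along each segment (finite-difference linearization of
the constrained dynamics per integration step; an exact RK4-stage chain
rule is available via `lin_stages = 4`). The short segments are what keeps
the transcription well-conditioned: walking dynamics are exponentially
unstable open loop, and single shooting over a 0.4 s stance phase amplifies
control perturbations enough to defeat a first-order model.

Choices the source material leaves open, decided as follows:

* $W$ and $\gamma_u$: $W = \mathrm{diag}(1/u_{scale})$ with a common
  150 N m torque scale, $\gamma_u = 10^{-3}$ by default. For noise-free
  recovery studies $\gamma_u = 0$ is the exact-fit limit; with it the
  tracking term of a dynamically consistent reference can be driven to
  zero.
* All generalized coordinates are tracked, including the 6 base DoF, with
  configurable per-DoF weights.
* The reference is matched by linear interpolation in time where reference
  frames and integration nodes do not coincide.
* Phase durations are fixed at the detected event times (free-time modes
  are out of scope).
* Path bounds on states and controls are checked and reported by
  `check_solution()` rather than enforced as hard constraints: on tracking
  problems with physiological references the solution respects them, and
  the report keeps violations visible instead of hiding them behind an
  active-set mechanism.
* Unilaterality (vertical contact forces $\ge 0$) is likewise reported, not
  enforced.

`check_solution()` re-integrates every phase at half the solver step with
the solved controls and reports the worst defect against the stored
trajectory, the transition residuals against an independent impact-map
evaluation, the minimum vertical contact force, and bound violations.

### Identifiability of joint torques

In phases where both feet carry multi-point contact the actuation is
redundant: torque combinations satisfying $B\tau \in \mathrm{range}(G^T)$
produce no motion at all (dimension 1 in the heel + contralateral-toe
phases, 2 in flat + toe double support). Reconstructed torques are
therefore identifiable only up to this contact-redundancy gauge.
Comparisons between reconstructed and reference torques are made on the
identifiable projection, weighted by phase duration (the RMS difference of
the torque trajectories); within single-support phases the projection is
the identity and the comparison is plain.

A second, softer limit shows up around the touch-downs: the inelastic
impact discards velocity components, and joint velocities are not directly
observed, so over the short impact-adjacent phases a coordinated change of
initial velocities and torques can reproduce the tracked positions to
within their numerical precision. On the synthetic stride the
reconstruction recovers single-support torques to a fraction of a percent,
while the identifiable components in the two heel + contralateral-toe
phases retain residuals of order ten newton-metres — about six percent of
the stride's torque RMS overall — that no position-tracking method can
resolve at this sampling. Force-plate data, when available, closes exactly
this gap.

## Synthetic data

Two generators make the pipeline testable without recordings.

`simulate_lipm_gait()` produces closed-form LIPM walking: within each
support phase the COM follows the cosh/sinh solution about a fixed CoP
(implemented in exponential-mode form, which avoids catastrophic
cancellation when the growing mode is near zero — exactly the situation of
a capturing step). The default mode is the periodic gait whose support
exchange restores the single-support initial conditions implied by the step
length, width and time; the `on_icap` mode places the next foot exactly on
the COM-based ICaP and holds it, so the pendulum is captured. Support
exchanges are instantaneous by default (the CoP jumps; COM velocity is
continuous), emitting a heel strike for the landing side and a toe off for
the lifting side, and the synthetic footprint places the heel at the CoP.
The generator's default study conditions are a 0.9 m COM height, 0.6 m
steps, 0.2 m step width, 0.55 s step time and 10 steps.

`planar_stride_fixture()` builds a full multibody stride for a planar
7-segment walker (head, arms and trunk merged; 9 DoF, 6 actuated; a 1.75 m,
72 kg subject by default) in three stages: a contact-consistent kinematic
pattern (analytic leg IK over crafted ankle and foot-pitch trajectories,
0.42 m steps over a 1 s stride), constrained inverse dynamics along the
scheduled contacts sampled as piecewise-linear torques (minimum-norm
actuation-redundancy resolution except in the flat+toe double-support
phases, where the deterministic basic solution's internal loading
stabilizes the rollout), and an open-loop hybrid re-simulation with impact
maps at the touch-downs. The re-simulated trajectory — not the crafted
pattern — is the fixture's ground truth: it satisfies the package dynamics
exactly under exactly piecewise-linear torques, which is what downstream
recovery tests need. The toe-only phases are underactuated, so the rollout
drifts from the cosmetic pattern by up to about a radian late in the
stride; that deviation is irrelevant to the fixture's role. Markers are
synthesized by forward kinematics with optional seeded isotropic noise; all
randomness flows through explicit seeds and the global RNG state is
restored.

What the synthetic data does *not* emulate: soft-tissue artifact,
marker-labeling errors and gaps, force-plate noise, compliant ground,
muscle-level actuation, and three-dimensional balance (the stride fixture
is sagittal). Passing tests therefore demonstrate that the machinery is
internally correct and mutually consistent, not that laboratory recordings
of a particular subject would reproduce published values.

## Numerical choices

* Integrator: fixed-step RK4; default steps 10 ms (reconstruction), 5 ms
  (general simulation), 2 ms where conservation is asserted to $10^{-6}$.
* Constraint-row reduction tolerance $10^{-8}$ (relative); KKT solves are
  dense base-R solves at these problem sizes.
* IK damping: Levenberg with adaptive scaling from $10^{-6}$.
* OCP: merit function with quadratic constraint penalty $10^4$, damping
  floor $10^{-10}\,\max(\mathrm{diag}(J^TJ))$, trust-region cap 200 on the
  step norm, convergence at step norms below $10^{-8}$ and continuity below
  $10^{-8}$.
* Problem sizes used by the shipped tests: the 34-DoF model for dynamics
  oracles and conservation checks, the 9-DoF planar walker for IK and
  reconstruction, one stride at 10 ms with about 60 control nodes. These
  are the package's chosen desk-scale study conditions; the machinery
  accepts the spatial model throughout.

## Metric conventions

* ICaP reference point: the printed formula uses the CoP, the capture-point
  literature the COM ground projection. The package defaults to the COM
  projection — with it, "place the CoP on the ICaP and the pendulum comes
  to rest" is an exact identity, and the between-feet ICaP trajectory is
  smooth — and offers the as-printed CoP form behind
  `reference = "cop"`. Every output records which was used.
* Two pendulum lengths play different roles: $\omega_0$ is evaluated from
  the instantaneous COM height at each instant (a constant-leg-length mode
  exists), while the normalization length is the constant hip-to-ankle leg
  length.
* "Right after heel strike" means the post-impact side of the transition:
  at a duplicated boundary sample the later row (new CoP, post-impact
  velocity) is used; on smoothed kinematics without an impact map this is
  the first sample after the detected event.
* Body split for the momentum decomposition: lower body = pelvis + both
  legs + feet; everything else upper. Pelvis assignment is configurable.
  Plane mapping: frontal = x component, sagittal = y, horizontal = z.
* Event detection thresholds: vertical force above 2 % body weight, or
  contact-point height below 5 mm; both configurable.
* The stride aggregate of $E'_{res}$ is the mean of the left-heel-strike
  and right-heel-strike values.

## Worked example

```{r lipm-example, eval = FALSE}
spec <- lipm_gait_spec(com_height = 0.9, step_length = 0.6,
                       step_width = 0.2, step_time = 0.55, n_steps = 10)
gait <- simulate_lipm_gait(spec)
res <- residual_orbital_energy(gait$traj, gait$events)
print(res)
fps <- foot_placement_summary(gait$traj, gait$events, gait$footprints)
head(fps)
```

And the full multibody loop:

```{r stride-example, eval = FALSE}
fx <- planar_stride_fixture()
ref <- fit_trajectory(fx$model, fx$mset, fx$markers)
rec <- reconstruct_gait(fx$model, ref, fx$schedule,
                        ocp_config(gamma_u = 0))
summary(rec)
check_solution(rec)
```

## Known limitations

* The spatial 34-DoF reconstruction is supported by the same code paths but
  not exercised by the shipped tests; wall-clock cost grows roughly with
  `n_dof^2` per dynamics evaluation.
* C3D input is not implemented (binary vendor format); TRC and CSV exports
  are the ingestion paths.
* Free phase-boundary times, friction-cone checks, muscle models and
  predictive (non-tracking) optimization are out of scope.
* The synthetic stride's per-point contact-force split can transiently pull
  on a point within a foot (the gauge artifact discussed above) even while
  the per-foot resultant stays compressive; force-plate data, where
  available, should be preferred as the CoP source.
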