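---
title: "Center-of-mass estimation for standing balance: models, filters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-of-mass estimation for standing balance: models, filters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(standcom)
```

## The problem

Clinical balance assessment during quiet standing is usually built on the
center of pressure (COP), because a force platform measures it directly.
Control-theoretic analyses of posture, however, need the state of the
controlled plant: the horizontal displacement and velocity of the whole-body
center of mass (COM), to millimetre accuracy, ideally online and also when
the support surface is moved under the subject. Optical motion capture can
deliver that but is impractical outside the laboratory.

`standcom` implements per-sample algebraic inversions of linearized
inverted-pendulum models of upright stance that recover the COM from
force-platform channels (horizontal forces, moments about the horizontal
axes, vertical force), optionally extended by one head-mounted IMU, plus a
Kalman filter that fuses the two inversion outputs — displacement from the
moment balance, acceleration from the force balance — into a
displacement + velocity estimate with essentially no phase delay.

## Models and estimators

Conventions: $x$ forward (anteroposterior, AP), $y$ left (mediolateral,
ML), $z$ up; the moving frame is fixed to the plate center, and the support
may accelerate horizontally ($\ddot X_s$, $\ddot Y_s$). Subject mass $M$
and height $H$ scale every segment parameter through a published young-male
regression table (masses $\propto M$, lengths $\propto H$, moments of
inertia $\propto MH^2$); `segment_parameters()` evaluates it and
`composite_inertias()` assembles the lumped moment coefficients.

**Method I (force platform only).** The body above the ankle is one rigid
pendulum. Per sample,
$$\ddot x_b = \frac{-M\ddot X_s - R_x}{m_b}, \qquad
x_b = \frac{(J_b/l_b + m_b(L_f+l_b))\,\ddot x_b + M(L_f+l_b)\ddot X_s + N_y}{m_b g},$$
and analogously in the frontal plane with $R_y$ and $-N_x$ (the moment sign
flips between planes with the right-handed axes). No integration and no
filtering assumptions enter: statics and dynamics are solved exactly within
the model.

**Method II (platform + head IMU).** Sagittally, the body is a double
pendulum (lower body to the hip, upper body above it); frontally, a closed
linkage of two parallel legs, a translating pelvis, and an upper body
rotating about the waist. The head acceleration supplies the extra equation
that separates the two segment accelerations: a time-invariant
$3{\times}3$ system per sample in
$(\ddot x_1, \ddot x_2, x_b)$, factorized once. Besides the COM, the method
yields lower- and upper-body COM accelerations, which distinguish ankle-
from hip-strategy behaviour.

**Baselines.** Method III low-pass filters the COP (zero phase, default
corner 0.5 Hz); Method IV double-integrates the force-derived COM
acceleration with a zero-phase 0.1 Hz high-pass after each integration to
suppress drift. Both are standard literature formulations chosen by this
package — their original variants are not specified sharply enough to
reproduce bit-exactly — with all cutoffs exposed as arguments.

**Kalman fusion.** The displacement observation ($y$) and acceleration
input ($u$) feed a constant-velocity filter
$A = \begin{pmatrix}1&\Delta t\\0&1\end{pmatrix}$,
$b = (\Delta t^2/2, \Delta t)^T$, $c = (1, 0)$, with
$Q_w = \mathrm{diag}(0.0025, 0.04)$ and $Q_v = 1$, the filter operating on
millimetre-scaled signals (so $Q_v$ is 1 mm²; note the filter dynamics
depend only on $Q_w/Q_v$, so the unit is bookkeeping). At 100 Hz the
steady-state position gain is ≈ 0.08. Because the acceleration input is
the force-platform-derived COM acceleration — exact within the model — the
fused output tracks consistent motion with no measurable lag, while
content present only in the observation (for example the moment-equation
artifact during hip strategy) passes with a −41° phase at 1 Hz. The filter
is strictly causal, hence usable online. Initialization is
$\hat x_0 = (y_1, 0)$, $P_0 = \mathrm{diag}(Q_v, 100\,Q_{w,11})$; the
5-s head-cut of the evaluation window absorbs the transient. Non-finite
samples become flagged `NA` gaps with a warning, never silent values.

**Applicability test.** The plate-only method fails exactly when the
motion stops being ankle-strategy-like. `cp_validity()` computes the
correlation $C_p$ between the COP and the method-I COM over the evaluation
window and declares method I valid when $C_p > 0.8$ (threshold
configurable). On the synthetic trials below, ankle-strategy motions give
$C_p \approx 1$ and hip-strategy motions $C_p \approx 0$, so the flag
flips decisively.

## Signal conditioning

Horizontal forces are tiny compared with the vertical load and drift in
practice, so they pass a zero-phase high-pass (default 0.1 Hz) before
inversion. Filters are 8th-order Butterworth designs applied
forward–backward: "zero phase" holds by construction and the magnitude
response is the squared single-pass response. The order is interpreted as
per pass; both order and corner are arguments. Designs are realized as a
cascade of bilinear-transformed second-order sections — a direct
polynomial realization of order 8 at a normalized corner of 0.002 is
numerically unusable — with steady-state section initialization and
odd-reflection padding (three corner periods) so a series needs at least
`3 * ceiling(fs/fc)` samples.

The head IMU delivers specific force and angular rate in sensor axes.
`imu_horizontal_acceleration()` estimates attitude with an error-state
quaternion EKF (tilt + gyro bias). The design leans deliberately toward
the gyro: the accelerometer direction is a poor attitude reference
exactly when the head accelerates, so the measurement noise is set high
(2 m/s² direction noise, inflated 100× whenever the specific-force norm
deviates from gravity by more than 3%), giving a complementary-filter
crossover of a few mHz. The first second of each record must be quiescent;
it provides the gravity magnitude, the initial tilt and the initial bias,
which is why the trial generator holds the first second at rest. Yaw is
unobservable without a magnetometer and irrelevant to the two horizontal
components used here. All of these constants are this package's choices,
not reported facts.

## The synthetic-trial generator

No raw sensor recordings are distributed with the study this package
emulates, so validation rests on a generator whose ground truth is exact.
Six conditions at 40 s / 100 Hz: quiet standing; voluntary ankle-strategy
sway at 0.25 Hz (AP and ML, default amplitude 0.03 rad); voluntary
hip-strategy motion at 1 Hz (AP); and support-surface sway (AP and ML), a
superposition of 20 equal-amplitude harmonics at 0.05–1.00 Hz with
seed-random phases scaled to 10 mm RMS. Joint trajectories are prescribed
(open loop — there is no balance controller, an explicit non-goal), built
from analytic sinusoids/multisines so accelerations are exact, and tapered
by a C³ smoothstep (1 s rest, 2 s ramp) so every trial starts and ends at
rest.

Two generator constants deserve justification:

* **Hip-strategy ratio.** The upper body counter-rotates at twice the
  lower-body angle (`hip_ratio = 2`, lower amplitude 0.01 rad). This
  trunk-dominated counter-rotation keeps the COM excursion at a few
  millimetres while segment accelerations exceed 100 mm/s² — the regime in
  which the single-pendulum method collapses ($C_p \approx 0$) while the
  two-segment method stays sub-millimetre accurate.
* **Quiet-stance composition.** Background sway is a 0.05–1 Hz
  random-phase multisine (1/f amplitudes, 0.003 rad RMS) common to both
  segments, plus a smaller independent upper-body component (0.0015 rad
  RMS, 0.1–2 Hz). Quiet stance is not a pure single pendulum — a faster,
  partly independent hip component is well documented — and without it a
  head sensor could add nothing but noise in quiet standing.

Sensor noise defaults are instrument-realistic: 0.1 N on horizontal
forces, 0.05 N·m on moments, 0.5 N on the vertical force, 0.02 m/s² and
0.002 rad/s on IMU channels, optional force drift ramps and an optional
head-stream synchronization offset (a 20 ms offset measurably inflates the
two-segment method's error on hip trials — the method demands tight
synchronization).

**What the generator does not emulate.** Closed-loop balance control,
triple-segment or out-of-plane dynamics, vertical COM motion, soft-tissue
artifact, and subject-specific deviations from the regression
anthropometry. Passing these tests therefore demonstrates correctness of
the inversions, the fusion and the processing chain under the models'
assumptions — not the field accuracy of the method on a given subject,
which in real use is bounded by body-parameter error.

## The anti-circularity oracle

Linear inverse dynamics (`inverse_dynamics_linear()`) evaluates the same
printed model forms the estimators invert, in a separate code path: on its
output the estimators must recover truth to numerical precision (observed
≈ 1e-15 m), a round-trip test of both codes. Because a shared
misunderstanding could survive that loop, an independent nonlinear
Newton–Euler oracle (`inverse_dynamics_nonlinear()`) computes the exact
planar reaction force and moment about the (possibly accelerating) plate
origin, exact head acceleration and ideal IMU channels, with no
linearization. Its own correctness is audited without reference to the
estimators: linear- and angular-momentum balances against numerically
differentiated exact positions, and a work–energy audit on a conservative
(torque-free) pendulum fall integrated with `deSolve` — on a fixed base
the plate transmits no power, so the kinetic-energy rate must equal the
gravity power. Against this oracle the two-segment estimator's error
scales quadratically with sway amplitude (≈ 1/16 from 2° to 0.5°) and is
far below 1 mm at 1°, quantifying the cost of the small-angle step.

A subtlety worth recording: the tabulated whole-body lever $l_b$ (0.531 H)
and the mass-weighted composition of the segment rows (0.5305 H) disagree
by ~0.1% because the regression coefficients were rounded independently.
The table is used verbatim — the closure error is a property of the
source, not a bug — so the single- and double-pendulum models are not
exactly mutually consistent: method I carries a ~2.5 µm/trial systematic
on two-segment data, and exact method-I round-trips are asserted on
single-model generation. Similarly, the constrained frontal model divides
by $l_b$ where its own geometry composes to 0.455 H; the printed form is
implemented, and its consequence (a sub-millimetre method-I bias on
frontal loop-model data at ankle-strategy amplitudes) is visible in the
benchmark. In the frontal composite inertia the upper-body lever is
$(L_l + l_u)$, which is geometrically correct because the pelvis
translates without rotating — its height contributes no horizontal
displacement.

## Metrics and evaluation protocol

`rmse_windowed()` and `pearson_cc()` score the half-open window
$[5, 35)$ s — exactly 3000 samples at 100 Hz — for displacement (mm),
velocity (mm/s) and accelerations (mm/s²); both metrics are verified
against literal summation loops. The correlation uses the same window as
the RMSE. `evaluate_com()` bundles them; `run_benchmark()` runs the
six-motion, four-method comparison:

```{r benchmark}
b <- run_benchmark(seed = 7)
print(b)
```

The qualitative pattern expected of the methods holds throughout: the
two-segment method is the most accurate model-based estimator on every
motion and the only accurate one under hip strategy; COP filtering is
excellent in quiet standing but is not independent of the COP and fails
under hip strategy; double integration is always the weakest on
displacement; and $C_p$ cleanly separates the conditions where the
plate-only method may be trusted.

## Numerical choices and degenerate inputs

* Evaluation window half-open so the 100 Hz default gives exactly 3000
  samples; for other rates the window is time-based.
* The per-sample $3\times3$ solve reuses one factorization; a condition
  number above 1e12 is rejected with a parameter diagnostic.
* Kalman covariance is re-symmetrized each step; diagnostics expose the
  per-step covariance and gain for the positive-semidefiniteness checks.
* $F_z \le 0$ anywhere invalidates the COP; zero-variance windows make
  correlations an error rather than a silent 0; mismatched grids, missing
  CSV columns and non-uniform timestamps are rejected naming the offender.
* Differentiation is central with second-order one-sided ends; integration
  is trapezoidal from zero initial conditions.
* `g` defaults to 9.81 m/s² and is configurable on `com_subject()`.

## Problem sizes used by the test and acceptance suites

Trials are 40 s at 100 Hz (4001 samples); the oracle momentum audits use
10 s at 500 Hz for differentiation headroom; the covariance property runs
1e5 filter steps; the benchmark covers six motions × both planes × four
methods. These sizes make the whole validation suite run in well under a
minute while leaving every tolerance dominated by method error, not by
sample size.

## Known limitations

The anthropometric table is a young-male regression set: children, elderly
and female subjects need different coefficients, and body-parameter error
is the dominant real-world error source for any equation-of-motion method.
Vertical COM motion (knee/hip flexion) is outside all three models. The
COP baselines stand in for appendix-level formulations that are not
reproducible exactly. The generator's open-loop trajectories cannot test
closed-loop artifacts such as correlation between sensor noise and motion.
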