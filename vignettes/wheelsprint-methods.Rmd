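---
title: "wheelsprint: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheelsprint: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelsprint)
```

This vignette documents the signal models behind `wheelsprint`, the
parameters that matter, and the choices made where the underlying methods
leave room for interpretation. The package analyzes repeated 20 m
wheelchair sprints from four IMUs (left wheel, right wheel, frame, trunk)
sampled at 128 Hz, and ships a synthetic-session generator with analytic
ground truth that the test suite uses for validation.

## Wheel kinematics

### Camber correction

Sport wheelchairs camber their rear wheels by 15–20°. A wheel-hub gyroscope
therefore measures the wheel's spin **plus** a projection of the chassis yaw
rate Ω:

$$\omega_{meas,s} = \omega_{spin,s} + \Omega \sin\gamma_s, \qquad s \in \{L, R\}.$$

We close the system by modelling yaw as differential wheel speed over the
track width $w$ (the no-slip rigid-chassis relation):

$$\Omega = \frac{r_R\,\omega_{spin,R} - r_L\,\omega_{spin,L}}{w}.$$

Substituting gives a constant 2×2 linear system in the two spins, solved
per sample (`correct_camber()`). With zero camber the correction is exactly
the identity. The determinant is checked against 1e-8; geometries that make
spin unidentifiable raise a diagnostic error.

Two consequences of this model are worth stating. First, it is *exact*
whenever the chassis yaw really is produced by differential wheel rolling —
which is also how the generator injects yaw, so the round-trip
velocity → contaminated gyro → correction → velocity is exact to machine
precision and is tested at 1e-6 m/s with an 18° camber and a 0.5 rad/s yaw
wobble. Second, yaw produced by wheel *slip* (e.g. a skidding pivot) is
outside the model: for a slip-pivot with both wheels stationary the
corrected spin equals $\Omega\sin\gamma$, not zero. The protocol minimizes
slip physically (cleaned track, wiped tyres), so we accept this limit.

### Sprint window and cycles

The start is the first sample where the mean of the two wheel speeds
exceeds **0.06 m/s**; the end is the first sample where the trapezoidal
integral of that mean reaches the track length (20 m). As a precondition
the chair must be at rest beforehand: the mean speed over the 0.5 s
preceding the detected crossing must stay below the threshold, otherwise
the stream evidently starts mid-movement and an error is raised. Detected
distance exceeds the nominal track length by less than one sample's travel;
`V_mean` is defined as track length over duration so that
`V_mean × sprint_time = 20` holds exactly.

Propulsion cycles are local minima of the mean wheel speed within the
window, guarded by a minimum spacing of **0.25 s** (no athlete strokes
above 4 Hz) and a minimum topographic prominence of **2 %** of the window's
velocity range (rejects noise dimples). Both guards are exposed in
`analysis_config()`. Cycle windows follow the start/middle/end convention:
first 3 cycles, last 5 cycles, remainder in between. At least 8 cycles are
required; with exactly 8 the middle window is empty and middle-window
metrics are `NA`. A cycle runs from one onset to the next; the final cycle
runs from the last onset to the sprint end and is therefore usually
truncated by the finish line — its shortened trunk excursion is real, not
an artifact, and both the analysis and the generator's ground truth share
this definition.

## Dynamics

Velocity over the sprint window is fitted by a least-squares 4th-degree
polynomial $pV(x) = p_1x^4 + \dots + p_5$ with $x$ the time since sprint
start. Time (not distance) is the fitting abscissa because acceleration is
then the analytic derivative of the fit — the point of the polynomial is to
smooth intra-stroke fluctuation out of the acceleration estimate rather
than differentiating noisy samples. Force and power follow

$$F_{IMU} = m_t\,acc + m_t g(\mu_r + k_f\,pV^2) + \tfrac12 \rho\, C_dA\, pV^2,
\qquad P_{IMU} = F_{IMU}\cdot pV,$$

with $\rho = 1.22$ kg/m³ and $k_f = 0$ by default ($k_f$ is rarely
reported; the generator's coast-down ODE honours a nonzero $k_f$, so the
estimator's bias under $k_f \ne 0$ is measurable if desired).

The rolling-resistance coefficient comes from two coast-down trials in
opposite directions: per trial, the OLS slope of the wheel-derived speed
over the interval from 0.5 s after the push to 0.5 s before the stop; the
magnitudes are averaged and divided by $g$. Averaging opposite directions
cancels any direction-antisymmetric bias such as a track grade (tested with
an injected 0.4 % slope). Fewer than 1.0 s of coast after trimming raises
an "insufficient coast data" error. Two caveats are inherent to the field
method and deliberately preserved: the estimate absorbs low-speed
aerodynamic drag (with the default CdA of 0.4 m² the session-level
estimates sit roughly 10–15 % above the generator's true μ_r), and the
subsequent force model then counts a small part of drag twice. The
recovery tests therefore use drag-free trials (CdA = 0), where the
estimator is exact to within discretization (2 % tolerance, and 10 % under
0.05 rad/s gyro noise).

## Symmetry

The Instantaneous Symmetry Index on left/right wheel velocity,

$$ISI = \frac{\int_{t_1}^{t_2} |R - L|\,dt}
             {\int_{t_1}^{t_2} |R|\,dt + \int_{t_1}^{t_2} |L|\,dt},$$

is computed with trapezoidal integrals; window bounds snap to the nearest
sample (sub-sample interpolation would change the value by less than one
sample period and is not worth the complexity). ISI is computed on
camber-corrected *per-wheel* velocity, never on the polynomial fit — the
fit is chair-level and would destroy exactly the left/right detail the
index measures. Closed forms anchor the tests: identical traces give 0,
proportional traces with ratio $g$ give $(g-1)/(g+1)$, a one-sided trace
gives 1, and both-zero windows raise an "undefined ISI" error rather than
returning 0/0. Trapezoidal ISI at 128 Hz is checked against a 16×
oversampled oracle to 1e-4.

## Trunk kinematics

Trunk orientation quaternions are converted to rotation matrices and
decomposed in an intrinsic **y-z-x** Euler sequence,
$R = R_y(a) R_z(b) R_x(c)$. Flexion is the *first* angle $a$ — the rotation
about the mediolateral (pitch) axis, i.e. anteroposterior inclination
relative to the global earth frame; the sequence's remaining angles absorb
axial rotation and lateral lean. Which of the three angles is "flexion" is
a mapping choice; pitch-first is the only one consistent with
anteroposterior inclination. Samples whose middle angle comes within 0.5°
of ±90° are flagged (gimbal proximity); angles are unwrapped before any
max/min statistic to avoid ±180° artifacts.

The static offset is formalized as the mean flexion over a still-sitting
window preceding the sprint (the field protocol's visual assessment has no
numeric recipe). Stillness is enforced: more than 2° of flexion range
within the static window raises an "athlete not still" error. TRM is
max − min flexion per propulsion cycle, averaged per window; the cycle
windows deliberately reuse the ISI windows (first 3 / middle / last 5),
the only reading consistent with reporting both families side by side.
TRM is invariant to the offset correction by construction, and the
quaternion → flexion round-trip is tested at 1e-6°.

## The synthetic-session generator

The generator is first-class, tested code. Per sprint it builds a chair
velocity

$$v(t) = v_{max}\,d^{\,s-1}\left(1 - e^{-t/\tau}\right) + \text{ripple}(t),$$

with $d$ the per-sprint fatigue decay and the ripple a rectified sinusoid
at the stroke frequency, zero-mean within a stroke. Parameter choices, each
made once for realism:

| parameter | default | rationale |
|---|---|---|
| `sample_rate_hz` | 128 | the protocol's IMU rate |
| `track_length_m` / `recovery_s` / `n_sprints` | 20 / 20 / 6 | the sprint protocol |
| `v_max_true` | 4.5 m/s | between elite WB (~5.4) and WR (~4.4) peak speeds |
| `tau_s` | 1.6 s | yields ~6 s sprint times, bracketing WB (~5.5 s) and WR (~6.6 s) |
| `stroke_freq_hz` | 1.8 | typical sprint push rate |
| `ripple_depth` | 0.12 | ~0.5 m/s peak-to-trough intra-stroke fluctuation at plateau, as seen in measured traces; the first strokes carry ~1.8× deeper dips (pushes from near-rest), decaying within ~1.5 strokes |
| `camber_rad` | 18° | sport-chair range |
| `asymmetry_gain` | 1.03 | overall ISI ≈ 0.015, the reported magnitude |
| `start_asym_boost` | 2 | start-window ISI ≈ 2× mid-sprint, the reported pattern |
| `fatigue_decay` | 0.99 | ~5 % plateau loss over 6 sprints |
| `mu_r_true` / `CdA_true` | 0.012 / 0.4 m² | typical hard-court rolling resistance and seated frontal drag area |
| `trunk_amplitude_deg` | 10° | per-cycle TRM of 20°, between WB (~26°) and WR (~15°) |
| `noise_sd_gyro` | 0.02 rad/s | consumer-IMU rate noise |
| `yaw_oscillation_amp` | 0 | steering wobble off by default; enabled explicitly in tests |

Asymmetry in gain mode scales the two wheels to a constant ratio $g$ at
preserved mean (so detection sees the unperturbed chair speed and the
ground-truth ISI is exactly $(g-1)/(g+1)$); phase mode shifts the right
wheel's ripple by a cycle fraction at equal means, exercising ISI's
sensitivity to timing. The optional yaw wobble is injected as an
antisymmetric perturbation of the two wheel speeds, keeping the generator
kinematically consistent with the camber-correction model. The frame
stream receives the true forward acceleration plus random-walk drift and
20 Hz vibration — it emulates why frame-based velocity integration is
unreliable and is generated but never used by the pipeline.

Ground truth is computed on the noise-free traces *by the same
definitions* the pipeline uses (same threshold detection, same trapezoidal
ISI integrals, same cycle convention), so recovery tests compare like
with like.

What the generator does **not** emulate: wheel slip, curved trajectories
beyond the small yaw wobble, physiological fatigue structure
(within-sprint power fade, stroke-frequency drift), orientation-filter
error in the trunk quaternions, and sensor dropout. Passing recovery tests
therefore validate the pipeline's algebra and signal processing, not its
robustness to every artifact of real recordings.

## The report stage

`group_report()` produces the mean (SD) table per variable × group ×
condition and a thin inferential stage: Shapiro–Wilk on the two-way model
residuals and Levene's test route each variable to a two-way ANOVA
(group × condition) or to Kruskal–Wallis per factor; pairwise contrasts
are Bonferroni-corrected; significance markers use two tiers (p < 0.05,
p < 0.001). Groups with a single session get descriptives only. Simulation
tests check both error behaviours: identical-distribution groups are
flagged in well under 10 % of 100 replicates, and 5-SD-separated groups are
always flagged at the stricter tier. A mixed-effects sprint-trend fit
(`lme4`, random intercept per athlete) is provided as an optional
convenience; nothing else depends on it.

Problem sizes throughout the tests and the acceptance script are one
session to a dozen sessions of six ~6 s sprints at 128 Hz — a few thousand
samples per stream — which the full suite processes in seconds.

## Known limitations

- The camber correction assumes yaw from differential rolling; slip-driven
  yaw leaks into spin at $\sin\gamma$ attenuation.
- μ_r from coast-downs absorbs low-speed drag and interacts with the
  explicit aerodynamic term (double counting of a small component), as in
  the field method it implements.
- The quartic velocity model can deviate near the window endpoints
  (unconstrained polynomial ends); with realistic ripple amplitudes the
  V_max bias stays within ~1.5 %.
- The final propulsion cycle is truncated by the finish line; end-window
  TRM is accordingly conservative.
- `V_mean` is defined as track length over duration; alternative
  definitions (e.g. mean of the fitted polynomial) differ at the percent
  level.
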