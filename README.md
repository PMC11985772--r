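# wheelsprint

Analysis pipeline for repeated **20 m manual-wheelchair sprint tests**
recorded with inertial measurement units (IMUs) on the two rear wheels, the
frame and the athlete's trunk. It is aimed at sport scientists working with
wheelchair court-sport athletes (basketball, rugby) who want field-based
measures of sprint performance, propulsion asymmetry and trunk involvement
from wearable sensors alone — no instrumented wheels, force plates or motion
capture.

## What it computes

**Wheel kinematics with camber correction.** A cambered wheel's gyroscope
measures wheel spin plus a projection of the chassis yaw rate,
ω_meas = ω_spin + Ω·sin(γ). With yaw tied to the differential wheel speed,
Ω = (r_R ω_R − r_L ω_L)/w (track width w), the two measured signals form a
2×2 linear system solved per sample for the true spins; linear speed is
v = ω_spin·r. The sprint **start** is the first sample where the average
wheel speed exceeds 0.06 m/s; the **end** is where its trapezoidal integral
reaches 20 m. Propulsion cycles are local minima of the averaged speed.

**Force–velocity–power profile.** The averaged speed over the sprint window
is fitted with a 4th-degree polynomial pV(x) = p₁x⁴ + p₂x³ + p₃x² + p₄x + p₅
(x = time from sprint start), and propulsive force follows Newton's second
law:

    F_IMU = m_t·acc + F_rr + F_aero
    F_rr  = m_t·g·(μ_r + k_f·pV²)
    F_aero = ½·ρ·CdA·pV²
    P_IMU = F_IMU·pV

with acc the analytic derivative of pV. The rolling-resistance coefficient
μ_r is estimated from two coast-down (deceleration) trials in opposite
directions: OLS slope of the wheel-derived speed between 0.5 s after the
push and 0.5 s before the stop, averaged, divided by g.

**Instantaneous Symmetry Index (ISI).** On left/right wheel velocity,

    ISI = ∫|R − L| dt / ( ∫|R| dt + ∫|L| dt )

over a window (0 = perfect symmetry, 1 = one-sided), evaluated over the
first three propulsion cycles (start), the last five (end), the cycles in
between (middle), and the whole sprint.

**Trunk range of motion (TRM).** Trunk flexion is extracted from the trunk
IMU's quaternions via a y-z-x Euler decomposition (pitch about the
mediolateral axis), corrected by the mean over a still-sitting window, and
summarized as max − min flexion per cycle, averaged per window.

**Synthetic sessions with ground truth.** A generator emulates the full
protocol (6 × 20 m sprints, 20 s recovery, 128 Hz, coast-down trials):
saturating-exponential velocity envelope with per-stroke ripple,
gain/phase-mode bilateral asymmetry with optional start enhancement,
per-sprint fatigue decay, camber-contaminated gyros, noisy drifting frame
accelerometer, and quaternion-encoded trunk oscillation — everything with
analytically known truth, which the test suite uses for parameter-recovery
validation.

## Worked example

```r
library(wheelsprint)

cfg <- sim_config(seed = 42, fatigue_decay = 0.97)   # WR-like fatiguing session
ses <- generate_session(cfg)
sa  <- analyze_session(ses)                          # mu_r from coast-downs, then per-sprint pipeline
round(sa$metrics[, c("sprint", "V_max", "P_max", "sprint_time",
                     "isi_start", "isi_middle", "isi_end", "trm_start")], 3)
#>   sprint V_max   P_max sprint_time isi_start isi_middle isi_end trm_start
#> 1      1 4.460 301.860       5.977     0.023      0.015   0.015    19.993
#> 2      2 4.227 282.508       6.125     0.023      0.015   0.015    19.993
#> 3      3 4.110 266.921       6.258     0.021      0.015   0.015    19.995
#> 4      4 4.067 252.976       6.406     0.023      0.015   0.015    19.993
#> 5      5 3.954 238.593       6.555     0.023      0.015   0.015    19.993
#> 6      6 3.775 224.463       6.719     0.023      0.015   0.015    19.993

sa$mu_r_est
#> [1] 0.0135      # truth 0.012; the coast-down method absorbs low-speed drag

summarize_session(sa$metrics, "WR")
#> <session_summary> 6 sprints  ST = sprint 1 (5.98 s)  LT = sprint 6 (6.72 s)

sa$metrics$V_max[6] / sa$metrics$V_max[1]
#> [1] 0.846       # fatigue decay 0.97 per sprint -> 0.97^5 = 0.859
```

Maximal velocity declines monotonically at the configured fatigue rate, the
start window shows elevated asymmetry (0.023 vs 0.015 mid-sprint), per-cycle
trunk range recovers the generator's 2 × 10° oscillation, and the fastest
sprint is the first — the pattern expected of a fatiguing rugby-style
session.

## Cohort workflow

The `analysis/` scripts run the same pipeline as a small simulated study:

```sh
Rscript analysis/01_simulate_sessions.R   # 6 WB-like + 6 WR-like sessions -> scratch/sessions/
Rscript analysis/02_rolling_resistance.R  # per-session mu_r -> results/rolling_resistance.csv
Rscript analysis/03_sprint_metrics.R      # per-sprint metrics -> results/sprint_metrics.csv
Rscript analysis/04_group_report.R        # WB-vs-WR and sprint-1-vs-6 tables -> results/group_report_*.csv
```

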