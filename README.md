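# gaitaccel

Acceleration decomposition for shank-mounted inertial sensors.

## The problem

Accelerometers worn on the lower leg are an attractive basis for portable
gait assessment, but their raw output mixes several physically distinct
signals: gravity (which moves through the sensor axes as the shank tilts),
centrifugal and tangential accelerations produced by knee rotation, and the
translational acceleration of the knee-joint centre itself, which reflects
the motion of more proximal body segments. Gait evaluation based on "the
acceleration of walking" needs these contributions separated.

`gaitaccel` implements that separation for a 9-axis IMU (3-axis gyroscope,
accelerometer, magnetometer) strapped to the shank. The accelerometer output
is modelled as

```
A = A_tra + A_cen + A_tan + A_col + g_i
```

with, for a sensor at offset **r** from the knee-joint centre rotating at
body rate **ω**:

* `A_cen = ω × (ω × r)` — centrifugal, from the gyroscope;
* `A_tan = ω̇ × r` — tangential, with `ω̇` from the band-limited
  differentiator `D(s) = s / (1 + n s)`, `n = 0.01` s;
* `g_i = R0ᵀ g_o` — gravity projected into the sensor frame by the transpose
  of the body-to-reference rotation `R0 = Rz(ψ) Ry(θ) Rx(φ)`,
  `g_o = (0, 0, 9.8)` m/s²;
* `A_col = 2 ω × ṙ = 0` — Coriolis, zero because **r** is fixed;
* `A_tra = A − (A_cen + A_tan + g_i)` — translational, the remainder, so the
  identity holds to machine precision on every sample.

The pose trajectory `(φ, θ, ψ)` needed for the gravity term is estimated by
an extended Kalman filter that integrates the Euler-angle kinematics with
the gyroscope and corrects with two observations per sample: the
tilt-compensated magnetometer heading and the accelerometer compared against
pure gravity. Both noise covariances adapt to the sensor output
(`Ω_ω = a|ω|² + b`, `Ω_m = c(|m_c|² − m̄) + d`,
`Ω_a = e(Ax² + Ay² + (Az − g)²) + f`), so the filter automatically distrusts
the accelerometer when the leg is accelerating and the magnetometer when the
field is disturbed. The six coefficients can be tuned per record by
maximising the innovation log-likelihood.

Components are then summarised the way gait studies report them: cycles cut
at foot contact, stance and swing separately time-normalised onto a 0–100%
grid anchored at the average toe-off percentage, ensemble mean ± SD across
cycles, and per-phase Pearson correlations and RMSEs between channels.

A synthetic gait simulator with closed-form kinematics (sagittal-dominant
hip/knee Fourier series, 90 steps/min, exact analytic derivatives) provides
ground truth for every stage, so the whole pipeline is testable without
recordings.

## Worked example

```r
library(gaitaccel)

# 10 gait cycles at 90 steps/min after a 5 s standing lead-in
sim <- simulate_gait_imu(gait_model_params(seed = 1))
sim$imu
#> <imu_series> 1997 samples @ 100 Hz (19.97 s)
#>   gyro  rms: 1.392 rad/s   accel rms: 6.692 m/s^2

poses <- run_pose_estimation(sim$imu, calibration_window = 5)
poses
#> <pose_series> 1997 samples @ 100 Hz
#>   roll  [ -56.48,   23.59] deg
#>   pitch [  -2.08,    3.08] deg
#>   yaw   [  -3.21,    3.15] deg

comp <- decompose_acceleration(sim$imu, poses, sensor_geometry())
comp
#> <accel_components> 1997 samples; identity residual 3.55e-15 m/s^2
#>   grav rms:  5.658 m/s^2
#>   cen  rms:  1.465 m/s^2
#>   tan  rms:  2.918 m/s^2
#>   tra  rms:  1.334 m/s^2

# recovery against the simulator's exact translational component
err <- comp$tra[-comp$transient, ] - sim$components$tra[-comp$transient, ]
round(sqrt(colMeans(err^2)), 3)
#>     x     y     z
#> 0.079 0.119 0.060

normalize_to_gait_cycle(comp$tra, sim$truth$t, sim$truth$events)
#> <gait_ensemble> 10 cycles x 101 grid points, 3 channel(s); toe-off 60.0%
```

The roll range of about −56° to +24° is the sagittal shank swing (the
dominant gait rotation); pitch and yaw stay within a few degrees. The
decomposition identity residual is at floating-point level by construction,
and the translational component recovered through the estimated pose is
within ~0.1 m/s² RMSE of the simulator's ground truth — gravity is the
largest component (5.7 m/s² rms) and mis-projecting it by a degree would
already cost ~0.17 m/s².

A shell front end wrapping the same functions is installed at
`inst/scripts/gaitaccel` with subcommands `simulate`, `tune`,
`estimate-pose`, `decompose`, `gait-cycle`, `stats` and `run`
(`run_pipeline()` in R), all driven by a YAML config plus CLI overrides.

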