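---
title: "Decomposing shank accelerometer signals: models, tuning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing shank accelerometer signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind its functions:
the measurement model, the estimator, the choices we made where the design
was genuinely open, and what the validation on synthetic gait does and does
not establish.

## The measurement model

A 9-axis IMU is strapped to the shank, a rigid offset **r** from the
knee-joint centre (defaults `r = (0, -0.05, -0.2)` m in sensor coordinates:
x lateral, y anterior, z along the shank). For a rigidly attached sensor the
accelerometer output decomposes as

$$A = A_{tra} + A_{cen} + A_{tan} + A_{col} + g_i,$$

where $A_{cen} = \omega \times (\omega \times r)$ and
$A_{tan} = \dot\omega \times r$ follow from the gyroscope,
$g_i = R_0^\top g_o$ is gravity in sensor coordinates, and the Coriolis term
$A_{col} = 2\,\omega \times \dot r$ vanishes because $r$ is constant. The
type retains the Coriolis field anyway, so the modelling assumption is
visible and the conservation check
$g_i + A_{cen} + A_{tan} + A_{tra} + A_{col} = A$ is explicit; it holds to
machine precision because $A_{tra}$ is defined as the remainder. The
scientific content of $A_{tra}$ therefore hinges entirely on how well the
other three terms are estimated.

Angles are radians in memory and degrees at every file boundary. The
reference frame is chosen so that $g_o = (0, 0, +9.8)$ m/s² and a sensor at
the calibration pose reads $A = (0, 0, 9.8)$: with the rotation convention
below, this makes the static case self-consistent. The gravity constant is
configurable.

### Rotation convention

$R_0 = R_z(\psi) R_y(\theta) R_x(\varphi)$ maps sensor (body) coordinates to
the reference frame; reference-frame vectors (gravity, the magnetic field)
are brought into the sensor frame by $R_0^\top$, giving
$g_i = g(-\sin\theta,\ \sin\varphi\cos\theta,\ \cos\varphi\cos\theta)$.
Descriptions of $R_0$'s direction vary in the literature; we fix the
convention by requiring consistency between the gravity projection and the
accelerometer-based tilt initialisation at rest, which only this reading
satisfies.

### The gyroscope differentiator

$\dot\omega$ comes from the band-limited differentiator
$D(s) = s/(1 + n s)$ with time constant $n = 0.01$ s, discretised by the
bilinear (Tustin) transform at the record's sampling interval. At 100 Hz the
bilinear map reproduces the analogue gain to ~0.03% across the gait band
(< 10 Hz); forward-Euler discretisation would be several times worse at the
higher harmonics. The filter is causal: we initialise it as if the input had
been constant before the first sample (no start-up spike), flag the first
$\lceil 5n/\Delta t \rceil$ samples as transient, and — inside
`decompose_acceleration()` only — advance the output by
$\mathrm{round}(n/\Delta t)$ samples to cancel the filter's ≈ *n*-second
group delay. The advance cancels the phase lag to third order in
$\omega n$, leaving the second-order gain droop
$\tfrac12(\omega n)^2$ as the dominant residual; at the stride fundamental
(0.75 Hz) that is ~0.1%. The raw `differentiate_gyro()` output is left
causal and unshifted, which is what the frequency-response tests check.

## Pose estimation

The state is $(\psi, \theta, \varphi)$ (yaw, pitch, roll). The state
equation is one forward-Euler step of the Euler-rate kinematics driven by
the gyroscope; the 4-dimensional observation is the tilt-compensated
magnetometer heading plus the three accelerometer axes compared against
pure gravity. Both models are linearised analytically (`compute_jacobians()`
matches central finite differences to 1e-9 in the tests).

Initialisation averages a standing window (default 5 s, the protocol's
standing lead-in): roll and pitch from the two-argument arctangent of the
averaged accelerometer, yaw from the tilt-compensated averaged magnetometer.
Two-argument arctangents are used throughout — the stated $(-\pi, \pi)$
ranges force quadrant awareness. The initial covariance is
$P_0 = \mathrm{diag}((10°)^2, (5°)^2, (5°)^2)$ in (yaw, pitch, roll): the
accelerometer pins tilt to a few degrees at rest, while the heading depends
on the local field and is allowed twice the uncertainty.

Numerical safeguards: the innovation's yaw component is wrapped to
$(-\pi, \pi]$; the updated covariance is re-symmetrised each step; pitch is
clamped at 89° inside sec/tan evaluations with a logged warning (shank pitch
in gait stays far from gimbal lock, so the guard exists for corrupt inputs,
not normal operation); all adaptive variances are floored at
$\varepsilon = 10^{-9}$, with floor hits counted in the diagnostics.

### Adaptive noise covariances

The process noise is $\Omega_\omega = a\,|\omega|^2 + b$ on all three state
axes, and the observation noise is
$\Omega_m = c\,(|m_c|^2 - \bar m) + d$ for the heading and
$\Omega_a = e\,(A_x^2 + A_y^2 + (A_z - g)^2) + f$ for the accelerometer
channels. $\bar m$ is the time-average of the squared magnetometer norm over
the record; since the tilt-compensation matrix is a rotation, the corrected
and raw norms are identical, which resolves any ambiguity about which norm
to average. An undisturbed field then gives $\Omega_m = d$ exactly.

Defaults (`a = 1e-7`, `b = 1e-8` rad²; `c = 0.1`, `d = 0.01` rad²;
`e = 100`, `f = 0.05` (m/s²)²) encode three design rules, fixed once in a
design study on the synthetic conditions:

1. **Trust the gyroscope.** Gait rotation is fast and the gyro is the only
   sensor unaffected by motion acceleration; `a`, `b` are small so the
   filter's short-horizon memory is the integral of the gyro.
2. **Down-weight the accelerometer sharply during dynamics.** With
   `e = 100`, a 1 m/s² departure of the accelerometer norm from gravity
   already inflates $\Omega_a$ to 100 (m/s²)², so swing-phase motion
   acceleration barely perturbs the tilt estimate, while quiet-stance
   samples (deviation ~0) are trusted at `f`.
3. **Keep the heading variance safely positive.** $\Omega_m$ can go negative
   whenever the measured field magnitude dips below its average; if that
   happens systematically (field fluctuations larger than $d/c$), the floor
   engages, the filter treats the heading as near-exact, the yaw covariance
   collapses, and the roll/yaw cross-gains explode — a failure mode we
   observed directly. With `c = 0.1`, `d = 0.01`, magnitude fluctuations up
   to ~10% of the field keep $\Omega_m > 0$ without flooring.

### Likelihood-based tuning, and its limits

`tune_noise_parameters()` maximises the multivariate innovation
log-likelihood
$LL = -\tfrac{Nd}{2}\ln 2\pi - \tfrac12 \sum_j (\ln\det B_j + V_j^\top
B_j^{-1} V_j)$ over $(a, \ldots, f)$, using a derivative-free Nelder–Mead
simplex on the logarithms of the coefficients (positivity by construction),
with a 500-evaluation budget and one restart from a deterministically
perturbed best point. The printed scalar form of the likelihood is the
per-dimension special case of this expression for diagonal $B$; the
multivariate form is its only consistent generalisation to the
4-dimensional observation. All six coefficients are tuned jointly — nothing
in the method requires a staged order, and the simplex handles the
6-dimensional surface directly. The returned parameters never score below
the starting point (monotone-acceptance contract), and on records with
realistic sensor noise the result is locally optimal against ×10
perturbations of each coefficient.

One caveat belongs in the open. The observation model says "the
accelerometer measures gravity", which during walking is false by several
m/s². Innovation-likelihood tuning rewards predicting the *observations*,
and on high-dynamics records its optimum makes the filter chase the
accelerometer (small `f`): innovations whiten, the likelihood rises by
thousands of nats, and the *pose* error grows several-fold. This is the
textbook behaviour of ML innovation tuning under model misspecification,
not an implementation defect; on quasi-static records, where the model is
correct, the tuned process noise tracks the true gyro noise level (the test
suite demonstrates both regimes). For accuracy-critical use we therefore
recommend the physical defaults, with tuning reserved for records whose
noise environment genuinely differs from the MEMS assumptions — and the
package's own accuracy validation uses the defaults.

## Gait-cycle analysis

Cycles run from foot contact to the next foot contact of the same leg. Each
cycle's toe-off is expressed as a percentage, the average toe-off percentage
anchors the grid, and stance and swing are *independently* linearly
resampled onto $[0, \overline{TO}]$ and $(\overline{TO}, 100]$ — so the
stance/swing boundary is aligned across cycles before averaging, at the
cost of slightly non-uniform within-phase time scaling. The grid has 101
points (1% resolution), comfortably above the ~15 harmonics that carry gait
signal content. Ensemble spread uses the sample (n−1) standard deviation; a
single-cycle ensemble reports SD 0 with a warning rather than NaN.

Phase statistics (Pearson r, RMSE) are computed per cycle over the grid
points of a window and then summarised as mean ± SD across cycles, matching
the reporting convention of gait studies. Stance and swing windows default
to the toe-off split; sub-phases (initial/mid/terminal swing) have no
universally agreed numeric boundaries, so they are configurable windows
rather than package constants. A channel that is constant within the window
yields an undefined correlation, reported as NA with a warning.

The event detector is a convenience for records without annotations: it
verifies periodicity in the 0.5–2 Hz band (autocorrelation), standardises
polarity so the mid-swing extremum is positive, finds the per-cycle swing
peaks, and takes the flanking minima as toe-off (before) and foot contact
(after). External annotation files always take precedence in the pipeline.

## The synthetic gait model

The simulator exists to provide *exact* ground truth, so it is built from
closed-form, analytically differentiated primitives; no numerical
differentiation enters the truth. Euler angles are truncated Fourier series
over the cycle (roll = thigh angle − knee flexion; small pitch/yaw terms
exercise the out-of-plane axes), body rates follow from the exact inverse
Euler-rate map, and the knee-centre path is pelvis translation (forward
progression at 1.1 m/s plus vertical/lateral oscillation) plus the
thigh-segment swing. Defaults: cadence 90 steps/min (cycle 4/3 s), 10
steady cycles after a 5 s standing lead-in and a one-cycle C² smoothstep
amplitude ramp, knee flexion peaking near 60° at ~70% of the cycle, stance
fraction 60%. The hip/knee coefficients were fit once to the canonical
curve shapes under the additional requirement that the shank
angular-velocity landmarks (mid-swing peak, flanking troughs) fall at their
physiological positions relative to the declared events — without that, the
waveform and the event labels would contradict each other and no detector
could satisfy both. Sensor synthesis then applies the measurement model
exactly (so the component identity holds by construction), optionally
adding seeded Gaussian noise and a constant gyro bias; identical parameters
and seed give bit-identical records.

What the simulator does **not** emulate: heel-strike impact transients and
soft-tissue artefact (real shank accelerations have sharp spikes the smooth
Fourier model cannot produce), magnetic disturbances, double-support
asymmetries, stride-to-stride variability, and sensor scale-factor or
misalignment errors. Passing the recovery tests therefore establishes the
*correctness of the mathematics* — pose propagation, projection,
differentiation, bookkeeping — under the stated model, not field
performance on clinical recordings; the pose accuracies on real walkers
reported with optical references (a few degrees) are about 3–5× worse than
on our noiseless synthetic gait, which is the expected gap between a
model-consistent simulation and reality.

## Validation problem sizes

The shipped tests run the default conditions (10 cycles, ~2000 samples) for
recovery checks, a 60 s static record for drift, 1000-case random oracles
for the algebraic identities, 200 cases for the Jacobians, and 2-cycle
records with a 300-evaluation budget for the tuning contract — sizes chosen
so the whole suite exercises every claim in a few minutes on one core while
keeping every tolerance far from its failure point.

## Known limitations

* $A_{tra}$ inherits every error in the other components; with estimated
  poses its error budget is dominated by the gravity projection
  (~0.17 m/s² per degree of tilt error).
* The gravity-only observation model biases the filter during sustained
  accelerations; the adaptive $\Omega_a$ mitigates but cannot eliminate
  this, and ML tuning can amplify it (see above).
* Euler kinematics are ill-conditioned near ±90° pitch; the guard makes
  this safe, not accurate. Shank mounting keeps gait far from it.
* The event detector assumes sagittal-dominant walking; running, stairs or
  severely pathological gait need external annotations.
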