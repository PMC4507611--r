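---
title: "Methods: instrumented trunk endurance assessment with trunkdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumented trunk endurance assessment with trunkdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkdx)
library(dplyr)
```

`trunkdx` covers the full analytical path of an instrumented trunk
endurance assessment: raw inertial samples → trunk angle → timed test with
automatic termination → EMG fatigue indices → normative category and
ratios → inter-method agreement statistics. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Orientation estimation

Attitude is a unit quaternion $(q_1, q_2, q_3, q_4)$ (scalar first).
Each sample the filter blends two information sources:

1. **Gyroscope integration.** $\dot q_\omega = \tfrac12\, q \otimes
   (0, \boldsymbol\omega)$ with $\boldsymbol\omega$ in rad/s in the sensor
   frame, integrated with a first-order step and renormalization. The
   per-step angle error of this scheme is $O((\omega\,\Delta t)^3)$, which
   at 51.2 Hz and physiological rates is far below the 0.1° the tests
   require.
2. **Gradient-descent field correction.** The normalized accelerometer
   reading is compared with the sensor-frame prediction of the vertical
   (at rest the accelerometer reads the $+g$ reaction, $g = 9.80665$
   m/s²); when the magnetometer is enabled, the measured field is compared
   with a reference whose east component is zeroed from the current
   estimate, so the magnetometer constrains *heading only* — roll and
   pitch, hence the trunk angle, never depend on it. The stacked residual
   gradient is normalized and applied with gain $\beta$:
   $\dot q = \dot q_\omega - \beta\, \nabla f / \lVert\nabla f\rVert$.

**Gain $\beta$** (dimensionless, default 0.1): the normalized gradient
step corrects at most $\beta\,\Delta t$ rad per sample, so at 51.2 Hz the
default converges from a 30° initial error in roughly 5 s and leaves a
static limit cycle of ≈ 0.1°, comfortably inside the 0.5° static accuracy
the tests need. $\beta = 0$ degenerates to pure gyro integration, which is
what the unit tests exploit as a closed-form oracle.

**Euler convention.** Angles are the aerospace Z-Y-X sequence
(yaw–pitch–roll), with roll $\in(-180°, 180°]$ and pitch clamped into
$[-90°, 90°]$ by bounding the arcsine argument to $[-1, 1]$ — near gimbal
lock the conversion degrades gracefully rather than erroring; the fusion
state itself is a quaternion and is singularity-free. The roll angle is
the trunk angle for every protocol, and because the session layer works
with the *absolute deviation* from a reference, the sign convention of
roll cannot change any test outcome.

**Timing.** $\Delta t$ comes from consecutive stream timestamps, falling
back to $1/51.2$ s for the first sample or any non-positive difference.
All session timing uses the same stream clock, never the wall clock, so
results are reproducible offline.

**Degenerate inputs.** A zero-norm or non-finite accelerometer (or
magnetometer) sample disables that correction for the affected update
only; gyro integration continues and the output stream keeps one angle per
input sample.

## EMG fatigue indices

For an epoch of $N$ samples $EMG(k)$ in mV:

$$\mathrm{RMS} = \sqrt{\tfrac1N \sum_k EMG^2(k)}, \qquad
  \mathrm{ARV} = \tfrac1N \sum_k |EMG(k)|, \qquad
  \mathrm{MVC} = \max_k |EMG(k)|.$$

The maximum is taken over the *rectified* trace by default: surface EMG is
zero-mean, and a raw maximum would ignore a strongly negative-going burst;
`rectify = FALSE` restores the plain maximum. With the rectified
convention $0 \le \mathrm{ARV} \le \mathrm{RMS} \le \mathrm{MVC}$ holds by
the power-mean inequality, and all three indices are invariant to a sign
flip of the signal.

Epochs are consecutive and non-overlapping; the default epoch length is
1 s, a round figure that gives ≈ 51 samples per epoch (≈ 10% relative
sampling error on an epoch RMS — visible in the tests' tolerances). A
trailing partial epoch is kept only when at least half full. Whole-test
summaries (`emg_summary()`) are always available as well, since a clinical
results screen reports single per-test RMS/ARV/MVC values; whole-test
RMS² equals the count-weighted mean of epoch RMS² when the epochs
partition the samples. No band-pass filtering or detrending is applied —
the indices operate on the recorded trace as stored; an optional
whole-stream mean subtraction (`demean = TRUE`, default off) removes DC
offset when an acquisition chain leaves one.

## The endurance-test state machine

Each protocol fixes a droop tolerance (10° for STEET and both SBET sides,
30° for TCSET), a 240 s cap, and an attempt count (two for STEET, one
otherwise). The operator's start event is an *input timestamp*, not an
auto-detected posture: starting the test is a clinical judgement. The
angle at (or at the nearest sample preceding) the start event becomes the
reference.

An attempt terminates at the first sample where

* the operator's stop event has passed (`manual_stop`), else
* $|\phi - \phi_{ref}| > $ tolerance — *strictly* greater, matching a
  "more than ±tolerance" criterion, with the deviation computed on the
  shorter arc as a defensive measure although trunk angles in practice
  stay within ±90° of the reference, else
* elapsed time $> 240$ s (strict), with the reported duration capped at
  240 s.

When several criteria fire on the same sample the reason priority is
manual > angle > time cap. Duration is the terminating sample's stream
time minus the start time, so a detected duration can exceed the true
crossing time by at most one sample period (1/51.2 s ≈ 19.5 ms). A stream
that ends mid-attempt raises a typed `truncated_stream` error carrying the
partial duration rather than silently reporting a shorter test. The 240 s
cap applies *per attempt*; a two-attempt Sorensen total may therefore
exceed 240 s, and scoring clamps the total into the bins' domain.

STEET's second attempt is optional input; the rule that the second chance
follows an angle-droop finalization is advisory for the operator and not
enforced by the state machine.

## Normative scoring

Category bins (seconds): STEET bad [0, 61], good [62, 131], perfect
[132, 240]; SBET bad [0, 60], good [61, 108], perfect [109, 240]; TCSET
has two labels, bad up to 131 and good from 132. The published TCSET bins
overlap as printed (bad to 133, good from 132); the package resolves the
overlap at 131/132 so that the bins partition the domain, and the whole
table is replaceable via the `bins` argument for clinics using stratified
norms. Internally the bins are right-open at the printed integer edges, so
integer durations map exactly as printed and every continuous duration in
[0, 240] receives exactly one label, monotonically in duration.

Ratios: flexor/extensor = TCSET / STEET (normal reference 0.77) and
right/left side bridge (normal reference 0.96). "Side-to-side difference
greater than 0.05" is read as deviation of the ratio *from the 0.96
norm*; deviation from unity is available via `center = "unity"`. Both
ratios are scale-invariant by construction.

## Reliability statistics

The agreement analysis treats the two timing methods as interchangeable
raters of each subject, i.e. the one-way random model
$x_{ij} = \mu + b_i + e_{ij}$ with $b_i \sim N(0, \sigma_b^2)$,
$e_{ij} \sim N(0, \sigma_w^2)$. From the ANOVA mean squares (computed
directly; a unit test cross-checks them against `stats::aov`):

* ICC(average) $= (MSB - MSW)/MSB$ — the package default, describing the
  reliability of the mean of the two methods;
* ICC(single) $= (MSB - MSW)/(MSB + MSW)$ for $k = 2$;
* exact CI from $F_0 = MSB/MSW$ with $(n-1,\; n(k-1))$ degrees of freedom,
  using `stats::qf`; with $MSW = 0$ the interval degenerates to $[1, 1]$;
* Cronbach's $\alpha = 2\,(1 - (\mathrm{var}\,a + \mathrm{var}\,b)/
  \mathrm{var}(a + b))$, which for $k = 2$ is algebraically close to the
  average-measures ICC (equal when the two item variances are equal);
* Bland–Altman: differences oriented as `method_a − method_b`
  (traditional minus instrumented in the packaged case study, so a
  negative mean means the instrumented method measured longer), limits
  $\bar x \pm 1.96\, s_X$.

The average-measures form is the default because, on the packaged
case-study fixture, it is the form whose values are consistent with the
qualitative reliability categories the field reports for such data; the
single-measures form is one flag away. Estimates are carried at full
precision and only rounded (half-up, 2 dp) for display.

`simulate_paired_study()` draws from exactly this model and returns the
analytic average-measures ICC $2\sigma_b^2/(2\sigma_b^2 + \sigma_w^2)$ as
an attribute, which the test-suite uses for parameter-recovery and
CI-coverage checks (500 replicates of $n = 200$ subjects at true ICC 0.9 —
a size chosen to make the binomial error on the coverage estimate small
while the whole check runs in seconds).

## The synthetic-data generator

`posture_scenario()` emulates what the endurance tests look like to the
sensor: a held roll angle with optional Gaussian per-sample tremor,
followed by a linear droop. With zero tremor the droop crosses a
tolerance $\tau$ at exactly `hold_duration` $+\ \tau/$`droop_rate`, giving
an analytic oracle for the state machine; tremor, when enabled, is
independent per sample — a crude stand-in for postural sway, which in
reality is autocorrelated. `synthesize_imu()` inverts the sensor model:
attitude-rotated gravity reaction, finite-difference body rates, and an
attitude-rotated unit magnetic field with 50° inclination, plus
independent Gaussian noise per axis. `simulate_emg()` is zero-mean
Gaussian noise amplitude-modulated to RMS `baseline_rms` $+$
`fatigue_slope`·t.

These generators intentionally omit real-world effects — sensor bias and
drift, soft-tissue artifact, autocorrelated sway, non-Gaussian and
band-limited EMG, magnetic disturbance — so passing tests demonstrate the
*algorithms'* correctness against known ground truth, not field accuracy
of a physical device. All generators are deterministic per `(scenario,
seed)` and restore the caller's RNG state.

## Known limitations

* The fusion filter is first-order; at sampling rates far below 51.2 Hz
  the integration error grows quadratically with the step.
* Reliability statistics assume exactly two raters/methods ($k = 2$).
* Normative bins and ratios are fixed constants for healthy young adults;
  no age- or sex-stratified norms are modelled.
* The session store is plain JSON on disk, chosen for reproducibility and
  diff-ability over database features; concurrent writers are not
  supported.

## Problem sizes used in the checks

The packaged agreement fixture is 10 subjects × 2 methods × 4 tests. The
state-machine fidelity checks use 100 random hold/droop scenarios at
51.2 Hz; orientation checks use 512-step integrations and 2000-step
static convergence runs; EMG identities use 1000 random epochs; ICC
coverage uses 500 replicates of n = 200. These sizes keep every property
estimate's Monte-Carlo error well below the tolerance it is compared
against while the whole suite runs in well under a minute per module.
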