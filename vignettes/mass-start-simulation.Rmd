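---
title: "Models and methods behind the simulated mass-start pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the simulated mass-start pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimass)
```

# The simulated mass-start

A simulated mass-start on a roller-ski treadmill has two parts. The initial
part (IP) is seven identical 3-min laps, each crossing a moderate uphill
(S1, 18 km/h), a flat (S2, 24 km/h), a steep uphill (S3, 14 km/h) and a
simulated downhill (S4); skiers who cannot hold the pace may take 30-s
breaks while the belt keeps running. The IP is followed immediately by an
all-out sprint (AOS) at 5% incline, starting at 20 km/h and increasing
1 km/h every 15 s until exhaustion. Performance rank is the number of
breaks first, then time to exhaustion (TTE) within equal breaks.

Only the three IP segment speeds and the AOS schedule are part of the
published design; the segment inclines and within-lap durations exist only
graphically. The package treats them as configuration with defaults S1
5%/60 s, S2 2%/35 s, S3 12%/45 s and S4 −3%/40 s, chosen so each segment
pairs with the incline at which its natural sub-technique is used in the
efficiency protocol (G3 at 5%, G4 at 2%, G2 at 12%). The S4 belt speed
(25 km/h) is likewise a configuration default: a downhill is simulated by a
negative grade and no propulsion, so its speed only affects distance
bookkeeping. Exact ranking ties (same breaks and same TTE) are kept in
input order and flagged; the observed field never contains one.

# What the generator simulates

`generate_trial()` produces one skier's full sensor bundle plus a
ground-truth sidecar. It is built for *statistical* fidelity — every
downstream stage sees data with the structure its method assumes — not for
biomechanical fidelity of human movement.

**Movement cycles.** Within each contiguous window of one gear, cycles have
a fixed gear-specific period (G2 1.75 s, G3 1.90 s, G4 1.65 s), placing
cycle rates in the observed 29–36 cpm band. The mediolateral chest
acceleration is `-A cos(phase)`: exactly one minimum per cycle at the
leftmost body position, which is the cycle-start definition used by the
detector (leftward acceleration is negative by convention). The other two
accelerometer axes carry gear-specific harmonic signatures standing in for
the different pole/leg phase structures of the gears (G2 one asymmetric
pole push per two leg pushes, G3 a pole push with every leg push, G4 a
symmetric push every other leg push). `Other` windows (downhill tuck,
breaks, transitions) carry an aperiodic low-frequency signal and no
ground-truth cycles.

**Metabolic demand and kinetics.** Each second's demand is the external
work rate divided by the gear's gross efficiency,
`MR = 100 * P / GE(gear)`, converted to VO2 through the same oxygen
equivalent the metabolism module uses (profile RER, default 0.91); seconds
without propulsion sit at a basal floor (120 W). Measured VO2 follows
first-order kinetics `dV/dt = (demand - V)/tau` — the observed response
delay documented for this kind of protocol, with no model given; the
mono-exponential is the standard minimal choice. Defaults tau = 25 s (VO2)
and 20 s (HR). VO2 is then binned into 10-s mixing-chamber values. HR
demand is affine in relative VO2 demand (`0.33 + 0.58 * VO2/VO2Max` of
HRMax, a standard %HR–%VO2 relation kept below the ceiling so drift is not
clipped) plus a drift term linear in time on task, `hr_drift` pp of HRMax
per lap (default 7.9/5, making the lap-7 − lap-2 statistic 7.9 pp). Both
signals are capped at the profile maxima. Because lap means of a linear
drift differ by exactly (7 − 2) per-lap units regardless of the first-order
lag, the drift statistic recovers the injected value up to a small kinetic
transient in the lap-2 baseline (about 0.02 pp at the default constants) —
the same residual the lap-2-instead-of-lap-1 baseline convention exists to
minimise.

**NIRS.** TSI is a baseline (leg 68%, arm 62%) minus an
intensity-proportional desaturation smoothed with an 8-s constant, plus an
arm-specific linear drift (default −3.0/5 pp per lap). One-second dropout
gaps are injected at a configurable rate to exercise the cleaning rule.

**Pole forces and markers.** The centre of mass advances at belt speed in a
ground-equivalent frame (x forward, y left-positive, z up) with small
cycle-locked oscillations; body markers ride rigidly on it, which keeps the
segment-model CoM an exact translate of the true trajectory and its
velocity exact. Each poling cycle contains one double-pole action: half-sine
axial impulses during a 0.4-s contact, with the pole at 15° off vertical at
plant and lift-off and 30° at mid-contact. The symmetric angle profile is a
deliberate numerical choice: it makes the cycle-average pole power
second-order insensitive to small force-clock alignment errors (with a
monotone angle sweep, a 10-ms misalignment already shifts the recovered
pole fraction by about 1 pp). Impulse amplitudes are scaled per cycle so
the cycle-average summed pole power equals `pole_frac` of the cycle work
rate, split `lr_left`/`1 - lr_left` between poles; axial force exceeds the
10-N touchdown threshold only during contact. The force stream is written
on a clock shifted by a known `sync_offset` (default 0.12 s) that the
alignment step must recover. Swing-phase pole orientation is blended
smoothly into and out of contact so the 15-Hz filter has no steps to ring
on. The study recorded motion capture only on alternate laps to bound data
volume; `marker_laps` reproduces that, defaulting to laps 1 and 3 (the
power summary windows), with unrecorded laps inside the span as NA.

**Noise.** All channels receive additive Gaussian noise with configurable
SDs (`noise_defaults()`); no physiological noise magnitudes are published,
so the defaults are free parameters chosen small relative to their signals
(e.g. 0.3 m/s² IMU, 1 bpm HR, 0.05 L/min on 10-s VO2 bins, 2 mm markers).
Everything is deterministic given the profile seed.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real recordings: soft-tissue and impact artefacts in
the IMU, breath-by-breath VO2 noise structure, cycle-to-cycle period
variability within a gear, marker occlusion/mislabeling, treadmill-frame
kinematics (the real lab frame has near-zero mean forward CoM velocity),
drafting and pacing behaviour, and any classifier transfer across skiers
with individual technique. Recovery results bound the pipeline's numerical
correctness, not its field accuracy.

# Processing choices

**Cycle detection.** The mediolateral channel is Gaussian-smoothed
(sigma 0.1 s) and strict local minima are found on a reflection-padded copy
so a cycle start on a stream edge is still found; minima closer than 0.8 s
(max 75 cpm) are pruned keeping the most negative, and shallow minima
(above `mean - 0.5 sd`) are rejected as ripple. Sigma and the minimum
period are not published; they were chosen once from the printed cycle-rate
range with headroom. A trailing edge cycle can be clipped by up to the
smoothing support (0.3 s).

**Classification.** Features per cycle: each accelerometer axis
time-normalised to 30 points and standardised within the window (shape,
amplitude-invariant), plus duration and the three raw axis variances
(3 × 30 + 4 = 94). The classifier is an RBF-kernel SVM over standardised
features with the class set fixed to G2/G3/G4/Other. The published
analysis states only "Gaussian filtering and a trained support vector
machine"; any separating choice is admissible, and the synthetic classes
are constructed to be separable (≥ 99% on the training set, ≥ 95% on
held-out seeds at default noise, mirroring the >99% the original model
reached on its own recordings — a figure that only its own data can
establish).

**Power.** Markers and forces are low-pass filtered with an 8th-order
15-Hz Butterworth applied forward–backward (zero phase; the published
order/cutoff say nothing about phase, and zero-phase is the biomechanical
standard). `signal::filtfilt` carries a startup transient, so filtering
runs on an odd-reflection padding long enough for the transient to die out
(~1.5 s at 200 Hz). The CoM uses de Leva's adjusted male segment
parameters with head+trunk as one hip–shoulder segment and forearm+hand
combined; CoM velocity is central differences. Force (100 Hz) is aligned to
the kinematic clock by matching the first 10-N force upcrossing (linearly
interpolated) to the first kinematic touchdown — the first local minimum of
pole-tip height near the contact level, the marker-side definition being
unpublished — and resampled by linear interpolation; the kinematic clock is
authoritative. Negative instantaneous pole power is retained in the cycle
average: whether the original analysis rectified it is unstated, and
clipping would break `P_Cycle = P_Pole + P_Ski`. Cycles with non-positive
work rate get NA percentages; missing force samples propagate NA through
the affected cycles (pairwise deletion downstream).

**Metabolism.** Grade percent converts to angle via `arctan(grade/100)`;
at the steepest grade used (12%) the small-angle alternative differs by
under 1%. Oxygen equivalents come from the non-protein RQ table
(4.686–5.047 kcal/L between RQ 0.70 and 1.00, ×4.184 kJ/kcal) with linear
interpolation; RER is clamped to [0.70, 1.00] for the lookup because
supra-1.0 RER reflects non-metabolic CO2, and below 0.70 is an error.
Overall GE is the unweighted mean over the available bouts (11 or 12). Any
table in this family satisfies the round-trip identity the tests enforce.

**Timeline.** Each master-timeline second is the mean of samples in
`[t, t+1)`; 10-s VO2 values are step-held over their bin so every second
carries a value. NIRS: fully missing seconds are filled with the mean of
their two neighbours, then a *centred* 3-s moving mean (centred vs trailing
is unstated; centred keeps the phase of terrain-driven fluctuations) is
sampled at 1 Hz; longer gaps stay missing. Missing values are always NA,
never zero. Group comparisons use laps 1–3 of the IP and the first three
AOS steps, the windows every skier completed.

**Statistics.** Spearman uses mid-ranks for ties then Pearson on the rank
vectors (the convention of standard statistical software), verified in the
tests against a brute-force counting oracle for all n ≤ 6 including ties;
p-values use the t approximation. Physiological drift is lap 7 − lap 2,
kinematic drift lap 7 − lap 1, each with a paired t-test across skiers
(p = 1 when all differences are exactly zero). Segment contrasts are
one-way ANOVA with Tukey HSD, lap 1 excluded by the caller. Magnitude
labels follow the published bands on |r|; 0.05 < p < 0.10 is reported as a
trend.

# The embedded summary tables

The per-skier physiology and kinematics tables (13 rows each) ship as CSVs
with MD5-checksum verification. Two skiers have NA power columns — their
pole-force recordings failed — and flow through the battery by pairwise
deletion. From these tables the battery reproduces, at printed precision:
rank vs %HRMax 0.87, RPE 0.73, VO2Max 0.68, VO2 peak reserve 0.72, HR peak
reserve 0.76, and the cohort VO2Max mean 69.5 mL/min/kg, with CL × CR / 60
within [5.7, 6.0] m/s for all rows.

Two conventions deserve note:

- **Peak-reserve variables.** The reserve is the raw difference between the
  peak reached in the AOS and in the IP (bpm for HR, mL/min/kg for VO2).
  Individual HRMax is not part of the tables, so raw differences are the
  only computable HR variant; for VO2 the max-normalised variant
  `(peak AOS − peak IP)/VO2Max × 100` is available via
  `reproduce_correlations(reserve = "normalized")`, but its rank
  correlation differs by 0.01 (−0.71 vs −0.72) because the printed inputs
  carry only one decimal. The raw-difference default keeps the two
  reserves consistent and reproduces both printed coefficients.
- **Tie-affected coefficients.** Columns with many printed-precision ties
  (%VO2Max, overall GE) give 0.88 and 0.68 from the rounded tables where
  full-precision inputs gave 0.89 and 0.70; these are reported with a
  ±0.01–0.02 caveat and not used as reproduction anchors. The same applies
  to quantities that exist only in figures (e.g. the G3-share-in-steep-
  uphill correlation 0.69): figure-only values are never targets. All
  statistics computed on the original sensor recordings (drift p-values,
  TSI segment means, the classifier's >99% on real data) are out of reach
  of a desk reproduction by construction.

# Problem sizes and determinism

The test-suite and acceptance runs use deliberately small simulations: GE
recovery uses the full 12-bout protocol per skier at 1 Hz; pole-power
recovery uses 45–60-s single-gear windows at 200 Hz; classification uses
four 2-min single-gear bouts per seed; drift recovery uses nine full-IP
breath/NIRS series at 1–10 Hz. A full default trial (IP + 90-s AOS with
markers on laps 1–3) generates in about 3 s. Every random draw is seeded —
profiles carry their own seed, and the acceptance script derives all seeds
from its `--seed` argument — so all reported numbers are reproducible.

# Known limitations

- The generator's gear periods are constant within a block; CL/CR
  variability within a gear, and speed-dependent period modulation, are not
  modelled.
- The HR–VO2 affine link and the linear drift are conveniences; real drift
  interacts with intensity, cardiovascular drift and thermoregulation.
- The ground-equivalent marker frame sidesteps treadmill-frame kinematics;
  the power decomposition contract (direction from handle to tip, dot with
  CoM velocity) is shared between generator and processor by convention.
- The classifier is trained and evaluated within the generator's waveform
  family; no claim transfers to real IMU data or across skiers.
- The AOS is simulated only until a profile-specified TTE; the decision to
  stop (exhaustion modelling) is not part of the generator.
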