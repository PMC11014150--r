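---
title: "Posture and intensity from hip-worn accelerometry: the MAD/APE pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture and intensity from hip-worn accelerometry: the MAD/APE pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madape)
```

## The measurement problem

Hip-worn accelerometers are the workhorse of population physical-activity
surveillance, but a hip sensor measures movement intensity, not body posture.
Sedentary behavior (SB) is defined by *both*: waking behavior at or below
1.5 metabolic equivalents (METs) **in a sitting, reclining or lying posture**.
Intensity-only processing cannot separate quiet standing from sitting, and
thigh-worn inclinometers, which can, struggle to separate sitting from lying.

`madape` implements a posture-aware pipeline for raw hip acceleration built on
two physical assumptions:

1. Earth's gravity is a constant 1 g reference available in every epoch of a
   triaxial recording, and
2. body posture during walking is upright.

The device orientation captured during recognized walking therefore defines
an "upright" reference direction, and the angle between the current
orientation and that reference — the *angle for posture estimation* (APE) —
proxies trunk inclination without requiring any a-priori knowledge of how the
device was mounted.

## Epoch features

Raw signals (nominally 100 Hz, ±16 g, 0.004 g resolution) are cut into
half-open 6 s epochs aligned to the recording start; a trailing partial epoch
is dropped. For each epoch with samples $(x_i, y_i, z_i)$, $i = 1..N$, the
resultant magnitude is $r_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$ and the package
computes

- **MAD** $= \frac{1}{N}\sum_i |r_i - R_{ave}|$, the mean amplitude deviation
  of the resultant about its epoch mean, reported in mg (1 mg = 0.001 g);
- **MADxyz** $= \frac{1}{N}\left(\sum_i |x_i - X_{ave}| + \sum_i |y_i -
  Y_{ave}| + \sum_i |z_i - Z_{ave}|\right)$, the summed axis-wise mean
  absolute deviations, also in mg;
- the epoch mean vector $(X_{ave}, Y_{ave}, Z_{ave})$ and its unit
  orientation $\hat e$;
- a step count (below) and a MET estimate.

The typeset source of the MADxyz formula is ambiguous between squared and
absolute deviations; `madape` implements the sum of axis-wise mean *absolute*
deviations, which is the reading consistent with its use as a
movement-steadiness ratio against MAD (both then share units and scale).

MET conversion is piecewise linear in intensity:

$$
\mathrm{MET} =
\begin{cases}
1.0000 + 0.0223\,\mathrm{MAD} & \mathrm{MAD} < 91.5\ \mathrm{mg}\\
2.1488 + 0.0093\,\mathrm{MAD} & 91.5 \le \mathrm{MAD} < 500\ \mathrm{mg}\\
0.4027 + 0.0107\,\mathrm{MADxyz} & \mathrm{MAD} \ge 500\ \mathrm{mg}
\end{cases}
$$

As printed, the function has a small downward seam at 91.5 mg (the low piece
approaches 3.0404 while the middle piece starts at 2.9998). `madape` applies
the equations exactly as calibrated and pins the seam in a test rather than
smoothing it away. Similarly, the sedentary gate is the *operational* rule
MAD < 22.5 mg, even though the low-intensity equation crosses 1.5 MET at
≈22.42 mg; the printed 22.5 mg rule wins because downstream studies used it.

```{r met}
estimate_met(0, 0)            # motionless epoch
round(estimate_met(22.5, 22.5), 1)  # the sedentary gate in MET units
```

## Step detection

The source method states the walking criteria (8–13 steps per 6 s epoch) but
not a step-detection algorithm, so the detector here is the package's own
design: the resultant is band-passed to the 0.5–3 Hz locomotion band
(zero-phase 2nd-order Butterworth), and local maxima with at least 100 mg
prominence separated by a 0.25 s refractory period are counted. The band
covers normal-walking step rates (1.33–2.17 Hz); the prominence gate rejects
sub-50 mg sensor noise; the refractory period caps the count at four events
per second. These three constants are exposed as arguments of
`count_steps()`.

## Walking recognition and the reference vector

An epoch qualifies as a *reference-setting* walking epoch when all three
criteria hold:

| criterion | bound | meaning |
|---|---|---|
| MAD | 150–350 mg, inclusive | normal walking intensity |
| steps per epoch | 8–13, inclusive | normal cadence |
| MADxyz / MAD | < 1.6, strict | steady, gait-like movement |

Each qualifying epoch sets its own orientation $\hat e$ as the new upright
reference $\hat u$; every epoch is assigned the most recent setting at or
before it ("last setting wins"). Epochs before the first setting carry an
undefined reference by default — the pipeline never uses future information
unless `backfill = TRUE` is requested for whole-file batch analysis. For
stationary epochs (wear epochs with MAD < 22.5 mg) the posture angle is

$$\mathrm{APE} = \cos^{-1}(\hat e \cdot \hat u) \in [0^\circ, 180^\circ],$$

with the inner product clamped to $[-1, 1]$ to absorb floating-point
rounding.

Postures are classified at validated cut-points, lower bounds inclusive:
standing below 11.6°, sitting in [11.6°, 30°), reclining in [30°, 73.9°),
lying at and above 73.9°. The package also reports the descriptive 18-bin
histogram (5° bins from 0° to 85°+) with its published annotation (bins
below 10° standing, 10–15° transition, 15–30° desk sitting, 30–55° sofa
sitting, 55–75° transition, 75°+ lying). Both mappings are configurable; the
4-way classifier is authoritative for posture minutes, and epochs between
55.9° and 73.9° — between the validation extremes for sitting and lying —
are assigned "reclining" by construction.

Note that the steadiness ratio is *axis-referenced*: MADxyz is not invariant
under device rotation even though MAD and APE are. This is intentional — the
criterion encodes how a firmly mounted hip device moves during gait — but it
means walking recognition tolerates only modest mount rotations
(roughly ±15–25° in the synthetic model) before the ratio crosses 1.6.

## Device trigger emulation and non-wear

The recording device arms when any axis departs more than 187.5 mg from its
running per-axis reference, confirms activity if a departure greater than
500 mg follows within 5 s, and otherwise returns to quiescence; the reference
updates to the coincident sample whenever either limit is exceeded, and all
comparisons are strict. `madape` re-purposes this on-device behavior as a
software quiescence detector (`emulate_trigger()`) so that non-wear — a
continuous quiescent run strictly longer than 120 min — can be computed from
continuously recorded files. A run of exactly 120 min therefore remains wear.

Two details are unspecified in the source description and were fixed here,
pinned by an independent brute-force oracle in the test suite:

- the reference updates on *any* exceedance, including arm-level deviations
  during the armed state;
- the active state ends after 5 s without an arm-level deviation, and the
  following quiescent run starts at the sample *after* the last deviation, so
  a motionless block begins its quiescent run immediately.

A confirmed activation is marked active retroactively from the arming sample;
an unconfirmed arming leaves its samples quiescent. The per-sample mask is
down-sampled to seconds (a second is active if any of its samples is) before
segmentation.

## Validity rules and summaries

- A **valid day** has wear time of at least 1436 of 1440 min (the source
  requires "complete 24 h wear" without stating a tolerance; four minutes
  absorbs epoch-boundary effects and is configurable) and at least 10
  reference settings.
- A **participant** is included with at least 4 valid days; per-bin means are
  taken over valid days only.
- MET minutes accumulate into nine 1.5-MET bins (below 1.5 to above 12);
  the lowest bin is stationary behavior, then light (1.5–3), moderate (3–6),
  vigorous (6–9) and very vigorous (9+) activity.
- Sleep-log intervals are excluded from all behavior summaries (the device
  moves to the wrist in bed); wear time itself still counts around the clock.
- Hour-by-hour stationary profiles split at APE 30° (the boundary counts
  upward) and average over valid days, with weekends defined as Saturday and
  Sunday on the local clock.

Every 6 s epoch contributes 0.1 min, so MET-bin minutes sum to awake wear
minutes and APE-bin minutes sum to stationary minutes with a defined APE —
conservation identities asserted on every simulated recording in the tests.

## Cohort statistics

`assign_groups()` forms sex-specific VO~2~max tertiles and BMI categories
(< 25, 25–30 inclusive, > 30 kg/m²). `compute_weights()` assigns
frequency-style weights equalizing the ten sex × age-decade cells (20–29
through 60–70). `partial_spearman()` is implemented as
rank-transform → residualize on an intercept, centered age, centered age
squared and a sex indicator → correlate the residuals; ranking before
residualization makes the statistic invariant to monotone transforms of
either variable, and centering age before squaring curbs collinearity.
Weights enter the correlation as frequency weights in all means and
cross-products; group tests (`group_compare()`: Kruskal–Wallis omnibus with
Dunn's pairwise z and Bonferroni adjustment) run unweighted, since the source
workflow does not state how weighting interacted with the tests — both
correlation modes are exposed.

## The synthetic generator

Because no study data are distributable, every stage is validated on
synthetic recordings with known ground truth. `activity_schedule()` scripts
segments of standing / desk sitting (20° tilt) / sofa sitting (45°) / lying
(85°) / walking / non-wear; `generate_recording()` renders them as a gravity
vector tilted in the body sagittal plane, composed with an arbitrary fixed
mount rotation, plus:

- a gait oscillation along the body-vertical axis at the set cadence, with a
  0.3-amplitude-fraction harmonic at twice the cadence on the anteroposterior
  axis. The amplitude starts at the closed-form value $A = \frac{\pi}{2}
  \cdot \mathrm{MAD}$ for a full-cycle sinusoid and is refined against the
  measured MAD of a noise-free epoch until the realized value is within ±10%
  of target. The harmonic fraction was set to 0.3 because the steadiness
  ratio of the two-sinusoid model is ≈1.33 at an identity mount, leaving
  headroom below the 1.6 walking bound for mount rotations up to ≈15–25°;
  a 0.5 fraction would sit at ≈1.53, where a 5° anteroposterior rotation
  already breaks walking recognition;
- white Gaussian sensor noise (default 5 mg per axis) on worn segments;
- optional 0.004 g quantization and ±16 g clipping;
- constant gravity, without noise, on non-wear segments.

The generator emulates posture-dependent gravity orientation, controllable
gait, sensor noise, quantization and non-wear gaps. It does **not** emulate
gradual posture transitions, soft-tissue artifact, multi-axial gait
complexity, device drift, or saturating impacts — so passing recovery tests
demonstrate the internal consistency of the pipeline under its own
assumptions, not field accuracy on human data. `generate_cohort()`
analogously plants monotone covariate effects (standing-range minutes rising
with fitness and falling with BMI; reclining-range minutes reversed) on a
fixed baseline bin profile, for sign-recovery checks of the correlation
machinery.

```{r pipeline}
sch <- activity_schedule(
  duration_s = c(60, 300, 60, 300),
  activity   = c("walking", "standing", "walking", "sofa_sitting"),
  tilt_deg   = c(0, 0, 0, 45))
g <- generate_recording(sch, sampling_rate = 20, seed = 1)
res <- process_recording(g$recording)
table(res$epochs$posture)
```

## Numerical and convention choices

- Epochs are half-open `[start, start + 6 s)`, aligned to the recording
  start, not to wall-clock minutes; remainder samples are dropped.
- All classification boundaries follow the published wording: strict where it
  says "exceeded" / "less than" (trigger thresholds, the 1.6 ratio, the
  120 min rule), inclusive lower bounds for posture cut-points and bins.
- Timestamps are local clock time; the test fixtures pin them to UTC for
  determinism.
- Validation-suite problem sizes: oracle equivalence runs 1000 random
  instances per primitive; recovery tests use 20 Hz recordings of tens of
  minutes and 100 seeded cohorts of n = 150 — small enough to run in
  seconds, large enough that every boundary and conservation law is
  exercised.

## Known limitations

- Step detection is a package design, not the device's proprietary counter;
  absolute step counts on real data would need calibration.
- The walking steadiness criterion limits tolerable mount rotation; strongly
  displaced devices will silently stop producing reference settings (the
  daily settings count in the run report is the diagnostic).
- Participants who never reach 150 mg MAD while walking acquire no reference
  vector and no posture labels — a known failure mode in low-fitness groups.
- Proprietary on-device file formats are out of scope; inputs are delimited
  text or Parquet/Feather columnar tables.
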