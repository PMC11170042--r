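---
title: "Methods: wearable activity and intensity monitoring for inpatient rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable activity and intensity monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearrehab)
```

## The measurement problem

Inpatients in subacute rehabilitation (for example after stroke) are at risk
of deconditioning: most of their day is unscheduled, and activity outside
therapist-led training sessions is rarely observed. A chest-worn sensor that
records tri-axial acceleration (25 Hz, units of g) and heart rate (1 Hz,
beats/min) over 48 hours makes both the *quantity* of movement and its
*cardiovascular intensity* measurable around the clock. This package turns
those two raw streams plus a therapist-recorded period schedule into per-day
summaries and cohort-level statistics, and ships a synthetic-cohort
generator so the whole chain is testable without patient data.

## Activity: the moving SD of acceleration (MSDA)

Step counts are unreliable in slow, irregular gait, so movement quantity is
quantified as the moving standard deviation of acceleration: the session is
cut into consecutive non-overlapping windows $[kw, (k+1)w)$ with $w = 2$ s
aligned to session start, and each window's value is the sample SD
(denominator $n-1$) of the Euclidean norm
$\sqrt{a_x^2 + a_y^2 + a_z^2}$ within the window. Daily MSDA totals are
*sums* of window values; because each window is assigned to exactly one
period by its start time, the daily total decomposes exactly as
training + nontraining — an identity the test-suite asserts for every
simulated day and that also holds for the cohort calibration constants
packaged with the generator.

Choices worth making explicit:

- **Norm, not per-axis SDs.** The norm is invariant to sensor rotation
  about the gravity axis, which matters on a chest strap. The cost is that
  an *exact* invariance to adding a constant vector only holds when the
  offset is collinear with the signal direction (for small fluctuations
  around a dominant gravity vector it holds to first order); the tests
  exercise the collinear case exactly, along with exact linearity under
  scaling.
- **Numerics.** Window SDs use a shifted two-pass algorithm (deviations
  from the window's first sample), so a constant window yields exactly
  zero, and random windows agree with a naive two-pass oracle to better
  than $10^{-12}$ relative.
- **Gaps.** A window that intersects a declared recording gap (bathing,
  device swap) is dropped entirely; it contributes to no period.
- **Units.** MSDA is reported in g. Device firmwares often scale this
  quantity by an undocumented constant; a configurable calibration factor
  (`msda_calibration`, default 1) is provided, and no attempt is made to
  guess any particular device's scaling.

## Posture and walking

Posture is classified per 5-s epoch. The gravity direction is the epoch
mean of a moving-median low-pass (2-s kernel) of each axis; the epoch is
**lying** when the angle between gravity and the device's longitudinal
(trunk) axis exceeds 50° from vertical, else upright. Epochs with fewer
than 50% of their expected samples are labelled **gap**. The threshold,
epoch length, kernel and trunk axis are all configurable
(`process_params()`); 50° splits the ambiguity between reclined sitting
and true lying in favour of specificity for the supine night block that
anchors the resting heart rate.

Upright epochs are refined to **walking** when two conditions hold: mean
MSDA over the epoch ≥ 0.05 g (movement is present) *and* the dominant
spectral peak of the mean-removed acceleration norm lies in the 1–3 Hz
gait cadence band. Stationary fidgeting and postural sway concentrate
spectral power at low frequency, so the cadence condition separates gait
from vigorous but stationary movement; the band deliberately reaches down
to 1 Hz to include slow hemiparetic gait. The rule is an explicit,
documented classifier — devices in this field embed an undisclosed one —
and its recovery error is measured against generator ground truth
(epoch-level agreement ≥ 95% away from transitions; walking minutes within
±20%).

## Intensity: percent heart rate reserve

Intensity normalizes heart rate to the individual's cardiac range:

$$\%HRR(t) = 100\,\frac{HR(t) - HR_{rest}}{HR_{max} - HR_{rest}}.$$

- $HR_{rest}$ is the **median** heart rate over samples that are
  simultaneously inside the night clock window 00:00–05:00 (half-open) and
  inside lying-labelled epochs, pooled over both nights of a 48-h session —
  a single anchor per session. The median is robust to brief arousals; an
  explicit error (naming patient and session) is raised below 30 minutes of
  qualifying data rather than silently falling back.
- $HR_{max}$ is the measured value when available, else age-predicted
  `220 − age` (the `208 − 0.7·age` variant is available by configuration).
- The transform is applied pointwise to the 1-Hz series; sub-resting values
  stay negative (they are informative) and values above 100 are kept.
  $HR_{max} \le HR_{rest}$ is a hard error reporting both values.

Daily mean %HRR is the unweighted mean over the day's samples, overall and
within each period; the overall mean equals the sample-count-weighted
combination of the period means to floating-point accuracy (asserted at
$10^{-9}$ relative in the tests).

## Days, periods and summaries

Days are calendar-clock slices `[00:00, 24:00)` — not rolling 24-h windows
— because the resting-heart-rate anchor is clock-bound and daily averages
are the reporting unit in this field. Leading/trailing partial days are
flagged and excluded from cohort means by default (a 48-h recording can
straddle three calendar days). Sleep is part of the nontraining period:
the nontraining intensity mean is a whole-of-nontraining quantity. Cohort
tables carry one row per patient-session (session means over full days,
joined with age, sex and the session's FIM motor score); patients missing a
session keep a row of missing markers.

## Cohort statistics

Both tests are implemented from first principles with exact small-sample
behaviour, since small cohorts are the norm in this setting:

- **Wilcoxon signed-rank** (paired, two-sided): zero differences are
  discarded (the classical convention; Pratt's is available), absolute
  differences are mid-ranked, and for $n \le 15$ the p value is computed by
  full enumeration of all $2^n$ sign assignments via subset-sum doubling —
  valid under ties, and verified against an independent brute-force
  enumeration for every $n \le 10$ and against the reference implementation
  on tie-free data. Beyond $n = 15$ a normal approximation with continuity
  correction uses $\mathrm{Var}(W^+) = \sum r_i^2/4$, which absorbs the tie
  correction automatically. Degenerate input (all differences zero) returns
  a flagged result with $p = 1$. Under null simulation the exact test at
  $\alpha = 0.05$, $n = 11$ holds its size within the conservative band
  expected from discreteness (empirical rejection in [0.03, 0.07] over
  2,000 replicates in the acceptance suite).
- **Spearman rank correlation**: Pearson correlation of mid-rank-transformed
  data; the two-sided p value uses the $t$ approximation with $n-2$ df
  (exact enumeration of $11!$ permutations is impractical and the
  approximation is adequate at these sizes), with a seeded Monte-Carlo
  permutation option (≥ 99,999 draws) for small samples; the two agree
  within 0.02 at $n = 11$ for moderate correlations. Zero rank variance is
  flagged, not silently returned as 0.
- No multiple-testing correction is applied by default ($\alpha = 0.05$ per
  test, matching common practice in this literature); a Holm option exists.

## The synthetic cohort: what it emulates

The generator produces fully annotated 48-h sessions for a configurable
cohort (default 11 patients × 2 sessions):

- **Ward day** (invented, configurable — wards differ and no standard
  timetable exists): lights out 21:00, rise 06:00, training inside
  09:00–17:00 split over two blocks (default 180 min/day — consistent with
  a 24-h intensity mean sitting at about 1/8 of the way from the
  nontraining to the training mean), one 30-min bathing pause per day
  (recording halted), and a 2-min recording gap at wear hour 24 when the
  strap and transmitter are swapped.
- **Acceleration** = posture-dependent gravity orientation + AR(1) noise
  with ~1-s correlation (postural sway is low-frequency; this is what makes
  the cadence-band walking rule informative), plus a sinusoid at the gait
  cadence (default 1.9 Hz, 0.35 g) during walking bouts. The AR(1) marginal
  variance is calibrated analytically (exact covariance-matrix moments plus
  a Satterthwaite correction for $E[\sqrt{s^2}]$) so the *expected 2-s
  window SD* equals the configured per-posture activity level — i.e.
  `posture_noise_sd` is defined on the MSDA scale, and the estimator's
  consistency against it is a test.
- **Heart rate** = $HR_{rest} + f(t)(HR_{max} - HR_{rest})$ where $f(t)$ is
  the per-interval true mean %HRR/100 plus AR(1) noise (SD 3 %HRR points,
  30-s correlation — chosen so night medians are stable). Sleep has a true
  %HRR of 0, which is what makes the night median identify $HR_{rest}$;
  the daytime nontraining level is then derived so the *whole-period*
  nontraining mean equals its configured value. Period means default to the
  packaged cohort calibration values (training 22.13%, nontraining 9.47%).
- **Cohort structure**: per patient-session activity multipliers
  $m = \exp(\beta z + \varepsilon)$ with $\beta = 0.7$ per SD of the FIM
  motor score (training) or $-0.7$ per SD of age (nontraining) and
  patient-level noise $\varepsilon \sim N(0, 0.28)$ — calibrated so
  recovered rank correlations are strong but not degenerate, in the 0.75–
  0.95 magnitude range reported for such cohorts. Zero slopes sever the
  couplings entirely.

All randomness flows from the single configured seed through named
substreams per patient, session and signal, so identical configurations are
bit-identical.

**What it does not emulate** — and hence what passing tests do *not* show
about real data: electrode motion artifacts and ECG-level noise,
Bluetooth-style dropouts beyond the configured gaps, circadian drift of
resting heart rate, atypical ward days (weekends, medical events),
intensity differences between walking bouts and other daytime activity,
and any correlation between age and FIM. Recovery results certify the
pipeline's correctness under the stated model, not device-level validity.

## Problem sizes and reproducibility

The test-suite and acceptance harnesses run at sizes chosen to keep the
full suite in a few minutes while preserving the quantities under test:
intensity recovery uses 20 seeds × one 24-h day at the full 25 Hz
(medians over seeds, ±0.5 %HRR point tolerance); the cohort
structure-recovery harness uses 20 seeds × 11 patients × 24 h at 5 Hz
accelerometry, since rank correlations of daily MSDA are invariant to the
sampling rate; the type-I-error simulation uses 2,000 null cohorts of
n = 11. `scripts/acceptance.R` re-runs the intensity recovery end to end
from a command-line seed.

## Known limitations

- The posture classifier assumes the device's longitudinal axis is worn
  along the trunk; a rotated or loosely worn strap degrades the lying
  threshold.
- Walking detection needs the cadence band below the Nyquist frequency;
  at accelerometer rates under ~4 Hz it degrades to "no walking" rather
  than guessing.
- MSDA units are device-relative (see the calibration constant); absolute
  comparisons across devices require an external calibration.
- Resting heart rate assumes the patient actually lies down during
  00:00–05:00; the loud failure path is the intended behaviour for
  patients who do not.
- The statistics stage implements the paired design only — no longitudinal
  modelling beyond admission vs 4 weeks.
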