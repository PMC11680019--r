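---
title: "Estimating peripheral hemodynamics from dual-wavelength photoplethysmograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating peripheral hemodynamics from dual-wavelength photoplethysmograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppghemo)
```

## The measurement model

A reflective PPG sensor at the finger base records light absorption at two
wavelengths. Green light (~525 nm) is absorbed strongly and, with a short
LED–photodiode separation, returns information from the superficial capillary
bed only; near-infrared light (~940 nm) penetrates deeper and, with a longer
separation, is dominated by arterioles at ≥ 0.3 mm depth. Both channels see
the same cardiac pulse, but the green channel sees it *later*: the pulse wave
still has to travel from arterioles into the capillaries. That transit shows
up as a delay of the green acceleration-plethysmogram a-wave behind the
near-infrared one.

Two quantities summarize peripheral hemodynamics per record:

* `inv_fwhm_vpg` (s⁻¹) — the reciprocal full width at half maximum of the
  systolic VPG peak. Steep upstrokes (healthy, well-pressurized capillaries)
  give narrow VPG peaks and large values; in the reference data it is
  roughly proportional to wrist systolic pressure within a subject and falls
  under vasoconstriction (cooling).
* `delay_green_nir` (s) — per-beat a-wave delay, aggregated per record. The
  Bramwell–Hill relation `PWV² = ΔP·V/(ρ·ΔV)` links a lower path pulse
  pressure to a slower pulse wave, hence a longer delay; the path length
  itself is unmeasurable, so the delay substitutes for a peripheral PWV.

The companion features `a/S`, `(a−b)/(a−d)` and `1/ab` time also index
upstroke steepness and are computed for completeness; `S` itself depends on
sensor contact pressure, so its absolute value is not comparable across
records (its reciprocal is still exported per record).

## Processing pipeline and its parameters

1. **Band-pass 0.5–20 Hz** (`filter_spec()`): 2nd-order Butterworth applied
   forward–backward. Only the cutoffs are prescribed by the protocol; the
   realization is ours. Zero-phase filtering is essential here: any phase lag
   would bias the inter-channel delay, and applying identical coefficients to
   both channels cancels residual effects. The channel mean is removed before
   filtering and signals are reflection-padded (~3 s) to tame edge
   transients of the 0.5 Hz high-pass.
2. **Differentiation** (`differentiate_smooth()`): central difference scaled
   to units/s, then a centred moving average, default 50 ms (odd sample
   count, reflection padding, length-preserving). The derivative scheme is
   symmetric, so it adds no phase lag either. Applied once for the VPG,
   twice for the APG.
3. **Beat segmentation** (`segment_beats()`): local VPG maxima above 45% of
   the 98th percentile, a 300 ms refractory period (taller peak wins), then a
   backward search for the preceding PPG minimum. Interval spacing outside
   the heart-rate bounds (default 30–180 bpm) marks the enclosed beat
   invalid; fewer than two beats flags the record instead of erroring.
4. **Fiducials** (`detect_fiducials()`): per beat, the slope-corrected pulse
   height `S` (maximum above the line joining the bounding minima), the VPG
   peak and its half-maximum width (linear interpolation at the crossings),
   and the APG a–e waves. The a-wave is the largest *interior local maximum*
   of the APG in the systolic-rise window — the beat-delimiting valley has
   strong positive curvature of its own and must not be mistaken for an
   a-wave — and all peak times are refined by 3-point parabolic
   interpolation, because delays of a few milliseconds approach the sample
   period. A beat whose a–b interval falls outside 10–450 ms is treated as a
   detection failure (pure-noise beats produce near-adjacent extrema).
   APG validity is tracked separately from basic beat validity: a beat with
   no clean a/b pair still contributes `S` and `inv_fwhm_vpg`.
5. **Delay pairing** (`channel_delay()`): each near-infrared a-peak is paired
   with the nearest green a-peak within ±0.3 s (under half the shortest
   plausible beat period; ties go to the earlier green peak). The record
   summary is the median by default — the delay varies considerably from
   beat to beat, and the median resists outlier beats; the mean is available
   by configuration.
6. **Record aggregation** (`aggregate_record()`): per-feature median (or
   mean) over valid beats.

All parameters live in one `pipeline_config` object (`default_config()`,
YAML-serializable) and are validated against the operations' preconditions at
load time.

## Quality control

The signal intensity is the pulse height `S`; the noise intensity is the RMS
of what remains after removing the repeating pulse component; their ratio is
the SNR, and a record is excluded when the SNR of any analyzed channel is
*strictly* below 200 (a record at exactly 200 is kept), when wrist blood
pressure is missing, or when the key features could not be computed.

The pulse component is estimated as an ensemble-average beat template. The
design detail that matters is alignment: templates anchored on PPG minima
inherit the sample-quantization jitter of a flat valley, and at a systolic
upstroke slope of order `S/σ` even a half-sample misalignment produces
residuals far above a realistic noise floor — the estimator would report
beat-timing artifacts, not noise. `noise_rms()` therefore anchors beats on
their VPG maxima, searches a small integer lag by normalized correlation,
and fits each beat with an offset, a linear trend, the template and the
template derivative (a first-order model of any remaining sub-sample shift);
the pooled, degrees-of-freedom-corrected residual SD is the noise estimate.
The template window covers the systolic-dominant ~60% of the beat
(−0.15 to +0.45 periods around the anchor); late diastole is excluded
because its content depends on the neighbouring beat's timing, which is
heart-rate variability, not sensor noise. On simulated records this
estimator returns the injected white-noise SD within a few percent across
the relevant range of pulse shapes and rates.

## The synthetic-data generator

No public recordings exist for this protocol, so validation rests on a
simulator whose ground truth is known exactly.

**Beat template.** The beat is defined in the *velocity* domain: an
asymmetric systolic bump (rise width `sigma_rise`, fall width
`fall_ratio × sigma_rise`, default ratio 1.6), a small dicrotic bump, and a
broad negative decay lobe whose area is fixed by the constraint that each
beat return to baseline. The PPG is the closed-form integral (Gaussian
CDFs), so the waveform can be evaluated at arbitrary real times — channel
delays are true fractional-sample shifts, not integer approximations. The
velocity-domain construction is deliberate: a symmetric PPG-domain bump
yields an APG whose b-trough is *deeper* than its a-peak
(`|b|/|a| = fall_ratio` would be ~2.2), which is unphysiological and breaks
the normalized a–b feature; here `|b|/|a| = 1/fall_ratio ≈ 0.6` and the
a, b, c, d wave ordering and polarities match clinical APG morphology.
The VPG FWHM is ≈ `sqrt(2 ln 2) · sigma_rise · (1 + fall_ratio)`, so
`sigma_rise` is the steepness dial; diastolic timing scales with the mean
beat period (diastole, not systole, absorbs heart-period variation).

**Calibration.** `calibrate_shape()` inverts the map from `sigma_rise` to
*pipeline-measured* `inv_fwhm_vpg` (the filter broadens narrow peaks, so the
map must be measured through the full pipeline, not computed analytically).
The map is tabulated once per condition at canonical conditions (70 bpm,
1000 Hz), inverted by monotone spline and polished by secant steps to within
0.5%. Achievable targets span roughly 2.5–18 s⁻¹. Calibration transfers
across the preset heart-rate range with < 1% bias for targets ≥ 6 s⁻¹,
growing to a few percent at the slow-upstroke/fast-rate corner. At extremely
low targets (~3 s⁻¹, below any value in the reference cohorts) systole fills
~40% of the cycle and the APG no longer has a separable a-wave; such records
yield no delay and are flagged by QC as feature failures — the same category
the clinical protocol used for uncomputable features.

**Record synthesis** (`simulate_record()`): near-infrared = beat sequence
(periods jittered by `hrv_cv`, default 3%) + baseline offset + sinusoidal
drift + white noise; green = the same beats evaluated at times shifted by
the per-beat true delay (record-level delay plus Gaussian jitter, default
SD 3 ms), independently noised. Defaults describe a clean resting recording:
30 s at 1000 Hz (so ms-scale delays are resolvable), 70 bpm, pulse amplitude
1000 a.u. on a 2000 a.u. baseline, noise SD 1.5 a.u. (SNR ≈ 650). Motion
artifacts (tapered random-walk bursts) are available but off by default.
Identical seeds give bit-identical records.

**Group presets** (`group_preset()`): record-level `inv_fwhm` and `delay`
are log-normal — both quantities are positive with right-skewed reported
ranges. Parameters are calibrated so the population mean equals the reported
group mean exactly (diabetes 5.6 s⁻¹ / 0.028 s; control 7.9 s⁻¹ / 0.012 s)
and the reported group minimum–maximum sits near the central ~95% of the
distribution, consistent with the reported sample sizes (50 and 21 kept
datasets). Wrist systolic pressure is normal (diabetes 134 ± 14 mmHg,
control 117 ± 10 mmHg — the diabetes group's pressures ran higher) and heart
rate normal (74/72 ± 7 bpm, truncated to 50–95); these two are not reported
as distributions and are our choice of realistic resting values.

**Cohort sampling** (`simulate_cohort()`): per-record parameters are drawn
by stratified (Latin-hypercube) sampling of the preset quantiles — each
record occupies one quantile stratum per parameter, in independent random
order. The marginal distribution is exactly the preset's, but a finite
cohort of 21 or 50 records realizes the calibrated mean and range instead of
adding Monte-Carlo noise on top of them; the generator's purpose is to
reproduce the reported group structure at the reported sample sizes.
Records are treated as independent; the within-subject repeat structure of
the clinical data (up to eight records per patient) is not reported and is
not modelled — a known limitation.

## Statistical choices

Comparisons use Welch's unequal-variance *t*-test on record-level values:
the reported group spreads are plainly unequal, the analysis unit in the
reference is the dataset (record), and no test is named in the protocol; the
textbook Satterthwaite formula serves as an independent oracle in the test
suite. Degenerate inputs (both groups constant and equal) return p = 1 by
convention. The hydrostatic subset helper selects subjects whose wrist
pressures obey the strict ordering navel > chest > forehead across the three
measurement heights; the additional "minimal overlap when plotted" criterion
used for figure legibility is subjective and deliberately not implemented.
The Bramwell–Hill helper converts mmHg at 133.322 Pa/mmHg.

## Numerical notes

* Half-maximum crossings: linear interpolation between adjacent samples;
  validated against a 16× spline-resampled brute-force search to < 0.5 ms.
* Peak times: 3-point parabolic refinement, clamped to ±half a sample.
* Beat boundaries in flat inter-beat valleys are only defined to within the
  valley width; all features that matter are anchored on sharp landmarks
  (VPG maxima, APG peaks), so this does not propagate.
* Degenerate inputs (constant signals, pure noise, < 2 beats, empty pairing)
  flag results rather than raising errors; configuration errors raise
  immediately and name the offending parameter.

## What the tests do and do not show

The suite validates every operation against closed forms, hand arithmetic,
brute-force oracles and generator ground truth, and the acceptance layer
checks that simulated cohorts at the reported sizes (50 diabetes / 21
control, 30 s records at 1000 Hz) reproduce the reported group means within
±10%, the group direction, and Welch p < 0.001 (the significance/direction
replication runs on 100 seeded draws of the record-level distributions, with
full-pipeline replication at cohort scale; pipeline measurement error is
bounded separately at < 3% for `inv_fwhm_vpg` and < 1.5 ms for the delay
over a 3–15 s⁻¹ × 3–73 ms grid). Problem sizes in the routine suite are
chosen to exercise every code path at comfortable statistical power — they
are simulation-design choices, not physical constants.

Passing these tests shows the *pipeline* is correct and unbiased under the
generator's assumptions. It does not validate the physiological claims: the
simulator has no optical tissue model (wavelength labels are semantic), no
reflected-wave physics beyond a fixed dicrotic bump, independent records
instead of repeated measures, and stationary noise. Real-world effects such
as contact-pressure drift, arrhythmia, or motion artifacts beyond the simple
random-walk model will stress the QC layer in ways the simulation only
sketches.
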