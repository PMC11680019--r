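# ppghemo

Peripheral hemodynamic feature extraction from multi-wavelength finger
photoplethysmograms (PPG).

## The problem

Diabetes impairs blood circulation in the smallest vessels — arterioles and
capillaries — but no everyday device measures peripheral hemodynamics at home.
A finger-worn optical sensor records PPG at two wavelengths that probe
different depths: green light (~525 nm) is strongly absorbed and carries
mostly superficial **capillary** information, while near-infrared light
(~940 nm) penetrates to the deeper **arterioles**. Two waveform features
separate diabetic from non-diabetic circulation:

- **1/FWHM_VPG** — the reciprocal of the full width at half maximum of the
  systolic peak of the *velocity plethysmogram* (VPG, the first derivative of
  the PPG). It indexes the steepness of the pulse upstroke and tracks the
  local pulse pressure; it is lower when capillary perfusion pressure is low.
- **Green-vs-NIR a-wave delay** — the lag of the green-channel a-wave (the
  first positive peak of the *acceleration plethysmogram*, APG, the second
  derivative) behind the near-infrared a-wave. It acts as a pulse transit
  time from arterioles to capillaries; by the Bramwell–Hill relation
  `PWV² = ΔP·V / (ρ·ΔV)` a lower perfusion pressure means a slower pulse
  wave and a longer delay.

In the reference cohorts, 1/FWHM_VPG (green) averages 5.6 s⁻¹ (range
4.1–9.6) in the diabetes group versus 7.9 s⁻¹ (5.2–14.1) in controls, and
the a-wave delay averages 0.028 s (0.006–0.073) versus 0.012 s
(0.003–0.021), both differences highly significant.

`ppghemo` implements the complete processing chain for whoever wants to
reproduce, stress-test or extend this kind of analysis:

1. **Signal processing** — 0.5–20 Hz zero-phase Butterworth band-pass
   (identical coefficients on every channel, so inter-channel timing is
   untouched), central-difference differentiation with centred moving-average
   smoothing to obtain VPG and APG, beat segmentation anchored on VPG maxima,
   and a DC-component (slow baseline) extractor.
2. **Fiducials and features** — slope-corrected pulse height *S*, APG a–e
   waves with sub-sample (parabolic) peak timing, FWHM_VPG by half-maximum
   interpolation, `a/S`, `(a−b)/(a−d)`, `1/ab` time, and the per-beat paired
   green-vs-NIR a-wave delay.
3. **Quality control** — the SNR is pulse height *S* divided by the residual
   RMS after subtracting an ensemble beat template; records with SNR < 200,
   missing wrist blood pressure, or uncomputable features are excluded.
4. **Statistics** — group summaries, Welch *t* comparisons, hydrostatic
   (measurement-height) subset selection, and a Bramwell–Hill PWV helper.
5. **Simulator** — a calibrated dual-wavelength synthetic PPG generator with
   per-beat ground truth (true 1/FWHM, true delay, injected noise), including
   group presets matched to the reported diabetes/control distributions, so
   every stage is testable without clinical recordings.

## Worked example

Simulate a 30 s dual-channel record with known ground truth (true
1/FWHM = 6.5 s⁻¹, true delay = 25 ms, noise SD 1.5 a.u.) and run the full
pipeline:

```r
library(ppghemo)
sim  <- simulate_record(sim_config(duration = 30, target_inv_fwhm = 6.5,
                                   channel_delay = 0.025, seed = 42))
proc <- process_record(sim$record)
proc
#> <processed_record> 34 beat(s), 1/FWHM 6.503 1/s, delay 0.0257 s, SNR 648.4
proc$features[c("S", "a_over_S", "inv_fwhm_vpg", "inv_ab_time",
                "delay_green_nir", "n_beats")]
#>         S a_over_S inv_fwhm_vpg inv_ab_time delay_green_nir n_beats
#> 1 976.265  67.2933       6.5032      7.0666          0.0257      34
proc$qc[c("S", "noise_rms", "snr")]
#>        S noise_rms    snr
#> 1 976.27      1.51 648.36
```

The pipeline recovers the injected values: 1/FWHM 6.503 vs 6.5 true, delay
25.7 ms vs 25 ms true (the per-beat delay is jittered around the target),
and the noise estimate 1.51 vs 1.5 injected, giving SNR ≈ 648 — well above
the 200 exclusion threshold.

Cohort-level comparison from the calibrated group presets:

```r
diab <- simulate_cohort(group_preset("diabetes"), 10, seed = 1, duration = 20)
ctrl <- simulate_cohort(group_preset("control"), 10, seed = 2, duration = 20)
tab  <- rbind(apply_exclusions(process_cohort(diab))$kept,
              apply_exclusions(process_cohort(ctrl))$kept)
summarize_group(tab, "diabetes", "inv_fwhm_vpg")
#>      group      feature  n     mean      min      max
#> 1 diabetes inv_fwhm_vpg 10 5.699482 4.142429 8.071471
compare_groups(tab, "delay_green_nir")
#>           feature        t       df    p_value mean_diabetes mean_control
#> 1 delay_green_nir 2.890022 10.39639 0.01551292     0.0282462   0.01194506
#>         direction
#> 1 diabetes higher
```

Even at n = 10 per group the diabetic records show the expected lower
1/FWHM_VPG and roughly doubled a-wave delay.

A thin command-line front end wraps the same functions
(`inst/cli/ppghemo.R`, subcommands `simulate`, `process`, `compare`).

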