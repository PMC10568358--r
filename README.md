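# rppgbench

Camera-based pulse extraction and skin-tone agreement benchmarking in R.

Remote photoplethysmography (rPPG) recovers the blood-volume pulse from the
minute colour fluctuations of facial skin in ordinary video. A persistent
question about the technology is whether its accuracy degrades for people
with darker skin tones, whose pulsatile colour fraction is smaller.
`rppgbench` is for researchers and engineers who want to (a) run a complete,
inspectable rPPG pipeline on RGB traces or toy video, and (b) benchmark its
heart-rate and heart-rate-variability estimates against contact-sensor
ground truth with the error statistics stratified by signal quality,
Fitzpatrick skin-tone band and gender.

## What it implements

**Signal path.** Per-frame ROI-averaged RGB traces (forehead + both cheeks,
fused) are converted to a pulse signal by the plane-orthogonal-to-skin (POS)
chrominance projection: within a sliding 1.6 s window the channels are
normalized by their window means, projected onto

    U = Gn − Bn        V = Gn + Bn − 2·Rn

and recombined as `U + α·V` with `α = σ(U)/σ(V)`; mean-removed window
segments are overlap-added into `s_orig`. A single-heartbeat template
(average of the `2K+1`-sample portions of `s_orig` around its detected
peaks, `K = 0.25 s · fs`) then denoises the signal by correlation,

    s_heart[n] = 1/(2K+1) · Σ_{k=−K..K} s_orig[n+k] · t[k],

after a 0.7–7.0 Hz zero-phase band-pass.

**Vitals.** Spectral heart rate (Welch PSD argmax in 42–200 bpm with
parabolic peak interpolation), spectral SNR in dB (fundamental + first
harmonic vs. the rest of 0.5–4 Hz), RR intervals
(`RR(i) = (peak(i+1) − peak(i))/fs × 1000` ms, gated to 300–2000 ms), and
HRV: IBI = mean(RR), SDNN (sample SD), RMSSD (RMS of successive
differences), plus LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) band powers of
the interpolated RR series. Contact-PPG ground truth goes through the
identical code path.

**Benchmark.** Sample-exclusion rules (ground-truth HR stuck at the sensor
error codes 255/129, reference HR ≥ 200 bpm, no confident estimate; plus
PPG-quality rules for the HRV benchmark), subgroup stratification
(all / SNR > 5, 8, 10 dB / Fitzpatrick 1–2, 3–4, 5–6 / gender), and
agreement statistics: MAE, signed mean error, Bland–Altman bias with
±1.96 SD limits of agreement, and OLS best-fit lines, with scatter and
Bland–Altman figures colour-coded by skin-tone band.

**Synthetic cohort generator.** Seeded recordings with exact generating
ground truth: RR series (i.i.d. Gaussian, AR(1) or sinusoidally modulated),
two-Gaussian pulse kernels, skin-tone-dependent RGB traces (pulsatile
amplitude attenuated by `m(FP) = 1 − 0.08·(FP−1)`), illumination drift,
additive noise, optional rendered frame stacks, and per-recording truth HRV
that equals the HRV formulas applied to the generating RR series exactly.

## Worked example

```r
library(rppgbench)

cohort  <- gen_cohort(seed = 1)    # 50 recordings: 25 subjects x 2, 60 s @ 30 fps
records <- cohort_vitals(cohort)   # full pipeline on every recording

mean(abs(records$est_hr   - records$truth_hr))    # 0.459  (bpm)
mean(abs(records$est_ibi  - records$truth_ibi))   # 1.177  (ms)
mean(abs(records$est_sdnn - records$truth_sdnn))  # 9.706  (ms)

usable <- filter_samples(records, mode = "hr")$records   # 47 of 50 confident
benchmark_run(usable, metrics = "hr", ref_prefix = "truth")
```

```
                group n_samples n_subjects    mae      me
1         All samples        47         25 0.3984 -0.0692
2             SNR > 5        27         19 0.2371  0.0661
3             SNR > 8         6          5 0.1660  0.0293
4            SNR > 10         2          2 0.0625 -0.0269
5 Fitzpatrick 1 and 2        18          9 0.4128 -0.1878
6 Fitzpatrick 3 and 4        14          8 0.3842  0.1435
7 Fitzpatrick 5 and 6        15          8 0.3943 -0.1253
8                Male        22         12 0.5482 -0.0807
9              Female        25         13 0.2665 -0.0590
```

Reading the table: over the 47 usable recordings the pipeline's heart-rate
estimates deviate from the generating truth by 0.40 bpm on average, with no
systematic bias (mean error −0.07 bpm), and the three skin-tone bands sit
within a few hundredths of a bpm of each other — under equal noise, skin
tone changes the pulsatile amplitude but not the accuracy. Error shrinks
monotonically as the SNR threshold tightens. `plot_scatter()` and
`plot_bland_altman()` draw the corresponding figures;
`write_report()` serialises detail and summary CSVs.

A command-line front end over the same functions lives at
`inst/cli/rppgbench.R` with `synth`, `vitals` and `benchmark` subcommands.

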