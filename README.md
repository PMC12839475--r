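# pottremor

Quantification of high-frequency (13–18 Hz) orthostatic tremor from short
triaxial accelerometer recordings, for movement-disorder researchers working
with wearable or smartphone accelerometry.

Primary orthostatic tremor (POT) produces a 13–18 Hz leg tremor classically
elicited on standing, but increasingly understood as a response to
load-bearing isometric muscle contraction: applied load (e.g. an
incremental leg-press schedule, seated) elicits the same tremor once a
subject-specific load threshold is crossed, at a frequency matching the
standing tremor, with amplitude growing with load. `pottremor` implements
the accelerometer analysis chain for this phenomenon and the load-response
characterization around it.

## The method

For a 10 s, 200 Hz triaxial recording with axes x(t), y(t), z(t) (m/s²):

1. **Magnitude**: m(t) = √(x² + y² + z²) — orientation-independent tremor
   intensity.
2. **Band-pass**: fourth-order Butterworth, 10–22 Hz, applied
   forward–backward (zero phase).
3. **Spectrum**: one-sided FFT power spectrum of the mean-removed filtered
   magnitude (0.1 Hz resolution at 10 s; Parseval-consistent
   normalization).
4. **Peak**: maximum-power bin in 10–22 Hz → tremor frequency and peak
   height.
5. **Dominance**: power within ±0.3 Hz of the peak divided by total non-DC
   power — near 1 for clear tremor, near 0 for noise. Dominance ≥ 0.5 calls
   the recording tremor-positive.

Across an ascending load schedule, the package estimates the **load
threshold** (smallest load with sustained supra-cutoff dominance at all
heavier loads), checks **frequency stability** against the standing
recording (±0.5 Hz), and measures **amplitude modulation** (Spearman rank
correlation of peak height vs load, with exact permutation p-values for
n ≤ 8). A seeded synthetic-recording generator (gravity + 1/f and white
sensor noise + condition/load-dependent tremor sinusoid) provides ground
truth for validation, including a seven-subject reference cohort preset.

## Worked example

```r
library(pottremor)

prof <- subject_profile("demo", tremor_frequency_hz = 14.31, threshold_kg = 40)
rec  <- simulate_recording(prof, recording_label("demo", "standing"), seed = 3)
analyze_recording(rec)
#> Tremor characterization
#>   recording: demo/standing/left
#>   peak: 14.30 Hz (height 48.11)
#>   dominance: 0.975 -> tremor PRESENT

sim <- simulate_load_series(prof, seed = 5)
analyze_load_series(sim$recordings, standing = sim$standing)
#> Load-series tremor analysis: subject demo, 10 load steps
#>   load threshold: 40 kg
#>   standing frequency: 14.30 Hz; supra-threshold frequency stable: TRUE
#>   amplitude trend (Spearman rho, height vs load): 0.71
```

The peak sits within one FFT bin (0.1 Hz) of the generative 14.31 Hz;
dominance 0.975 means the tremor peak carries ~98% of the filtered signal's
energy; the generative 40 kg threshold is recovered exactly, supra-threshold
frequency stays within 0.5 Hz of standing, and peak height rises with load
(rho = 0.71).

Cohort descriptives (means and sample SDs of age, weight, disease duration,
tremor frequency) come from `summarize_cohort()` on a TSV table; a
seven-patient example table ships in `inst/extdata/pot_cohort.tsv`.

A thin command-line front end is provided in `inst/scripts/tremor.R`
(`analyze`, `loadseries`, `simulate`, `cohort` subcommands).

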