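# phonemark

Voice biomarkers from sustained phonemes for Parkinson's disease (PD)
screening research.

Hypokinetic dysarthria — the speech disorder of PD — shows up in a
sustained vowel at three levels of motor control: unstable respiratory
drive (loudness fluctuation), perturbed vocal-fold vibration (jitter,
shimmer, breath noise) and unstable vocal-tract articulation (formant
fluctuation). phonemark turns a directory of sustained-vowel WAV
recordings into a per-recording table of 17 features spanning those three
levels, compares the patient and control groups with nonparametric
statistics, and evaluates class separation with a Gaussian-kernel SVM
under leave-one-out cross-validation, optionally after Relief-F feature
ranking.

The 17 features per recording:

| family | features |
| --- | --- |
| intensity stability | SD and range of the framewise energy-averaged intensity (dB) |
| glottal perturbation | absolute/relative jitter, dB/relative shimmer, pitch SD, HNR, NHR |
| vocal tract | SD of formants F1–F4; apparent vocal tract length VTL(F1)–VTL(F4) |

The tract features use the closed-tube quarter-wavelength inversion
`VTL(F_i) = (2i − 1)·c / (4·F_i)` with `c = 33,500` cm/s, applied to the
per-recording mean formants from Burg LPC tracking (5.5 kHz ceiling,
25 ms windows every 6.25 ms, pre-emphasis from 50 Hz). Harmonicity comes
from the normalized autocorrelation peak `r0` at the pitch lag:
`HNR = 10·log10(r0 / (1 − r0))`, `NHR = 1 − r0`.

Clinical voice corpora are typically available on request only, so the
package ships a source–filter synthesizer (`synth_spec()`,
`synthesize_vowel()`, `synth_dataset()`) that generates sustained vowels
with exactly known pulse times, periods, amplitudes, formants and noise
level — every stage of the pipeline is testable against ground truth
without any external data.

## Worked example

Synthesize one moderately dysphonic vowel and extract its features:

```r
library(phonemark)

spec <- synth_spec(duration = 0.8, f0 = 110, jitter_rel_target = 0.01,
                   shimmer_rel_target = 0.05, noise_db = -25,
                   tract_length_cm = 16.75, seed = 42)
out <- synthesize_vowel(spec)
out$truth
#> <synth_truth: 87 cycles, jitter_rel 0.0102, shimmer_rel 0.0503, tract 16.75 cm>

round(extract_features(out$audio), 4)
#>    intensity_sd intensity_range      jitter_abs      jitter_rel      shimmer_db
#>          0.5638          2.2805          0.0001          0.0111          0.4483
#>     shimmer_rel        pitch_sd             hnr             nhr           sd_f1
#>          0.0520          1.0671         14.9733          0.0308          6.0686
#>           sd_f2           sd_f3           sd_f4          vtl_f1          vtl_f2
#>         10.8852         10.0599         14.0215         16.9005         16.5029
#>          vtl_f3          vtl_f4
#>         16.7065         16.7186
```

The extracted relative jitter (0.0111) and shimmer (0.0520) recover the
realized ground truth (0.0102, 0.0503) of the emitted pulse sequence, and
all four apparent vocal tract lengths sit within ~1% of the 16.75 cm
synthesis tube.

A full synthetic two-class run (control-like vs PD-like presets, glottal
feature set):

```r
res <- run_pipeline(run_config(n_per_class = 6, feature_set = "glottal",
                               seed = 7))
res$report
#> Leave-one-out Gaussian-SVM classification
#>   samples: 12  (TP 6, TN 6, FP 0, FN 0)
#>   accuracy 100.0%  sensitivity 100.0%  specificity 100.0%

head(res$stats[, c("feature", "mean_co", "mean_pd", "p_value", "effect_size")], 4)
#>           feature      mean_co      mean_pd     p_value effect_size
#> 1    intensity_sd 4.419692e-01 5.006003e-01 0.132034632  -0.9836748
#> 2 intensity_range 1.874763e+00 2.004575e+00 0.309523810  -0.8689784
#> 3      jitter_abs 4.111758e-05 6.524278e-05 0.004329004  -4.4536725
#> 4      jitter_rel 5.134872e-03 8.809624e-03 0.002164502  -8.4741144
```

`p_value` is the two-sided Mann–Whitney U test between groups and
`effect_size` is Glass's delta (control SD as denominator; negative when
the PD-like group is higher). The synthetic classes are far cleaner than
clinical cohorts, hence the perfect separation here.

For real data, lay recordings out as
`<root>/<group>/<subject>/<phoneme>_<rep>.wav` (groups `CO` and `PD`) and
pass `input_dir` to `run_config()`, or use the thin CLI in
`exec/phonemark` (`phonemark run --in <root> --out results/`).

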