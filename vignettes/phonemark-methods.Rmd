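---
title: "Voice biomarkers from sustained phonemes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice biomarkers from sustained phonemes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonemark)
```

## The problem

Hypokinetic dysarthria — the speech impairment of Parkinson's disease (PD)
— disturbs three levels of speech-production control: respiratory drive
(unstable loudness), vocal-fold vibration (period and amplitude
perturbation, breath noise), and vocal-tract articulation (unstable
formants). phonemark extracts one feature family per level from sustained
vowel recordings and evaluates how well they separate PD voices from
controls with nonparametric statistics and a leave-one-out SVM. Because
clinical voice corpora are distributed on request only, the package also
contains a synthesizer that generates sustained vowels with exactly known
ground truth, so every stage of the pipeline is testable end to end.

## Feature definitions

All features are computed on a recording standardized by the front end:
the central `0.5` s of the recording, band-passed with a causal 4th-order
Butterworth filter, 50 Hz–4 kHz. Formant analysis is the one exception
(below).

**Intensity stability.** The framewise intensity is the energy average in
decibels, $I = 10\log_{10}(\overline{s^2}/p_0^2)$ with $p_0 = 2\times
10^{-5}$, on 32 ms frames every 8 ms. The features are the SD and the
range of the contour; both are invariant to the reference and to overall
gain, so the choice of $p_0$ is cosmetic.

**Glottal perturbation.** Pulse detection yields cycle times $t_i$, periods
$T_i = t_{i+1}-t_i$ and per-cycle peak amplitudes $A_i$. The measures are

* absolute jitter $\frac{1}{N-1}\sum |T_{i+1}-T_i|$ and relative jitter
  (the same normalized by $\bar T$),
* shimmer in dB $\frac{1}{N-1}\sum |20\log_{10}(A_{i+1}/A_i)|$ and
  relative shimmer $\frac{1}{N-1}\sum|A_{i+1}-A_i| / \bar A$,
* the SD of the instantaneous pitch $f_{0i} = 1/T_i$,
* HNR and NHR from the normalized autocorrelation peak $r_0$ at the pitch
  lag: $\mathrm{HNR} = 10\log_{10} \frac{r_0}{1-r_0}$,
  $\mathrm{NHR} = 1-r_0$. Frame values of $r_0$ (40 ms frames, 75%
  overlap) are averaged in the correlation domain and converted once, so
  $\mathrm{NHR} = 1/(1+10^{\mathrm{HNR}/10})$ holds exactly on every
  output. Averaging in dB would break that identity.

**Vocal tract.** Formants are tracked by Burg autoregressive modelling
with a 5.5 kHz ceiling, 25 ms Gaussian windows every 6.25 ms, and
pre-emphasis from 50 Hz, after resampling to twice the ceiling. Candidate
poles below 90 Hz or with bandwidth above 400 Hz are discarded; the lowest
four survivors are $F_1\ldots F_4$. Each recording contributes the
per-formant SD and the four apparent vocal tract lengths
$$\mathrm{VTL}(F_i) = (2i-1)\,\frac{c}{4\,F_i},\qquad c = 33{,}500\ \mathrm{cm/s},$$
the closed-tube quarter-wavelength inversion applied to the per-recording
mean formants. The four estimates agree only for a uniform tract; their
spread is informative in itself.

### Pulse detection

Cycle marking is a two-stage procedure. A framewise normalized
autocorrelation tracker (40 ms frames, lags restricted to the 75–500 Hz
search range) gives a smooth period contour and a voicing decision; if
fewer than half the frames are periodic the segment is rejected as
unvoiced. Pulse instants are then walked outward from the strongest crest:
each next pulse is located by maximizing the normalized cross-correlation
between the waveform chunk around the current pulse and the signal one
period away, with parabolic sub-sample interpolation. We chose shape
alignment over single-crest picking deliberately: when jitter perturbs the
interference pattern between resonance ring-downs, the tallest crest hops
between candidates one $1/F_1$ apart, which wrecks both jitter and shimmer;
shape alignment is immune because consecutive cycles remain near-copies of
each other. Cycles whose period strays more than 30% from the local running
median are discarded, which also suppresses octave errors. $A_i$ is the
peak absolute sample over the first three quarters of cycle $i$ — the last
quarter is excluded because the next pulse's onset rises inside it and
would contaminate $A_i$ with $A_{i+1}$.

## The synthesizer

The generator is a source–filter model rendered pitch-synchronously:

1. A differentiated Rosenberg glottal pulse (open quotient 0.6, speed
   quotient 2.5) is shaped by a cascade of second-order resonators. For a
   tube specification the resonances are the odd quarter-wave series of the
   stated length; for an explicit formant list the list is continued at its
   mean spacing. In both cases the cascade includes all resonances up to
   0.95 of Nyquist, not only the four reported formants: truncating the
   series removes the rising skirts of the higher poles and starves the
   upper formants of energy (the classic higher-pole correction). The first
   four bandwidths default to 80 Hz, a typical speech value.
2. The response is faded out inside one nominal period (cosine fade between
   0.6 and 0.95 $T_0$) and scaled copies are overlap-added at the pulse
   times, with two-tap fractional-delay placement so event times are not
   quantized to the sample grid. The fade is essential for a usable ground
   truth: with free-running ring-down, consecutive cycles interfere and the
   realized per-cycle peak amplitude differs from the declared $A_i$ by
   several percent once jitter randomizes the interference phase.
3. Cycle periods are $(1/f_0)(1+s\,\varepsilon_i)$ with
   $\varepsilon_i$ zero-mean truncated Gaussian ($\pm3\sigma$) and $s$
   solved in closed form so the realized relative jitter of the emitted
   sequence equals the target exactly; amplitudes are calibrated the same
   way for shimmer. The `synth_truth` record stores the emitted sequence
   and its realized jitter/shimmer recomputed with the package's own
   measures, so truth and measurement can never drift apart.
4. Aspiration noise is white Gaussian passed through the same resonator
   cascade — it is injected at the glottis physically, and shaping it keeps
   the harmonic-to-noise balance roughly uniform across the formant bands.
   Unshaped broadband noise would bury $F_4$ under a floor no real
   recording has, and band-limiting it with a sharp edge inside the LPC
   band creates a spectral shelf that Burg modelling mistakes for a
   resonance. The noise level is set relative to the harmonic RMS
   (`noise_db`) and controls the extracted HNR monotonically.
5. A linear-in-dB gain ramp spanning `intensity_drift_db` emulates unstable
   respiratory drive, and the waveform is peak-normalized to 0.95.

The class presets shift the PD-like voice toward higher jitter (0.008 vs
0.005), shimmer (0.06 vs 0.045), noise (−21 vs −26 dB) and drift (2.5 vs
1.5 dB) — the direction consistently reported for hypokinetic dysarthria.
The magnitudes are generator conventions chosen to be plausible for
moderate dysphonia; they are not claimed to reproduce any clinical cohort,
and nothing downstream depends on their exact values. What passing tests on
synthetic data do show is that the extraction chain recovers known
perturbation, tract length and noise ordering; what they cannot show is
robustness to room acoustics, microphone coloration, vocal fry, diplophonia
or onset/offset instability, none of which the generator emulates.

## Statistics

Group screening uses the Anderson–Darling normality test per feature and
group (statistic with the small-sample correction
$A^{*2} = A^2(1+0.75/n+2.25/n^2)$, 5% critical value 0.752), the two-sided
Mann–Whitney U test for group differences (exact by enumeration when
$n_x+n_y \le 12$ without ties, otherwise the normal approximation with tie
and continuity corrections), and Glass's delta
$(\bar x_{CO}-\bar x_{PD})/s_{CO}$ as effect size. Glass's delta was
chosen over Cohen's d because only the former reproduces the published
effect-size columns from their printed group summaries; its sign is
positive when controls exceed patients, so perturbation features yield
negative values. Summary-level pooled t-tests and one-way ANOVA are
provided to reproduce demographic tables reported as mean ± SD; with two
equal-size groups the pooled and Welch statistics coincide, which is why
pooled was adopted. One printed demographic SD (female PD age, 72.66) is
inconsistent with its published ANOVA p-value and is presumably a typo for
≈7.66; the age ANOVA is therefore not used as a reproduction check. No
multiple-testing correction is applied by default, matching the original
analysis; `group_stats_table(p_adjust = "holm")` enables one.

## Classification

Relief-F (binary form, `k = 10` nearest hits/misses on min–max scaled
features, Euclidean distances) ranks features; ties break alphabetically so
the ranking is deterministic. The classifier is an SVM with Gaussian kernel
under leave-one-out cross-validation; features are z-scored with training
fold statistics only, so the scaler cannot leak the held-out label. The
kernel width defaults to $1/p$ on standardized features and the cost to 1;
the original study states neither, so results on real data will vary with
these and both are exposed. Each repetition of a phoneme is one sample, and
multi-vowel inputs are built by concatenating phoneme-prefixed features per
(subject, repetition); a leave-one-subject-out variant would be
methodologically safer with repeated measures and is noted as future work.
Metrics are accuracy, sensitivity and specificity in percent with PD as
the positive class.

## Numerical and design choices

* Trim position: the central 0.5 s, on the stationarity argument for
  sustained vowels; whether the original front end trimmed from onset or
  center is not stated anywhere we could verify.
* Filtering is causal by default (`zero_phase = TRUE` is available);
  formant analysis runs on the trimmed but *unfiltered* signal with its own
  pre-emphasis front end, because a 4 kHz band edge contradicts a 5.5 kHz
  formant ceiling — with the band-pass applied, $F_4$ of a short tract is
  simply removed.
* LPC order defaults to 12, two poles per resonance for up to six
  resonances under the 5.5 kHz ceiling (a 19 cm tract has six); order 10
  cannot represent them together with spectral tilt and biases
  $F_2$–$F_4$ upward by several percent.
* The printed intensity equation in the source material is typographically
  garbled; the implementation uses the standard energy-averaging formula,
  and since SD and range are reference-invariant the substitution cannot
  affect any feature value.
* Degenerate inputs raise classed conditions (`phonemark_unvoiced`,
  `phonemark_too_short`, `phonemark_formant_failure`, ...) rather than
  NA-filled rows; the pipeline logs every skipped recording with its
  reason.

## Problem sizes

The bundled checks run the synthesizer at 44.1 kHz with 0.8 s vowels:
a 3 × 2 jitter/shimmer grid with five seeds per cell, tract lengths
{12, 14, 16.75, 19} cm averaged over three speaker-like $f_0$ values and
two seeds, four noise levels with three seeds, and synthetic two-class
cohorts of 8–20 subjects per class for the classifier checks. These sizes
were chosen so the whole battery completes in minutes on one core while
keeping seed-averaged recovery errors well inside their tolerances; larger
cohorts change none of the conclusions, only the runtime.

## Known limitations

Recovery tolerances are calibrated for adult sustained vowels (75–500 Hz
pitch range); very high fundamentals shorten the cycle relative to the
pulse response and degrade both the in-cycle fade and formant resolution.
The uniform-tube interpretation of VTL is a modelling convenience — real
tracts are non-uniform, which is exactly why the four per-formant estimates
disagree on real speech. Classification hyperparameters are fixed rather
than tuned; on clinical data a nested search and subject-level
cross-validation would both be advisable before any claim of diagnostic
accuracy.
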