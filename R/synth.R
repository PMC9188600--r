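# Source-filter synthesizer for sustained vowels with known ground truth.
#
# A differentiated-Rosenberg glottal pulse is shaped by a cascade of
# second-order formant resonators (at explicit formants or at the
# odd-quarter-wave resonances of a uniform tube), and scaled copies of the
# response are overlap-added pitch-synchronously at the perturbed pulse
# times; resonator-shaped aspiration noise and a slow gain ramp complete the
# signal. Cycle periods and amplitudes carry calibrated perturbation so the
# realized jitter and shimmer of the emitted pulse sequence are known
# exactly.

SPEED_OF_SOUND_CM_S <- 33500  # speed of sound used for the closed-tube model

#' Resonance frequencies of a uniform closed-open tube
#'
#' A uniform tube of length `L` closed at one end resonates at odd quarter
#' wavelengths: `F_i = (2i - 1) c / (4 L)` with `c` = 33,500 cm/s. This is
#' the forward model whose inversion defines apparent vocal tract length.
#'
#' @param tract_length_cm tube length in cm (> 0).
#' @param n number of resonances to return.
#' @return numeric vector of `n` formant frequencies in Hz.
#' @seealso [vtl_from_formants()] for the inverse map.
#' @export
#' @examples
#' tube_formants(16.75, 4)  # 500, 1500, 2500, 3500 Hz
tube_formants <- function(tract_length_cm, n = 4) {
  if (!is.numeric(tract_length_cm) || length(tract_length_cm) != 1L ||
      !is.finite(tract_length_cm) || tract_length_cm <= 0) {
    pm_stop("`tract_length_cm` must be a single positive number",
            "phonemark_invalid_argument")
  }
  if (n < 1) pm_stop("`n` must be >= 1", "phonemark_invalid_argument")
  i <- seq_len(n)
  (2 * i - 1) * SPEED_OF_SOUND_CM_S / (4 * tract_length_cm)
}

#' Specify a synthetic sustained vowel
#'
#' Collects and validates every knob of the generator. Exactly one of
#' `tract_length_cm` and `formants` must be given.
#'
#' @param duration seconds; at least 0.6 and at least 40 glottal cycles.
#' @param sample_rate Hz.
#' @param f0 fundamental frequency in Hz, within 75--500.
#' @param jitter_rel_target relative cycle-period perturbation in \[0, 0.2\];
#'   the emitted pulse sequence is calibrated so its realized relative jitter
#'   equals this value.
#' @param shimmer_rel_target relative cycle-amplitude perturbation in
#'   \[0, 0.2\], calibrated the same way.
#' @param noise_db aperiodic noise level in dB relative to the harmonic
#'   signal (more negative = cleaner; controls the extracted HNR).
#' @param tract_length_cm uniform-tube length in cm; formants are its odd
#'   quarter-wave resonances.
#' @param formants explicit formant frequencies in Hz (alternative to
#'   `tract_length_cm`).
#' @param bandwidths formant bandwidths in Hz; default 80 Hz each, a typical
#'   speech value.
#' @param intensity_drift_db peak-to-peak slow gain modulation in dB.
#' @param seed integer; all randomness in the generator derives from it.
#' @return a validated object of class `synth_spec`.
#' @export
synth_spec <- function(duration = 0.8, sample_rate = 44100, f0 = 120,
                       jitter_rel_target = 0.005, shimmer_rel_target = 0.04,
                       noise_db = -25, tract_length_cm = NULL,
                       formants = NULL, bandwidths = NULL,
                       intensity_drift_db = 2, seed = 1) {
  if (duration < 0.6) {
    pm_stop("`duration` must be >= 0.6 s", "phonemark_invalid_argument")
  }
  if (f0 < 75 || f0 > 500) {
    pm_stop("`f0` must lie within [75, 500] Hz", "phonemark_invalid_argument")
  }
  if (duration * f0 < 40) {
    pm_stop("`duration` must cover at least 40 glottal cycles",
            "phonemark_invalid_argument")
  }
  for (v in c(jitter_rel_target, shimmer_rel_target)) {
    if (v < 0 || v > 0.2) {
      pm_stop("jitter/shimmer targets must lie in [0, 0.2]",
              "phonemark_invalid_argument")
    }
  }
  if (is.null(tract_length_cm) == is.null(formants)) {
    pm_stop("give exactly one of `tract_length_cm` or `formants`",
            "phonemark_invalid_argument")
  }
  if (!is.null(tract_length_cm)) {
    formants_hz <- tube_formants(tract_length_cm, 4)
  } else {
    formants_hz <- sort(as.numeric(formants))
    if (any(formants_hz <= 0)) {
      pm_stop("formants must be positive", "phonemark_invalid_argument")
    }
  }
  if (any(formants_hz >= sample_rate / 2)) {
    pm_stop("formants must lie below Nyquist", "phonemark_invalid_argument")
  }
  if (is.null(bandwidths)) bandwidths <- rep(80, length(formants_hz))
  # Rendering uses the full resonance series up to ~Nyquist, not only the
  # four reported formants: a truncated all-pole cascade loses the rising
  # skirts of the higher poles and starves the upper formants of energy
  # (the classic higher-pole correction). For a tube these are its true
  # higher resonances; an explicit formant list is continued at its mean
  # spacing. Bandwidths of the continuation grow mildly with frequency.
  f_hi <- numeric(0)
  lim <- 0.95 * sample_rate / 2
  if (!is.null(tract_length_cm)) {
    all_f <- tube_formants(tract_length_cm, ceiling(lim * 4 * tract_length_cm /
                                                      (2 * SPEED_OF_SOUND_CM_S)))
    f_hi <- all_f[all_f > max(formants_hz) & all_f <= lim]
  } else {
    spacing <- if (length(formants_hz) > 1) mean(diff(formants_hz)) else
      2 * formants_hz
    f_hi <- seq(max(formants_hz) + spacing, lim, by = spacing)
  }
  structure(list(duration = duration, sample_rate = sample_rate, f0 = f0,
                 jitter_rel_target = jitter_rel_target,
                 shimmer_rel_target = shimmer_rel_target,
                 noise_db = noise_db, tract_length_cm = tract_length_cm,
                 formants = formants_hz, bandwidths = bandwidths,
                 synth_formants = c(formants_hz, f_hi),
                 synth_bandwidths = c(bandwidths, pmax(80, 0.02 * f_hi)),
                 intensity_drift_db = intensity_drift_db,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("<synth_spec: %.2f s @ %g Hz, f0 %g Hz, jitter %g, ",
                     "shimmer %g, noise %g dB, drift %g dB, seed %d>\n"),
              x$duration, x$sample_rate, x$f0, x$jitter_rel_target,
              x$shimmer_rel_target, x$noise_db, x$intensity_drift_db, x$seed))
  cat("  formants (Hz):", paste(round(x$formants), collapse = ", "), "\n")
  invisible(x)
}

# Truncated standard normal draws (+-3 sigma), zero-centered afterwards so
# the calibration below is exact regardless of truncation asymmetry.
rnorm_trunc3 <- function(n) {
  z <- rnorm(n)
  while (any(bad <- abs(z) > 3)) z[bad] <- rnorm(sum(bad))
  z
}

# Solve for the scale s such that the perturbed sequence x0 * (1 + s*z)
# has relative successive perturbation (mean |diff| over mean level) equal
# to `target`. Closed form from target = s*m_d / (1 + s*m_z).
calibrate_scale <- function(z, target) {
  if (target == 0) return(0)
  m_d <- mean(abs(diff(z)))
  m_z <- mean(z)
  s <- target / (m_d - target * m_z)
  if (!is.finite(s) || s <= 0) {
    pm_stop("perturbation target is not attainable for this draw",
            "phonemark_invalid_argument")
  }
  s
}

#' Generate a perturbed glottal pulse sequence
#'
#' Cycle periods are `(1/f0) * (1 + s * eps_i)` with `eps_i` zero-mean
#' truncated Gaussian and `s` calibrated in closed form so the realized
#' relative jitter of the sequence equals `jitter_rel_target`; cycle
#' amplitudes are perturbed the same way to hit `shimmer_rel_target`.
#' Deterministic under the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return a [pulse_train()] covering `spec$duration`.
#' @export
make_pulse_train <- function(spec) {
  if (!inherits(spec, "synth_spec")) {
    pm_stop("`spec` must be a synth_spec", "phonemark_invalid_argument")
  }
  n_cyc <- ceiling(spec$duration * spec$f0) + 2L
  if (n_cyc < 40L) {
    pm_stop("duration too short for 40 cycles", "phonemark_invalid_argument")
  }
  with_seed(spec$seed, {
    eps <- rnorm_trunc3(n_cyc); eps <- eps - mean(eps)
    eta <- rnorm_trunc3(n_cyc); eta <- eta - mean(eta)
    s_t <- calibrate_scale(eps, spec$jitter_rel_target)
    s_a <- calibrate_scale(eta, spec$shimmer_rel_target)
    periods <- (1 / spec$f0) * (1 + s_t * eps)
    amps <- 1 + s_a * eta
    times <- c(0, cumsum(periods)) + 0.5 / spec$f0
    keep <- times <= spec$duration
    times <- times[keep]
    pulse_train(times, amps[seq_len(length(times) - 1L)])
  })
}

# Differentiated Rosenberg glottal pulse sampled at fs: raised-cosine
# opening phase, cosine closing phase; the closing-edge discontinuity in the
# derivative provides the broadband excitation.
rosenberg_deriv <- function(period, fs, open_quotient = 0.6,
                            speed_quotient = 2.5) {
  t_open <- open_quotient * period
  t_p <- t_open * speed_quotient / (1 + speed_quotient)
  t_n <- t_open - t_p
  tt <- seq(0, t_open, by = 1 / fs)
  g <- ifelse(tt <= t_p,
              0.5 * (1 - cos(pi * tt / t_p)),
              cos(pi * (tt - t_p) / (2 * t_n)))
  d <- diff(c(0, g, 0))
  d / max(abs(d))
}

# One second-order resonator (unit DC gain) per formant, applied in cascade.
apply_resonators <- function(x, formants, bandwidths, fs) {
  for (j in seq_along(formants)) {
    r <- exp(-pi * bandwidths[j] / fs)
    theta <- 2 * pi * formants[j] / fs
    a <- c(1, -2 * r * cos(theta), r^2)
    b <- sum(a)
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Synthesize a sustained vowel with known ground truth
#'
#' Runs the full source-filter chain of the generator and returns both the
#' waveform and a `synth_truth` record holding the emitted pulse times,
#' periods and amplitudes, the formant frequencies, the tube length (if
#' any), and the realized jitter/shimmer of the pulse sequence recomputed
#' with the package's own perturbation measures, so downstream extraction
#' can be scored against exact truth.
#'
#' @param spec a [synth_spec()].
#' @return a list with elements `audio` ([audio_segment()], peak-normalized
#'   to 0.95) and `truth` (class `synth_truth`).
#' @export
synthesize_vowel <- function(spec) {
  pt <- make_pulse_train(spec)
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  # Pitch-synchronous overlap-add rendering: one fixed Rosenberg-derivative
  # pulse per recording is passed through the resonator cascade once, the
  # response is faded out within a single nominal period, and per-cycle
  # scaled copies are placed at the pulse times. A fixed pulse shape keeps
  # the glottal event rigidly attached to the pulse time (a per-cycle-scaled
  # pulse would smear jitter across neighboring periods via the moving
  # closure instant), and the in-cycle fade removes inter-cycle ring-down
  # interference, which would otherwise modulate cycle peaks by several
  # percent under jitter and make the amplitude ground truth ill-defined.
  pulse0 <- rosenberg_deriv(1 / spec$f0, fs)
  t0_n <- round(fs / spec$f0)                  # nominal period in samples
  h_len <- round(0.95 * t0_n)
  h <- apply_resonators(c(pulse0, numeric(max(0, h_len - length(pulse0)))),
                        spec$synth_formants, spec$synth_bandwidths,
                        fs)[seq_len(h_len)]
  tt_h <- seq_len(h_len) / t0_n
  fade <- ifelse(tt_h <= 0.6, 1,
                 0.5 * (1 + cos(pi * (tt_h - 0.6) / 0.35)))
  h <- h * fade / max(abs(h * fade))
  exc <- numeric(n)
  for (i in seq_len(pt$n)) {
    pulse <- h * pt$amplitudes[i]
    # sub-sample placement: split each copy across two adjacent bins so the
    # emitted event time is not quantized to the sample grid (grid rounding
    # alone would inject ~0.1-0.3% spurious jitter)
    pos <- pt$pulse_times[i] * fs
    i0 <- floor(pos) + 1L
    frac <- pos - floor(pos)
    idx <- i0:min(i0 + length(pulse) - 1L, n)
    exc[idx] <- exc[idx] + (1 - frac) * pulse[seq_along(idx)]
    idx2 <- idx + 1L
    keep <- idx2 <= n
    exc[idx2[keep]] <- exc[idx2[keep]] + frac * pulse[seq_along(idx)][keep]
  }
  harm <- exc
  # aperiodic (aspiration) noise is injected at the glottis, so it passes
  # through the same vocal-tract resonators as the pulses; unshaped
  # broadband noise would bury the weak upper formants under a noise floor
  # no real recording has, while shaped noise leaves the harmonic-to-noise
  # balance roughly uniform across the formant bands
  noise <- with_seed(spec$seed + 101L, rnorm(n))
  noise <- apply_resonators(noise, spec$synth_formants, spec$synth_bandwidths, fs)
  hp <- signal::butter(2, 50 / (fs / 2), type = "high")
  noise <- as.numeric(signal::filter(hp, noise))
  rms <- function(v) sqrt(mean(v^2))
  noise <- noise / rms(noise) * rms(harm) * 10^(spec$noise_db / 20)
  x <- harm + noise
  tt <- seq_len(n) / fs
  gain_db <- spec$intensity_drift_db * (tt / spec$duration - 0.5)
  x <- x * 10^(gain_db / 20)
  x <- x / max(abs(x)) * 0.95
  truth <- structure(list(
    pulse_times = pt$pulse_times,
    periods = pt$periods,
    amplitudes = pt$amplitudes,
    formants = spec$formants,
    tract_length_cm = if (is.null(spec$tract_length_cm)) NA_real_ else
      spec$tract_length_cm,
    jitter_abs = jitter_abs(pt),
    jitter_rel = jitter_rel(pt),
    shimmer_db = shimmer_db(pt),
    shimmer_rel = shimmer_rel(pt)), class = "synth_truth")
  list(audio = audio_segment(x, fs), truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(paste0("<synth_truth: %d cycles, jitter_rel %.4f, ",
                     "shimmer_rel %.4f, tract %s cm>\n"),
              length(x$periods), x$jitter_rel, x$shimmer_rel,
              ifelse(is.na(x$tract_length_cm), "-",
                     format(x$tract_length_cm))))
  invisible(x)
}

#' Per-class generator presets
#'
#' Parameter presets for "control-like" and "PD-like" synthetic voices. The
#' PD-like preset raises period/amplitude perturbation, aperiodic noise and
#' intensity drift, the direction consistently reported for hypokinetic
#' dysarthria; the magnitudes are generator conventions, not claims about
#' any clinical cohort.
#'
#' @param class `"control"` or `"pd"`.
#' @return a named list of [synth_spec()] arguments.
#' @export
class_preset <- function(class = c("control", "pd")) {
  class <- match.arg(class)
  if (class == "control") {
    list(jitter_rel_target = 0.005, shimmer_rel_target = 0.045,
         noise_db = -26, intensity_drift_db = 1.5)
  } else {
    list(jitter_rel_target = 0.008, shimmer_rel_target = 0.06,
         noise_db = -21, intensity_drift_db = 2.5)
  }
}

#' Generate a synthetic two-class dataset on disk
#'
#' Writes `n_per_class` control-like and PD-like vowels per phoneme as
#' 16-bit mono WAV files, each with a `.truth.json` sidecar holding its
#' `synth_truth`, laid out as `<root>/<group>/<subject>/<phoneme>_<rep>.wav`.
#' Per-subject fundamental frequency and tract length are drawn around
#' typical adult values so recordings differ across subjects.
#'
#' @param out_dir output directory root.
#' @param n_per_class subjects per class.
#' @param phonemes character vector of phoneme labels.
#' @param n_rep repetitions per subject and phoneme.
#' @param seed master seed.
#' @param duration,sample_rate passed to [synth_spec()].
#' @return a data.frame manifest (one row per written WAV), invisibly.
#' @export
synth_dataset <- function(out_dir, n_per_class = 10, phonemes = "a",
                          n_rep = 1, seed = 1, duration = 0.8,
                          sample_rate = 44100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (grp in c("CO", "PD")) {
    preset <- class_preset(if (grp == "PD") "pd" else "control")
    for (s in seq_len(n_per_class)) {
      sub_id <- sprintf("%s%03d", grp, s)
      sub_seed <- seed * 100000L + (grp == "PD") * 50000L + s * 37L
      draws <- with_seed(sub_seed, list(
        f0 = min(max(rnorm(1, 130, 20), 85), 300),
        tract = min(max(rnorm(1, 16, 1.2), 12), 20)))
      dir.create(file.path(out_dir, grp, sub_id), recursive = TRUE,
                 showWarnings = FALSE)
      for (ph in phonemes) for (rep in seq_len(n_rep)) {
        spec <- do.call(synth_spec, c(list(
          duration = duration, sample_rate = sample_rate, f0 = draws$f0,
          tract_length_cm = draws$tract,
          seed = sub_seed + match(ph, phonemes) * 1000L + rep), preset))
        out <- synthesize_vowel(spec)
        wav <- file.path(out_dir, grp, sub_id, sprintf("%s_%d.wav", ph, rep))
        write_wav(out$audio, wav)
        jsonlite::write_json(unclass(out$truth),
                             sub("\\.wav$", ".truth.json", wav),
                             auto_unbox = TRUE, digits = NA)
        rows[[length(rows) + 1L]] <- data.frame(
          path = wav, group = grp, subject_id = sub_id, phoneme = ph,
          repetition = rep, stringsAsFactors = FALSE)
      }
    }
  }
  invisible(do.call(rbind, rows))
}
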