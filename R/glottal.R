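# Glottal-cycle detection and the periodicity/stability measures defined on
# the resulting pulse sequence: absolute/relative jitter, dB/relative
# shimmer, pitch SD, and autocorrelation-based HNR/NHR.

#' Construct a glottal pulse train
#'
#' @param pulse_times strictly increasing pulse instants in seconds.
#' @param amplitudes per-cycle peak amplitudes (one per period, i.e. one
#'   fewer than `pulse_times`); all positive.
#' @return an object of class `pulse_train` with fields `pulse_times`,
#'   `periods`, `amplitudes` and `n` (number of periods).
#' @export
pulse_train <- function(pulse_times, amplitudes) {
  if (length(pulse_times) < 2L || any(diff(pulse_times) <= 0)) {
    pm_stop("`pulse_times` must be >= 2 strictly increasing values",
            "phonemark_invalid_argument")
  }
  periods <- diff(pulse_times)
  if (length(amplitudes) != length(periods)) {
    pm_stop("need one amplitude per period", "phonemark_invalid_argument")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0)) {
    pm_stop("amplitudes must be positive and finite", "phonemark_invalid_cycle")
  }
  structure(list(pulse_times = as.numeric(pulse_times),
                 periods = as.numeric(periods),
                 amplitudes = as.numeric(amplitudes),
                 n = length(periods)),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train: %d periods, mean f0 %.1f Hz>\n",
              x$n, 1 / mean(x$periods)))
  invisible(x)
}

assert_cycles <- function(pt, n_min = 2L) {
  if (!inherits(pt, "pulse_train")) {
    pm_stop("expected a `pulse_train`", "phonemark_invalid_argument")
  }
  if (pt$n < n_min) {
    pm_stop(sprintf("need at least %d glottal cycles, got %d", n_min, pt$n),
            "phonemark_insufficient_cycles")
  }
  invisible(pt)
}

#' Absolute jitter (seconds)
#'
#' Mean absolute difference between consecutive cycle periods,
#' `mean(|T[i+1] - T[i]|)`.
#'
#' @param pt a [pulse_train()] with at least 2 periods.
#' @return absolute jitter in seconds.
#' @export
jitter_abs <- function(pt) {
  assert_cycles(pt)
  mean(abs(diff(pt$periods)))
}

#' Relative jitter (dimensionless)
#'
#' Absolute jitter normalized by the mean period, so
#' `jitter_rel(pt) * mean(periods) == jitter_abs(pt)` holds exactly.
#'
#' @inheritParams jitter_abs
#' @return relative jitter (dimensionless fraction).
#' @export
jitter_rel <- function(pt) {
  jitter_abs(pt) / mean(pt$periods)
}

#' Shimmer in dB
#'
#' Mean absolute successive amplitude ratio expressed in decibels,
#' `mean(|20 log10(A[i+1]/A[i])|)`.
#'
#' @inheritParams jitter_abs
#' @return shimmer in dB.
#' @export
shimmer_db <- function(pt) {
  assert_cycles(pt)
  mean(abs(20 * log10(pt$amplitudes[-1] / pt$amplitudes[-pt$n])))
}

#' Relative shimmer (dimensionless)
#'
#' Mean absolute successive amplitude difference divided by the mean
#' amplitude.
#'
#' @inheritParams jitter_abs
#' @return relative shimmer (dimensionless fraction).
#' @export
shimmer_rel <- function(pt) {
  assert_cycles(pt)
  mean(abs(diff(pt$amplitudes))) / mean(pt$amplitudes)
}

#' Standard deviation of the instantaneous pitch
#'
#' Sample SD (n-1 denominator) of the per-cycle instantaneous fundamental
#' `f0_i = 1 / T_i`.
#'
#' @inheritParams jitter_abs
#' @return pitch SD in Hz.
#' @export
pitch_sd <- function(pt) {
  assert_cycles(pt)
  sd(1 / pt$periods)
}

# Framewise autocorrelation period estimates. Returns frame centers and the
# best normalized-correlation lag per frame (NA where unvoiced).
frame_periods <- function(x, fs, fmin, fmax, frame_s = 0.04,
                          voicing_threshold = 0.35) {
  step <- round(frame_s * fs * 0.25)       # 75% overlap
  flen <- round(frame_s * fs)
  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- ceiling(fs / fmin)
  starts <- seq(1L, length(x) - flen + 1L, by = step)
  centers <- (starts + flen / 2) / fs
  per <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    fr <- x[starts[k]:(starts[k] + flen - 1L)]
    fr <- fr - mean(fr)
    if (all(fr == 0) || lag_max >= flen) next
    r <- norm_xcorr(fr, lag_min, lag_max)
    j <- which.max(r)
    if (r[j] >= voicing_threshold) {
      lag <- lag_min + j - 1L + parabolic_offset(r, j)
      per[k] <- lag / fs
    }
  }
  list(centers = centers, periods = per)
}

# Normalized cross-correlation of a frame with itself over a lag range:
# r[tau] = sum(x_t x_{t+tau}) / sqrt(sum head^2 * sum tail^2).
# Unlike the biased autocorrelation this stays ~1 for a pure periodic frame.
norm_xcorr <- function(fr, lag_min, lag_max) {
  n <- length(fr)
  vapply(lag_min:lag_max, function(lag) {
    h <- fr[1:(n - lag)]
    t <- fr[(lag + 1):n]
    den <- sqrt(sum(h^2) * sum(t^2))
    if (den == 0) 0 else sum(h * t) / den
  }, numeric(1))
}

# Sub-sample refinement of a discrete peak by parabolic interpolation.
parabolic_offset <- function(r, j) {
  if (j <= 1L || j >= length(r)) return(0)
  denom <- r[j - 1L] - 2 * r[j] + r[j + 1L]
  if (denom == 0) return(0)
  off <- 0.5 * (r[j - 1L] - r[j + 1L]) / denom
  if (abs(off) > 1) 0 else off
}

#' Detect glottal pulses
#'
#' Two-stage pulse marking: (1) framewise autocorrelation pitch tracking
#' (40 ms frames, 75% overlap, lags restricted to `[1/fmax, 1/fmin]`) gives
#' a local period contour; (2) pulse instants are walked outward from the
#' strongest waveform peak, each refined to the parabolic-interpolated local
#' maximum within the predicted cycle window. Per-cycle amplitude is the
#' peak absolute sample within the cycle. Cycles whose period deviates more
#' than 30% from the local running median are discarded (this also guards
#' against octave errors).
#'
#' @param seg a voiced [audio_segment()].
#' @param fmin,fmax pitch search range in Hz (default 75--500).
#' @return a [pulse_train()].
#' @export
detect_pulses <- function(seg, fmin = 75, fmax = 500) {
  assert_segment(seg)
  if (fmin >= fmax) pm_stop("need fmin < fmax", "phonemark_invalid_argument")
  if (duration(seg) < 10 / fmin) {
    pm_stop("segment too short for pitch analysis", "phonemark_too_short")
  }
  x <- seg$samples
  fs <- seg$sample_rate
  fp <- frame_periods(x, fs, fmin, fmax)
  voiced <- !is.na(fp$periods)
  if (mean(voiced) < 0.5) {
    pm_stop("no stable periodicity found: segment appears unvoiced",
            "phonemark_unvoiced")
  }
  # period as a function of time, interpolated across any unvoiced gaps
  period_at <- function(t) {
    approx(fp$centers[voiced], fp$periods[voiced], xout = t, rule = 2)$y
  }
  # cycle marking by waveform-shape alignment (cross-correlation method):
  # successive cycles of a sustained vowel are near-copies of one another,
  # so the lag maximizing the normalized cross-correlation between the
  # chunk around the current pulse and the signal one period away locates
  # the next pulse; single-crest picking instead hops between resonance
  # crests once jitter perturbs their interference pattern
  n <- length(x)
  y <- if (max(-x) > max(x)) -x else x   # dominant-polarity view, seeding
  mid <- floor(n / 3):ceiling(2 * n / 3)
  seed_i <- mid[which.max(y[mid])]
  xcorr_step <- function(t, dir, p) {
    half_t <- round(0.35 * p * fs)            # template half-width
    half_s <- max(3L, round(0.25 * p * fs))   # lag search half-width
    i_t <- round(t * fs)
    i_c <- i_t + dir * round(p * fs)
    lo <- i_c - half_s; hi <- i_c + half_s
    if (i_t - half_t < 1L || i_t + half_t > n ||
        lo - half_t < 1L || hi + half_t > n) {
      return(NA_real_)
    }
    tem <- x[(i_t - half_t):(i_t + half_t)]
    cc <- vapply(lo:hi, function(ic) {
      seg2 <- x[(ic - half_t):(ic + half_t)]
      den <- sqrt(sum(tem^2) * sum(seg2^2))
      if (den == 0) 0 else sum(tem * seg2) / den
    }, numeric(1))
    j <- which.max(cc)
    (lo + j - 1L + parabolic_offset(cc, j)) / fs
  }
  walk <- function(t0, dir) {
    out <- numeric(0)
    t <- t0
    repeat {
      t_next <- xcorr_step(t, dir, period_at(t))
      if (is.na(t_next)) break
      out <- c(out, t_next)
      t <- t_next
    }
    out
  }
  t_seed <- seed_i / fs + parabolic_offset(y, seed_i) / fs
  times <- sort(unique(c(rev(walk(t_seed, -1)), t_seed, walk(t_seed, +1))))
  if (length(times) < 3L) {
    pm_stop("too few pulses detected", "phonemark_unvoiced")
  }
  per <- diff(times)
  # drop cycles straying >30% from the local (running) median period
  med <- stats::runmed(per, k = min(11L, length(per) - (length(per) + 1) %% 2))
  ok <- abs(per - med) / med <= 0.30
  # amplitudes: peak |x| within the first 3/4 of each retained cycle (the
  # following pulse's onset rises inside the last quarter and would
  # contaminate A_i with A_{i+1})
  amp <- vapply(seq_along(per), function(i) {
    i1 <- max(1L, round(times[i] * fs))
    i2 <- min(n, round((times[i] + 0.75 * per[i]) * fs))
    max(abs(x[i1:i2]))
  }, numeric(1))
  ok <- ok & amp > 0 & per > 1 / (fmax * 1.3) & per < 1 / (fmin / 1.3)
  if (sum(ok) < 2L) {
    pm_stop("too few valid cycles after screening", "phonemark_unvoiced")
  }
  # rebuild a train from maximal runs of consecutive valid cycles
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  idx <- starts[best]:ends[best]
  pulse_train(times[c(idx, idx[length(idx)] + 1L)], amp[idx])
}

#' Harmonics-to-noise ratio of a voiced segment
#'
#' Per 40 ms frame (75% overlap) the segment's normalized autocorrelation is
#' evaluated and `r0`, the height of the highest peak at a lag within 20% of
#' the frame's expected period (from the pulse train), is recorded. Frame
#' `r0` values are averaged in the correlation domain, and HNR/NHR follow as
#' `HNR = 10 log10(r0 / (1 - r0))` and `NHR = 1 - r0`, so the identity
#' `NHR = 1 / (1 + 10^(HNR/10))` holds exactly.
#'
#' @param seg a voiced [audio_segment()].
#' @param pt the segment's [pulse_train()] (supplies the expected period).
#' @return an object of class `harmonicity` with fields `hnr_db`, `nhr`,
#'   `r0`, `t0` (seconds).
#' @export
harmonicity <- function(seg, pt) {
  assert_segment(seg)
  assert_cycles(pt)
  x <- seg$samples
  fs <- seg$sample_rate
  flen <- round(0.04 * fs)
  step <- round(0.01 * fs)
  starts <- seq(1L, length(x) - flen + 1L, by = step)
  t_mid <- pt$pulse_times[-length(pt$pulse_times)] + pt$periods / 2
  r0s <- numeric(0)
  lags <- numeric(0)
  for (s in starts) {
    fr <- x[s:(s + flen - 1L)]
    fr <- fr - mean(fr)
    if (all(fr == 0)) next
    t_c <- (s + flen / 2) / fs
    p_exp <- pt$periods[which.min(abs(t_mid - t_c))]
    lag_lo <- max(2L, floor(0.8 * p_exp * fs))
    lag_hi <- min(flen - 2L, ceiling(1.2 * p_exp * fs))
    if (lag_hi <= lag_lo) next
    r <- norm_xcorr(fr, lag_lo, lag_hi)
    j <- which.max(r)
    off <- parabolic_offset(r, j)
    pk <- if (j > 1L && j < length(r)) {
      r[j] - 0.25 * (r[j - 1L] - r[j + 1L]) * off
    } else r[j]
    if (is.finite(pk) && pk > 0 && pk < 1) {
      r0s <- c(r0s, pk)
      lags <- c(lags, (lag_lo + j - 1L + off) / fs)
    }
  }
  if (length(r0s) == 0L) {
    pm_stop("no frame yielded a valid autocorrelation peak in (0, 1)",
            "phonemark_degenerate_signal")
  }
  r0 <- mean(r0s)
  structure(list(hnr_db = 10 * log10(r0 / (1 - r0)),
                 nhr = 1 - r0,
                 r0 = r0,
                 t0 = mean(lags)),
            class = "harmonicity")
}

#' @export
print.harmonicity <- function(x, ...) {
  cat(sprintf("<harmonicity: HNR %.2f dB, NHR %.4f, r0 %.4f, T0 %.2f ms>\n",
              x$hnr_db, x$nhr, x$r0, x$t0 * 1000))
  invisible(x)
}
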