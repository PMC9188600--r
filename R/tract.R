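# Formant tracking by Burg autoregressive modelling and the apparent vocal
# tract length features derived from the tracked formants via the uniform
# closed-tube quarter-wavelength relation.

#' Track the first four formants
#'
#' Standard LPC formant analysis: the segment is resampled to twice the
#' formant ceiling, pre-emphasized with a first-order filter
#' `1 - a z^-1`, `a = exp(-2 pi preemph_from / fs)`, and Burg AR models are
#' fitted on Gaussian-windowed frames. AR pole angles give candidate
#' frequencies; candidates below 90 Hz or with bandwidth above 400 Hz are
#' discarded as spurious, and the lowest four survivors (ascending) are the
#' frame's formants.
#'
#' @param seg a voiced [audio_segment()] with sample rate at least
#'   `2 * max_formant`.
#' @param max_formant formant ceiling in Hz (default 5500).
#' @param window frame length in seconds (default 25 ms).
#' @param step frame hop in seconds (default 6.25 ms).
#' @param preemph_from pre-emphasis corner frequency in Hz (default 50).
#' @param lpc_order AR model order (default 12: two poles per resonance for
#'   up to six resonances across the 0--5.5 kHz band -- a long adult tract
#'   fits six below the ceiling -- with any remainder absorbing spectral
#'   tilt).
#' @return an object of class `formant_track`: `frame_times` (seconds), a
#'   `frames x 4` matrix `formants` (Hz, NA where a formant is missing), and
#'   the settings.
#' @export
formant_track <- function(seg, max_formant = 5500, window = 0.025,
                          step = 0.00625, preemph_from = 50,
                          lpc_order = 12) {
  assert_segment(seg)
  if (seg$sample_rate < 2 * max_formant) {
    pm_stop("sample rate must be at least twice the formant ceiling",
            "phonemark_invalid_argument")
  }
  fs2 <- 2 * max_formant
  x <- resample_to(seg$samples, seg$sample_rate, fs2)
  a <- exp(-2 * pi * preemph_from / fs2)
  x <- c(x[1], x[-1] - a * x[-length(x)])
  flen <- round(window * fs2)
  hop <- round(step * fs2)
  if (length(x) < flen) {
    pm_stop("segment shorter than one analysis window", "phonemark_too_short")
  }
  # Gaussian analysis window (sigma = flen/6 so the edges taper near zero)
  w <- exp(-0.5 * ((seq_len(flen) - (flen + 1) / 2) / (flen / 6))^2)
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  fmat <- matrix(NA_real_, nrow = length(starts), ncol = 4L)
  for (k in seq_along(starts)) {
    fr <- x[starts[k]:(starts[k] + flen - 1L)] * w
    if (var(fr) == 0) next
    ar <- tryCatch(ar.burg(fr, aic = FALSE, order.max = lpc_order,
                           demean = TRUE),
                   error = function(e) NULL)
    if (is.null(ar) || length(ar$ar) == 0L) next
    cand <- poles_to_formants(ar$ar, fs2)
    cand <- cand[cand$freq >= 90 & cand$freq <= max_formant &
                   cand$bw <= 400, , drop = FALSE]
    if (nrow(cand) == 0L) next
    f <- sort(cand$freq)
    fmat[k, seq_len(min(4L, length(f)))] <- f[seq_len(min(4L, length(f)))]
  }
  n_full <- sum(stats::complete.cases(fmat))
  if (n_full < 0.5 * nrow(fmat)) {
    pm_stop("fewer than four stable formants in most frames",
            "phonemark_formant_failure")
  }
  structure(list(frame_times = (starts - 1L + flen / 2) / fs2,
                 formants = fmat,
                 settings = list(max_formant = max_formant, window = window,
                                 step = step, preemph_from = preemph_from,
                                 lpc_order = lpc_order)),
            class = "formant_track")
}

# AR coefficients -> complex pole pairs -> (frequency, bandwidth) in Hz.
# polyroot() solves 1 - a1 x - ... - ap x^p = 0, whose roots are the
# reciprocals of the AR poles; a stable pole (inside the unit circle) is a
# root with modulus > 1 and thus a positive bandwidth below.
poles_to_formants <- function(ar_coef, fs) {
  r <- polyroot(c(1, -ar_coef))
  r <- r[Im(r) > 1e-9]                      # one of each conjugate pair
  freq <- abs(Arg(r)) * fs / (2 * pi)
  bw <- log(Mod(r)) * fs / pi
  data.frame(freq = freq, bw = bw)
}

# Low-pass (anti-alias) then linear-interpolate onto the target grid. For
# formant analysis the mild interpolation roll-off is immaterial.
resample_to <- function(x, fs_in, fs_out) {
  if (fs_out >= fs_in) return(x)
  flt <- signal::butter(8, 0.95 * fs_out / fs_in, type = "low")
  y <- signal::filtfilt(flt, x)
  t_new <- seq(0, (length(x) - 1) / fs_in, by = 1 / fs_out)
  approx((seq_along(x) - 1) / fs_in, y, xout = t_new)$y
}

#' @export
print.formant_track <- function(x, ...) {
  m <- colMeans(x$formants, na.rm = TRUE)
  cat(sprintf("<formant_track: %d frames, mean F1-F4 %s Hz>\n",
              nrow(x$formants), paste(round(m), collapse = "/")))
  invisible(x)
}

#' Per-recording formant means and SDs
#'
#' Mean and sample SD of each formant over the frames where that formant is
#' present.
#'
#' @param track a [formant_track()] with at least 2 complete frames.
#' @return a list with numeric vectors `mean` and `sd`, each length 4
#'   (named F1..F4), in Hz.
#' @export
formant_stats <- function(track) {
  if (!inherits(track, "formant_track")) {
    pm_stop("expected a `formant_track`", "phonemark_invalid_argument")
  }
  fmat <- track$formants
  if (sum(stats::complete.cases(fmat)) < 2L) {
    pm_stop("need at least 2 frames with all four formants",
            "phonemark_insufficient_frames")
  }
  m <- colMeans(fmat, na.rm = TRUE)
  s <- apply(fmat, 2, sd, na.rm = TRUE)
  names(m) <- names(s) <- paste0("F", 1:4)
  list(mean = m, sd = s)
}

#' Apparent vocal tract length from formant frequencies
#'
#' Inverts the uniform closed-tube resonance model: the `i`-th formant of a
#' tube of length `L` sits at `(2i - 1) c / (4 L)`, so each measured mean
#' formant yields its own length estimate
#' `VTL_i = (2i - 1) c / (4 F_i)`, `c = 33,500 cm/s`. The four estimates
#' agree only for a truly uniform tract, and their values are the four VTL
#' features of the pipeline.
#'
#' @param mean_formants numeric vector of mean formant frequencies in Hz
#'   (positive; one VTL per entry).
#' @return an object of class `vtl_features`: `vtl` (cm, named VTL_F1..),
#'   `mean_formants`, `c`.
#' @export
#' @examples
#' vtl_from_formants(c(500, 1500, 2500, 3500))  # 16.75 cm each
vtl_from_formants <- function(mean_formants) {
  if (any(!is.finite(mean_formants)) || any(mean_formants <= 0)) {
    pm_stop("formants must be positive and finite",
            "phonemark_invalid_argument")
  }
  i <- seq_along(mean_formants)
  vtl <- (2 * i - 1) * SPEED_OF_SOUND_CM_S / (4 * mean_formants)
  names(vtl) <- paste0("VTL_F", i)
  structure(list(vtl = vtl, mean_formants = mean_formants,
                 c = SPEED_OF_SOUND_CM_S),
            class = "vtl_features")
}

#' @export
print.vtl_features <- function(x, ...) {
  cat("<vtl_features (cm):",
      paste(sprintf("%s=%.2f", names(x$vtl), x$vtl), collapse = ", "), ">\n")
  invisible(x)
}
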