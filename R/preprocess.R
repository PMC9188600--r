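# Front-end standardization applied to every recording before feature
# extraction: fixed-duration center trim, then a Butterworth band-pass over
# the analysis band.

#' Trim a segment to a uniform duration
#'
#' Keeps exactly `round(duration * sample_rate)` samples taken from the
#' temporal center of the input. Sustained vowels are treated as stationary,
#' so the center window avoids onset/offset transients; the original study
#' does not state which window was kept, and center is this package's choice.
#'
#' @param seg an [audio_segment()].
#' @param duration target duration in seconds (default 0.5).
#' @return the trimmed [audio_segment()], `origin_time` updated.
#' @export
trim_uniform <- function(seg, duration = 0.5) {
  assert_segment(seg)
  n_out <- round(duration * seg$sample_rate)
  n <- length(seg$samples)
  if (n < n_out) {
    pm_stop(sprintf("segment is %.3f s, shorter than the requested %.3f s",
                    n / seg$sample_rate, duration), "phonemark_too_short")
  }
  start <- (n - n_out) %/% 2L
  audio_segment(seg$samples[start + seq_len(n_out)], seg$sample_rate,
                origin_time = seg$origin_time + start / seg$sample_rate)
}

#' Band-pass filter a segment
#'
#' IIR Butterworth band-pass of the given order (default 4th order,
#' 50 Hz--4 kHz). Applied as a plain causal (forward) filter by default; set
#' `zero_phase = TRUE` for a forward-backward pass.
#'
#' @param seg an [audio_segment()].
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @param order filter order.
#' @param zero_phase apply forward-backward (`signal::filtfilt`) instead of
#'   the default causal pass.
#' @return the filtered [audio_segment()], same length as the input.
#' @export
bandpass <- function(seg, lo = 50, hi = 4000, order = 4, zero_phase = FALSE) {
  assert_segment(seg)
  nyq <- seg$sample_rate / 2
  if (!(lo > 0 && lo < hi)) {
    pm_stop("need 0 < lo < hi", "phonemark_invalid_argument")
  }
  if (hi >= nyq) {
    pm_stop(sprintf("upper band edge %g Hz is not below Nyquist (%g Hz)",
                    hi, nyq), "phonemark_invalid_argument")
  }
  # signal::butter builds a band-pass of order 2n from n; request order/2
  # second-order sections worth so the overall order matches the request.
  flt <- signal::butter(order / 2, c(lo, hi) / nyq, type = "pass")
  y <- if (zero_phase) {
    signal::filtfilt(flt, seg$samples)
  } else {
    as.numeric(signal::filter(flt, seg$samples))
  }
  audio_segment(y, seg$sample_rate, origin_time = seg$origin_time)
}
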