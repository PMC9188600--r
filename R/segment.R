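#' Construct an audio segment
#'
#' The basic container for a mono waveform: amplitude samples in \[-1, 1\]
#' with a sample rate and the time offset of the first sample within its
#' source recording.
#'
#' @param samples numeric vector of amplitudes; must be finite.
#' @param sample_rate sampling frequency in Hz; must exceed 8000 Hz so that
#'   the 50 Hz--4 kHz analysis band fits below Nyquist.
#' @param origin_time time (seconds) of the first sample in the source
#'   recording; bookkeeping only.
#' @return an object of class `audio_segment` with fields `samples`,
#'   `sample_rate`, `origin_time`.
#' @export
#' @examples
#' seg <- audio_segment(sin(2 * pi * 100 * (0:999) / 8001), 8001)
#' duration(seg)
audio_segment <- function(samples, sample_rate, origin_time = 0) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    pm_stop("`samples` must be a non-empty numeric vector",
            "phonemark_invalid_argument")
  }
  if (!all(is.finite(samples))) {
    pm_stop("`samples` contains non-finite values", "phonemark_invalid_argument")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 8000) {
    pm_stop("`sample_rate` must be a single value > 8000 Hz",
            "phonemark_invalid_argument")
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 origin_time = as.numeric(origin_time)),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %g Hz (%.3f s), origin %.3f s>\n",
              length(x$samples), x$sample_rate, duration(x), x$origin_time))
  invisible(x)
}

#' Segment duration in seconds
#' @param seg an [audio_segment()].
#' @return duration in seconds.
#' @export
duration <- function(seg) length(seg$samples) / seg$sample_rate

is_segment <- function(x) inherits(x, "audio_segment")

assert_segment <- function(x) {
  if (!is_segment(x)) {
    pm_stop("expected an `audio_segment`", "phonemark_invalid_argument")
  }
  invisible(x)
}
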