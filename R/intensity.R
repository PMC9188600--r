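# Framewise intensity contour (energy-averaged, dB re 2e-5) and its
# stability summaries. The dB reference is the conventional 20 micropascal
# pressure reference; SD and range are invariant to it.

#' Framewise intensity contour
#'
#' Per frame, intensity is the energy average of the signal expressed in dB:
#' `I = 10 log10(mean(s^2) / ref^2)` with `ref = 2e-5` amplitude units.
#' Frames are half-open `[start, start + window)` and tile the whole
#' segment. An all-zero frame is floored at -100 dB with a warning.
#'
#' @param seg an [audio_segment()].
#' @param window frame length in seconds (default 32 ms, at least two
#'   glottal cycles at 75 Hz).
#' @param step hop between frame starts in seconds (default 8 ms); must not
#'   exceed `window`.
#' @return an object of class `intensity_contour` with fields `frame_times`
#'   (frame centers, seconds), `values` (dB), `window`, `step`, `ref`.
#' @export
intensity_contour <- function(seg, window = 0.032, step = 0.008) {
  assert_segment(seg)
  if (step > window) {
    pm_stop("`step` must not exceed `window`", "phonemark_invalid_argument")
  }
  fs <- seg$sample_rate
  flen <- round(window * fs)
  hop <- round(step * fs)
  x <- seg$samples
  if (length(x) < flen) {
    pm_stop("segment shorter than one analysis window", "phonemark_too_short")
  }
  ref <- 2e-5
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  vals <- vapply(starts, function(s) {
    e <- mean(x[s:(s + flen - 1L)]^2)
    if (e == 0) NA_real_ else 10 * log10(e / ref^2)
  }, numeric(1))
  if (anyNA(vals)) {
    warning("silent frame(s) floored at -100 dB")
    vals[is.na(vals)] <- -100
  }
  structure(list(frame_times = (starts - 1L + flen / 2) / fs,
                 values = vals, window = window, step = step, ref = ref),
            class = "intensity_contour")
}

#' @export
print.intensity_contour <- function(x, ...) {
  cat(sprintf("<intensity_contour: %d frames, mean %.1f dB, range %.2f dB>\n",
              length(x$values), mean(x$values),
              diff(range(x$values))))
  invisible(x)
}

#' Intensity stability features
#'
#' Sample SD and range (max - min) of the contour values: the two
#' lung-pressure stability features of the pipeline.
#'
#' @param contour an [intensity_contour()] with at least 2 frames.
#' @return named numeric vector `c(sd = ..., range = ...)`, both in dB.
#' @export
intensity_stats <- function(contour) {
  if (!inherits(contour, "intensity_contour")) {
    pm_stop("expected an `intensity_contour`", "phonemark_invalid_argument")
  }
  v <- contour$values
  if (length(v) < 2L) {
    pm_stop("need at least 2 frames", "phonemark_insufficient_frames")
  }
  c(sd = sd(v), range = max(v) - min(v))
}
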