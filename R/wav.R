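# Minimal RIFF/WAVE reader and writer.
#
# Reads mono PCM (8-bit unsigned, 16/24-bit signed little-endian) and 32-bit
# IEEE float WAV files; anything multi-channel is rejected because every
# analysis in this package is defined on a single microphone channel.

#' Read a mono WAV file
#'
#' @param path path to a RIFF/WAVE file. Supported encodings: PCM 8-bit
#'   unsigned, 16-bit and 24-bit signed, and 32-bit IEEE float; mono only.
#' @return an [audio_segment()] with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    pm_stop(sprintf("'%s' is not a RIFF/WAVE file", path), "phonemark_bad_wav")
  }
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    pm_stop(sprintf("'%s' is not a RIFF/WAVE file", path), "phonemark_bad_wav")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    pm_stop(sprintf("'%s': missing fmt or data chunk", path), "phonemark_bad_wav")
  }
  if (fmt$channels != 1L) {
    pm_stop(sprintf("'%s' has %d channels; only mono input is supported",
                    path, fmt$channels), "phonemark_not_mono")
  }
  x <- decode_wav_samples(data_raw, fmt$format, fmt$bits, path)
  audio_segment(x, fmt$rate)
}

decode_wav_samples <- function(raw, format, bits, path) {
  if (format == 1L && bits == 8L) {
    (as.integer(raw) - 128) / 128
  } else if (format == 1L && bits == 16L) {
    readBin(raw, "integer", length(raw) %/% 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (format == 1L && bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (format == 3L && bits == 32L) {
    readBin(raw, "double", length(raw) %/% 4L, 4L, endian = "little")
  } else {
    pm_stop(sprintf("'%s': unsupported WAV encoding (format %d, %d bit)",
                    path, format, bits), "phonemark_bad_wav")
  }
}

#' Write a mono WAV file
#'
#' @param seg an [audio_segment()]; samples are clipped to \[-1, 1\].
#' @param path output path.
#' @param bits one of 16 (PCM, default), 8, 24 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(seg, path, bits = 16L) {
  assert_segment(seg)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 24L, 32L)) {
    pm_stop("`bits` must be 8, 16, 24 or 32", "phonemark_invalid_argument")
  }
  x <- pmin(pmax(seg$samples, -1), 1)
  fmt_code <- if (bits == 32L) 3L else 1L
  payload <- switch(as.character(bits),
    "8"  = as.raw(as.integer(round(x * 127)) + 128L),
    "16" = writeBin(as.integer(round(x * 32767)), raw(), 2L, endian = "little"),
    "24" = {
      v <- as.integer(round(x * (2^23 - 1)))
      v <- ifelse(v < 0, v + 2^24, v)
      as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
    },
    "32" = writeBin(x, raw(), 4L, endian = "little"))
  rate <- as.integer(round(seg$sample_rate))
  block <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  wchar("RIFF"); w32(36L + length(payload)); wchar("WAVE")
  wchar("fmt "); w32(16L); w16(fmt_code); w16(1L); w32(rate)
  w32(rate * block); w16(block); w16(bits)
  wchar("data"); w32(length(payload))
  writeBin(payload, con)
  if (length(payload) %% 2L == 1L) writeBin(as.raw(0L), con)
  invisible(path)
}
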