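#' Minimal WAV audio I/O
#'
#' A small RIFF/WAVE codec for the microphone recordings this package
#' consumes: uncompressed PCM (16 or 24 bit) or IEEE float32.  Multi-channel
#' files are reduced to the first channel with a warning; samples are
#' returned as doubles in \[-1, 1\].
#'
#' @param path file path.
#' @return `read_wav()` returns a list with `samples` (numeric) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    pp_stop("format_error", "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    pp_stop("format_error", "not a WAVE file")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE)
      )
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    pp_stop("format_error", "missing fmt or data chunk")

  bits <- fmt$bits
  if (fmt$audio_format == 1L && bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && bits == 24L) {
    n <- length(data_raw) %/% 3
    m <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$audio_format == 3L && bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else {
    pp_stop("format_error", sprintf(
      "unsupported WAV encoding (format %d, %d bit)", fmt$audio_format, bits))
  }
  if (fmt$n_channels > 1L) {
    pp_warn("multichannel_audio", sprintf(
      "%d channels in %s; using the first", fmt$n_channels, path))
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}

#' @rdname read_wav
#' @param samples numeric vector in \[-1, 1\] (values outside are clipped).
#' @param sample_rate sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  samples <- pmin(1, pmax(-1, as.numeric(samples)))
  if (!bits %in% c(16L, 32L))
    pp_stop("invalid_input", "bits must be 16 or 32")
  bytes_per <- bits / 8L
  data_size <- length(samples) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(samples * 32767)), con, 2, endian = "little")
  } else {
    writeBin(samples, con, 4, endian = "little")
  }
  invisible(path)
}
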