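# Minimal RIFF/WAVE PCM16 reader and writer. Only the dialect the pipeline
# needs: little-endian PCM, 16 bit. Chunks other than "fmt " and "data" are
# skipped, so files with LIST/INFO metadata still load.

#' Read a 16-bit PCM WAV file
#'
#' Returns the waveform scaled to `[-1, 1]` (integer samples divided by
#' 32768). Multi-channel files are reduced to channel 1 with a warning.
#' The sampling rate is taken from the file header.
#'
#' @param path Path to a RIFF/WAVE file, PCM, 16 bit.
#' @return An [hl_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file (bad magic): ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file (no WAVE tag): ", path, call. = FALSE)

  fmt <- NULL; raw_data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        rate         = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      raw_data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(raw_data)) break
  }
  if (is.null(fmt) || is.null(raw_data))
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (fmt$audio_format != 1L)
    stop("unsupported WAV encoding (need uncompressed PCM): ", path,
         call. = FALSE)
  if (fmt$bits != 16L)
    stop("unsupported bit depth ", fmt$bits, " (need 16): ", path,
         call. = FALSE)

  ints <- readBin(raw_data, "integer", length(raw_data) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  if (fmt$channels > 1L) {
    warning("multi-channel WAV: keeping channel 1 of ", fmt$channels,
            call. = FALSE)
    ints <- ints[seq(1L, length(ints), by = fmt$channels)]
  }
  hl_signal(ints / 32768, rate = fmt$rate)
}

#' Write a signal as a 16-bit PCM mono WAV file
#'
#' Samples outside `[-1, 1]` are clipped with a warning before
#' quantization (round to nearest of `sample * 32768`, clamped to the
#' 16-bit range), so `read_wav(write_wav(s))` agrees with `s` within one
#' quantization step, `2^-15`.
#'
#' @param signal An [hl_signal()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(signal, path) {
  signal <- as_hl_signal(signal)
  x <- signal$samples
  if (any(x > 1 | x < -1)) {
    warning("samples outside [-1, 1] clipped before writing", call. = FALSE)
    x <- pmin(1, pmax(-1, x))
  }
  ints <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  rate <- as.integer(round(signal$rate))
  n_bytes <- length(ints) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
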