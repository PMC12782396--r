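# Minimal RIFF/WAVE I/O for mono stimuli. Supports 16-bit integer PCM
# (format 1) and 32-bit float (format 3); stereo and other encodings are
# rejected with a clear error. Written in-package because the installed R
# stack ships no audio-file reader.

#' Read a mono WAV file
#'
#' @param path WAV file (PCM 16-bit or IEEE float 32-bit, mono).
#' @return A [waveform()], amplitudes scaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_emogate("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_emogate("not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * 256^(0:3))
      fmt <- list(code = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort_emogate("WAV file is missing its fmt or data chunk")
  }
  if (fmt$channels != 1) {
    abort_emogate("only mono WAV files are supported (got stereo/multichannel)")
  }
  if (fmt$code == 1 && fmt$bits == 16) {
    n <- length(data_raw) %/% 2
    s <- readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$code == 3 && fmt$bits == 32) {
    n <- length(data_raw) %/% 4
    s <- readBin(data_raw, "numeric", n, size = 4, endian = "little")
  } else {
    abort_emogate(paste0("unsupported WAV encoding (format ", fmt$code,
                         ", ", fmt$bits, " bit); use 16-bit PCM or 32-bit float"))
  }
  waveform(pmin(1, pmax(-1, s)), fmt$rate)
}

#' Write a mono WAV file
#'
#' @param audio A [waveform()].
#' @param path Output file.
#' @param bits 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "waveform"))
  if (!bits %in% c(16, 32)) abort_emogate("bits must be 16 or 32")
  n <- length(audio$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(fmt_code)
  w16(1)                       # mono
  w32(audio$sample_rate_hz)
  w32(audio$sample_rate_hz * bytes_per)  # byte rate
  w16(bytes_per)               # block align
  w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bits == 16) {
    q <- as.integer(pmin(32767, pmax(-32768, round(audio$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(audio$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
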