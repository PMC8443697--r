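# Minimal RIFF/WAVE I/O: IEEE float32 and 16-bit PCM, single channel.
# The pre-installed stack has no WAV reader, and the pipeline only needs
# mono pressure series, so the two chunk layouts used here are written and
# parsed directly.

#' Write a mono WAV file
#'
#' @param samples Numeric vector of samples. For `"pcm16"` they must lie in
#'   `[-1, 1]` and are scaled to the 16-bit integer range; `"float32"` writes
#'   them verbatim (pressure units survive the round trip).
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "float32") {
    audio_fmt <- 3L; bits <- 32L; data_bytes <- 4L * n
  } else {
    audio_fmt <- 1L; bits <- 16L; data_bytes <- 2L * n
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    x <- pmax(pmin(samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Accepts the two layouts written by [write_wav()]: IEEE float32 and 16-bit
#' PCM, single channel. PCM samples are rescaled to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  audio_fmt <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1L) stop("only mono WAV supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      if (audio_fmt == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      } else if (audio_fmt == 1L && bits == 16L) {
        samples <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (need float32 or pcm16)")
      }
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, fs = fs)
}
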