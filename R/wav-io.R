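#' Read a RIFF/WAVE audio file
#'
#' Minimal PCM WAV reader covering the formats the rest of the package
#' produces and consumes: 16-bit integer PCM and 32-bit IEEE float, mono or
#' multi-channel, arbitrary sample rate. Samples are returned as a channel x
#' sample numeric matrix scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (channels x n matrix), `sample_rate` (Hz),
#'   `bits` and `n_channels`.
#' @keywords internal
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("audio file does not exist: '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("cannot decode '%s': not a RIFF/WAVE file", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("cannot decode '%s': not a RIFF/WAVE file", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunks are word-aligned
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stopf("cannot decode '%s': missing fmt/data chunk", path)

  nch <- fmt$n_channels
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2L,
                    endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", n = length(data_raw) %/% 4L, size = 4L,
                    endian = "little")
  } else {
    stopf("cannot decode '%s': unsupported WAV encoding (format %d, %d-bit)",
          path, fmt$audio_format, fmt$bits)
  }
  if (length(vals) == 0L) stopf("audio file '%s' contains no samples", path)
  samples <- matrix(vals, nrow = nch)
  list(samples = samples, sample_rate = fmt$sample_rate,
       bits = fmt$bits, n_channels = nch)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (clipped if outside).
#' @param sample_rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
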