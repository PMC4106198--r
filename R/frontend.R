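#' Front-end configuration
#'
#' Fixed settings for the spectral front-end: non-overlapping 1024-sample
#' Hamming-windowed STFT frames mapped through a 40-band Mel filterbank whose
#' lower edge sits at 500 Hz (a heuristic high-pass that discards most
#' environmental noise), followed by a single RMS normalisation of the whole
#' spectrogram.
#'
#' @param sample_rate Target sample rate in Hz (audio is resampled on load).
#' @param frame_size STFT frame length in samples; frames do not overlap.
#' @param window Analysis window; only `"hamming"` is supported.
#' @param n_mels Number of Mel bands.
#' @param fmin_hz Lower edge of the filterbank in Hz.
#' @param log_mel If `TRUE` the Mel matrix is log-compressed
#'   (`log(1 + x)`) before RMS normalisation; the default keeps linear
#'   magnitudes, with log compression applied only inside [compute_mfcc()].
#' @return A `front_end_config` list.
#' @export
front_end_config <- function(sample_rate = 44100, frame_size = 1024,
                             window = "hamming", n_mels = 40,
                             fmin_hz = 500, log_mel = FALSE) {
  if (!identical(window, "hamming"))
    stopf("only the Hamming window is supported (got '%s')", window)
  stopifnot(sample_rate > 0, frame_size >= 2, n_mels >= 1,
            fmin_hz >= 0, fmin_hz < sample_rate / 2)
  structure(list(sample_rate = sample_rate, frame_size = as.integer(frame_size),
                 window = window, n_mels = as.integer(n_mels),
                 fmin_hz = fmin_hz, log_mel = isTRUE(log_mel)),
            class = "front_end_config")
}

#' Construct an audio clip
#'
#' @param samples Numeric vector of amplitudes (dimensionless).
#' @param sample_rate Sample rate in Hz.
#' @param source_id Opaque identifier (defaults to `"clip"`).
#' @return An `audio_clip` object.
#' @export
audio_clip <- function(samples, sample_rate, source_id = "clip") {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) == 0L) stopf("audio clip '%s' is empty", source_id)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 source_id = as.character(source_id)),
            class = "audio_clip")
}

#' Load an audio file as a mono clip at a target sample rate
#'
#' Multi-channel audio is downmixed by averaging the channels; audio at a
#' different rate is resampled (polyphase FIR via [signal::resample()]).
#' A file already mono and at the target rate is returned bit-identically.
#'
#' @param path Path to a WAV file. FLAC is not supported by this build and
#'   raises an explicit error.
#' @param target_rate Target sample rate in Hz.
#' @return An [audio_clip()].
#' @export
load_audio <- function(path, target_rate = 44100) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "flac")
    stopf("cannot decode '%s': FLAC is not supported; convert to WAV", path)
  w <- read_wav(path)
  x <- if (w$n_channels > 1L) colMeans(w$samples) else as.numeric(w$samples)
  if (length(x) == 0L) stopf("audio file '%s' is empty", path)
  if (w$sample_rate != target_rate) {
    x <- as.numeric(signal::resample(x, p = target_rate, q = w$sample_rate))
  }
  audio_clip(x, target_rate, source_id = basename(path))
}

# Slaney-style Mel scale: linear below 1 kHz, logarithmic above.
hz_to_mel <- function(hz) {
  f_sp <- 200 / 3
  brk <- 1000
  min_log_mel <- brk / f_sp
  logstep <- log(6.4) / 27
  ifelse(hz < brk, hz / f_sp, min_log_mel + log(hz / brk) / logstep)
}

mel_to_hz <- function(mel) {
  f_sp <- 200 / 3
  brk <- 1000
  min_log_mel <- brk / f_sp
  logstep <- log(6.4) / 27
  ifelse(mel < min_log_mel, mel * f_sp, brk * exp(logstep * (mel - min_log_mel)))
}

#' Mel filterbank matrix
#'
#' Triangular, area-normalised (Slaney-style) filters spanning `fmin_hz` to
#' Nyquist; rows are bands ordered by increasing centre frequency, columns are
#' FFT bins.
#'
#' @param n_mels Number of bands.
#' @param n_fft STFT frame length.
#' @param sample_rate Sample rate in Hz.
#' @param fmin_hz Lower edge in Hz.
#' @return Matrix `n_mels` x `(n_fft/2 + 1)` with attribute `centres_hz`.
#' @keywords internal
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin_hz) {
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges_hz <- mel_to_hz(seq(hz_to_mel(fmin_hz), hz_to_mel(sample_rate / 2),
                            length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges_hz[m]; ce <- edges_hz[m + 1L]; hi <- edges_hz[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    dn <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn)) * 2 / (hi - lo)  # area normalisation
  }
  attr(fb, "centres_hz") <- edges_hz[2:(n_mels + 1L)]
  fb
}

#' Compute a Mel spectrogram
#'
#' The clip is cut into non-overlapping `frame_size`-sample frames (a trailing
#' partial frame is discarded), Hamming-windowed, and the linear STFT magnitude
#' of each frame is mapped through the Mel filterbank. The whole matrix is then
#' scaled so its root-mean-square value equals 1, making downstream features
#' invariant to recording level.
#'
#' @param clip An [audio_clip()].
#' @param cfg A [front_end_config()]; its `sample_rate` must match the clip.
#' @return A `mel_spectrogram`: numeric matrix frames x bands with attributes
#'   `frame_duration_s` and `band_centres_hz`.
#' @export
compute_mel_spectrogram <- function(clip, cfg = front_end_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  fs <- cfg$frame_size
  if (n < fs)
    stopf("clip '%s' too short: %d samples < one %d-sample frame",
          clip$source_id, n, fs)
  if (all(clip$samples == 0))
    stopf("clip '%s' is all zeros: RMS normalisation undefined", clip$source_id)
  if (clip$sample_rate != cfg$sample_rate)
    stopf("clip sample rate %g does not match front-end %g",
          clip$sample_rate, cfg$sample_rate)

  n_frames <- n %/% fs
  frames <- matrix(clip$samples[seq_len(n_frames * fs)], nrow = fs)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, fs - 1) / (fs - 1))
  spec <- Mod(stats::mvfft(frames * win))[seq_len(fs %/% 2L + 1L), , drop = FALSE]
  fb <- mel_filterbank(cfg$n_mels, fs, cfg$sample_rate, cfg$fmin_hz)
  m <- t(fb %*% spec)  # frames x bands
  if (cfg$log_mel) m <- log1p(m)
  m <- m / rms(m)
  structure(m,
            class = c("mel_spectrogram", "matrix", "array"),
            frame_duration_s = fs / cfg$sample_rate,
            band_centres_hz = attr(fb, "centres_hz"))
}

n_frames <- function(mel) nrow(mel)

#' Compute MFCCs with delta features
#'
#' Log-compressed Mel bands are transformed by an orthonormal DCT-II; the
#' first 13 cepstral coefficients (c0..c12) are kept and concatenated with
#' their deltas (symmetric first difference over adjacent frames, edges
#' replicated), giving 26-dimensional frames.
#'
#' @param mel A `mel_spectrogram` with at least 3 frames.
#' @param n_ceps Number of cepstral coefficients kept (default 13).
#' @return Numeric matrix frames x `2 * n_ceps` carrying the
#'   `frame_duration_s` attribute of its input.
#' @export
compute_mfcc <- function(mel, n_ceps = 13) {
  stopifnot(inherits(mel, "mel_spectrogram") || is.matrix(mel))
  if (nrow(mel) < 3L)
    stopf("need at least 3 frames for delta features (got %d)", nrow(mel))
  M <- ncol(mel)
  logm <- log(unclass(mel) + 1e-10)
  # orthonormal DCT-II basis, n_ceps x M
  k <- seq_len(n_ceps) - 1
  i <- seq_len(M) - 1
  dct <- sqrt(2 / M) * cos(outer(k, i, function(k, i) pi * k * (i + 0.5) / M))
  dct[1, ] <- dct[1, ] / sqrt(2)
  cep <- logm %*% t(dct)
  nr <- nrow(cep)
  prev <- cep[c(1, seq_len(nr - 1)), , drop = FALSE]
  nxt <- cep[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  delta <- (nxt - prev) / 2
  out <- cbind(cep, delta)
  attr(out, "frame_duration_s") <- attr(mel, "frame_duration_s")
  out
}
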