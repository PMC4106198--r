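#' Median-based spectral noise reduction
#'
#' Estimates the stationary noise floor of one spectrogram as the per-band
#' median magnitude, subtracts that median spectrum from every frame, and
#' clips negative values to zero. Only energy rising above the median bandwise
#' level survives, which suppresses stationary backgrounds well but is not
#' designed for fluctuating noise. The profile is estimated per recording.
#'
#' @param mel A `mel_spectrogram` (or plain frames x bands matrix).
#' @return The reduced spectrogram with the same shape, class and attributes,
#'   plus a `noise_profile` attribute holding the per-band median spectrum.
#' @export
reduce_noise <- function(mel) {
  if (is.null(dim(mel)) || nrow(mel) == 0L || ncol(mel) == 0L)
    stopf("cannot noise-reduce an empty spectrogram")
  med <- apply(unclass(mel), 2, stats::median)
  out <- pmax(sweep(unclass(mel), 2, med, "-"), 0)
  attributes(out) <- attributes(mel)
  attr(out, "noise_profile") <- med
  out
}
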