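#' Summarise a feature sequence by per-dimension mean and standard deviation
#'
#' Standard deviation uses the population convention (divide by n).
#'
#' @param x Frames x features matrix with at least one frame.
#' @return Numeric vector `c(means, sds)` of length `2 * ncol(x)`.
#' @export
summarise_mean_std <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stopf("cannot summarise an empty feature sequence")
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  sd_pop[!is.finite(sd_pop)] <- 0
  c(mu, pmax(sd_pop, 0))
}

#' Summarise a feature sequence by per-dimension maximum
#'
#' @param x Frames x features matrix with at least one frame.
#' @return Numeric vector of length `ncol(x)`.
#' @export
summarise_max <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stopf("cannot summarise an empty feature sequence")
  apply(x, 2, max)
}

#' Summarise a feature sequence by modulation coefficients
#'
#' For each feature dimension the magnitude spectrum of a single full-length
#' Fourier transform along the time axis is computed (normalised by the number
#' of frames so durations do not dominate) and averaged into `n_coeffs`
#' equal-width frequency bins spanning 0 to the frame-rate Nyquist. Bins that
#' receive no spectrum point (very short sequences) are zero. Using one
#' full-length transform keeps the output length independent of duration.
#'
#' @param x Frames x features matrix with at least 2 frames.
#' @param n_coeffs Number of modulation bins (default 10).
#' @return Numeric vector of length `n_coeffs * ncol(x)`, ordered
#'   dimension-major (all bins of dimension 1, then dimension 2, ...).
#' @export
summarise_modulation <- function(x, n_coeffs = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stopf("modulation summary needs at least 2 frames (got %d)", n)
  spec <- Mod(stats::mvfft(x)) / n
  n_keep <- n %/% 2L + 1L                  # DC .. Nyquist of the frame rate
  spec <- spec[seq_len(n_keep), , drop = FALSE]
  rel_freq <- (seq_len(n_keep) - 1) / (n / 2)  # 0 .. 1 of Nyquist
  bin <- pmin(floor(rel_freq * n_coeffs) + 1L, n_coeffs)
  out <- matrix(0, n_coeffs, ncol(x))
  for (b in unique(bin)) {
    out[b, ] <- colMeans(spec[bin == b, , drop = FALSE])
  }
  as.numeric(out)
}

#' The twelve feature configurations
#'
#' The feature-type x summarisation grid evaluated by the workflow: MFCC and
#' Mel-spectrum features under mean/std, max and modulation summaries, and six
#' learned-feature variants (1/2/3/4/8 stacked frames and the two-layer
#' variant) under mean/std summarisation only.
#'
#' @param k Dictionary size used by the learned variants (affects dimensions).
#' @param n_mels Number of Mel bands.
#' @return data.frame with columns `label`, `features`, `summarisation`,
#'   `delta`, `two_layer`, `dimension`.
#' @export
feature_configs <- function(k = 500, n_mels = 40) {
  rows <- list(
    list("mfcc-ms",      "mfcc",    "mean_std",   NA, FALSE),
    list("mfcc-maxp",    "mfcc",    "max",        NA, FALSE),
    list("mfcc-modul",   "mfcc",    "modulation", NA, FALSE),
    list("melspec-ms",   "melspec", "mean_std",   NA, FALSE),
    list("melspec-maxp", "melspec", "max",        NA, FALSE),
    list("melspec-modul","melspec", "modulation", NA, FALSE),
    list("melspec-kfl1-ms", "learned", "mean_std", 1, FALSE),
    list("melspec-kfl2-ms", "learned", "mean_std", 2, FALSE),
    list("melspec-kfl3-ms", "learned", "mean_std", 3, FALSE),
    list("melspec-kfl4-ms", "learned", "mean_std", 4, FALSE),
    list("melspec-kfl8-ms", "learned", "mean_std", 8, FALSE),
    list("melspec-kfl4pl8kfl4-ms", "learned", "mean_std", 4, TRUE))
  df <- data.frame(
    label = vapply(rows, `[[`, "", 1),
    features = vapply(rows, `[[`, "", 2),
    summarisation = vapply(rows, `[[`, "", 3),
    delta = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    two_layer = vapply(rows, `[[`, FALSE, 5),
    stringsAsFactors = FALSE)
  width <- ifelse(df$features == "mfcc", 26,
                  ifelse(df$features == "melspec", n_mels, k))
  per <- c(mean_std = 2, max = 1, modulation = 10)
  df$dimension <- width * per[df$summarisation]
  df
}

#' Summary-vector length for a feature configuration label
#'
#' @param label One of the labels of [feature_configs()].
#' @inheritParams feature_configs
#' @return Integer dimensionality of the summary vector.
#' @export
summary_dim <- function(label, k = 500, n_mels = 40) {
  cfgs <- feature_configs(k = k, n_mels = n_mels)
  i <- match(label, cfgs$label)
  if (is.na(i)) stopf("unknown feature configuration label '%s'", label)
  as.integer(cfgs$dimension[i])
}

#' Apply a summarisation scheme by name
#'
#' @param x Frames x features matrix.
#' @param scheme One of `"mean_std"`, `"max"`, `"modulation"`.
#' @param n_coeffs Modulation bins (modulation scheme only).
#' @return Summary vector.
#' @export
summarise_features <- function(x, scheme, n_coeffs = 10) {
  switch(scheme,
         mean_std = summarise_mean_std(x),
         max = summarise_max(x),
         modulation = summarise_modulation(x, n_coeffs),
         stopf("unknown summarisation scheme '%s'", scheme))
}
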