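# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (naive loops, batch algorithms) so agreement is a
# genuine cross-check.

# Exhaustive Mann-Whitney pair count: ties get half credit.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Rank-walking average precision.
oracle_average_precision <- function(scores, relevant) {
  ord <- order(scores, decreasing = TRUE)
  hits <- 0; s <- 0
  for (r in seq_along(ord)) {
    if (relevant[ord[r]]) {
      hits <- hits + 1
      s <- s + hits / r
    }
  }
  s / sum(relevant)
}

# Batch spherical k-means run to convergence on unit rows (Lloyd-style:
# assign by max dot product, recompute centroids as normalised member sums).
batch_spherical_kmeans <- function(x_unit, k, max_iter = 200) {
  centroids <- x_unit[seq_len(k), , drop = FALSE]
  assign_old <- rep(-1L, nrow(x_unit))
  for (it in seq_len(max_iter)) {
    dots <- x_unit %*% t(centroids)
    assign_new <- max.col(dots, ties.method = "first")
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      rows <- which(assign_new == j)
      if (length(rows) > 0) {
        s <- colSums(x_unit[rows, , drop = FALSE])
        if (sum(s^2) > 0) centroids[j, ] <- s / sqrt(sum(s^2))
      }
    }
  }
  list(centroids = centroids, assignment = assign_old)
}

# Mean cosine distance of unit rows to their nearest centroid.
spherical_objective <- function(x_unit, centroids) {
  mean(1 - apply(x_unit %*% t(centroids), 1, max))
}

# Exhaustive best-match cosine similarities between two small sets of unit
# vectors: for each row of `truth`, the best |cosine| over rows of `fitted`.
best_match_cosims <- function(truth, fitted) {
  apply(abs(truth %*% t(fitted)), 1, max)
}

# Random Mel-like feature sequence with the attributes the pipeline expects.
random_feature_seq <- function(n_frames, width, frame_duration_s = 0.025,
                               seed = 1) {
  set.seed(seed)
  structure(matrix(abs(rnorm(n_frames * width)), n_frames, width),
            frame_duration_s = frame_duration_s)
}

# A short deterministic tone clip for front-end tests.
tone_clip <- function(freq_hz, duration_s = 0.6, sample_rate = 22050,
                      id = "tone") {
  t <- seq_len(round(duration_s * sample_rate)) / sample_rate
  audio_clip(0.5 * sin(2 * pi * freq_hz * t), sample_rate, source_id = id)
}

unit_rows_for_test <- function(x) x / sqrt(rowSums(x^2))
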