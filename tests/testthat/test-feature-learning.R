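test_that("cosine distance matches its closed forms and rejects zero vectors", {
  expect_equal(cosine_distance(c(2, 5, 1), c(2, 5, 1)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_equal(cosine_distance(c(1, 0), c(-2, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("frame stacking produces patch rows of stacked consecutive frames", {
  x <- matrix(seq_len(10 * 40), 10, 40)
  p <- stack_frames(x, 4)
  expect_equal(dim(p), c(7L, 160L))
  expect_equal(p[1, ], c(x[1, ], x[2, ], x[3, ], x[4, ]))
  expect_equal(p[7, ], c(x[7, ], x[8, ], x[9, ], x[10, ]))
  expect_identical(stack_frames(x, 1), x)
  expect_error(stack_frames(x[1:3, ], 4), "at least delta")
})

test_that("PCA whitening yields zero mean and identity covariance on its sample", {
  set.seed(10)
  x <- matrix(rnorm(600 * 8), 600, 8) %*% matrix(runif(64, -1, 1), 8, 8)
  wt <- fit_whitening(x)
  xw <- apply_whitening(x, wt)
  expect_equal(unname(colMeans(xw)), rep(0, 8), tolerance = 1e-10)
  # epsilon-floored eigenvalues leave a relative bias of ~epsilon/lambda
  expect_equal(unname(stats::cov(xw)), diag(8), tolerance = 1e-4)

  # i.i.d. standard normal: the whitening map is close to a rotation
  z <- matrix(rnorm(5000 * 6), 5000, 6)
  wtz <- fit_whitening(z)
  expect_equal(unname(stats::cov(apply_whitening(z, wtz))), diag(6), tolerance = 1e-6)

  # constant column: floored, no blow-up
  xc <- cbind(x[, 1:3], 5)
  expect_warning(wc <- fit_whitening(xc), "near-zero variance")
  expect_true(all(is.finite(apply_whitening(xc, wc))))
})

test_that("reservoir sampling is exhaustive under capacity, deterministic, and uniform", {
  x <- matrix(seq_len(100), ncol = 1)
  s <- reservoir_sample_pass(x, capacity = 1000, seed = 3)
  expect_equal(sort(s[, 1]), 1:100)

  s1 <- reservoir_sample_pass(x, capacity = 10, seed = 42)
  s2 <- reservoir_sample_pass(x, capacity = 10, seed = 42)
  expect_identical(s1, s2)
  expect_false(identical(s1, reservoir_sample_pass(x, capacity = 10, seed = 43)))

  expect_error(reservoir_sample_pass(matrix(numeric(0), 0, 2), 5), "empty stream")

  # streamed in chunks == one pass over a single matrix
  chunks <- list(x[1:30, , drop = FALSE], x[31:77, , drop = FALSE],
                 x[78:100, , drop = FALSE])
  expect_identical(reservoir_sample_pass(chunks, 10, seed = 7),
                   reservoir_sample_pass(x, 10, seed = 7))

  # Monte-Carlo uniformity: per-item inclusion frequency ~ Binomial(R, c/N)
  N <- 1000; cap <- 100; R <- 300
  counts <- integer(N)
  stream <- matrix(seq_len(N), ncol = 1)
  for (seed in seq_len(R)) {
    kept <- reservoir_sample_pass(stream, cap, seed = seed)[, 1]
    counts[kept] <- counts[kept] + 1L
  }
  p <- cap / N
  sigma <- sqrt(R * p * (1 - p))
  expect_true(all(abs(counts - R * p) < 4.5 * sigma))
  expect_equal(sum(counts), R * cap)
})

test_that("fitted dictionaries have unit bases and are reproducible", {
  pd <- planted_dictionary_data(3, 8, 400, snr_db = 30, seed = 21)
  d1 <- fit_dictionary(pd$x, patch_config(delta = 1), k = 3, seed = 5,
                       patch_normalise = FALSE)
  d2 <- fit_dictionary(pd$x, patch_config(delta = 1), k = 3, seed = 5,
                       patch_normalise = FALSE)
  expect_equal(unname(sqrt(rowSums(d1$bases^2))), rep(1, 3), tolerance = 1e-6)
  expect_identical(d1$bases, d2$bases)
  expect_identical(d1$update_counts, d2$update_counts)
  expect_equal(sum(d1$update_counts), 400 + 400)  # both passes tallied

  expect_error(fit_dictionary(pd$x[1:2, ], patch_config(delta = 1), k = 3),
               "at least k")
})

test_that("online learning matches planted structure and the batch oracle", {
  for (case_seed in c(22, 23, 24)) {
    pd <- planted_dictionary_data(3, 8, 400, snr_db = 30, seed = case_seed)
    dict <- fit_dictionary(pd$x, patch_config(delta = 1), k = 3, seed = 9,
                           patch_normalise = FALSE, whiten = FALSE)
    # every planted direction is matched by some centroid
    expect_true(all(best_match_cosims(pd$directions, dict$bases) >= 0.98))

    # objective within 10% of converged batch spherical k-means
    xu <- unit_rows_for_test(pd$x)
    batch <- batch_spherical_kmeans(xu, 3)
    expect_lte(spherical_objective(xu, dict$bases),
               1.10 * spherical_objective(xu, batch$centroids) + 1e-9)
  }
})

test_that("projection reproduces the stacked dot-product by brute force", {
  set.seed(30)
  # identity whitening + standard basis: projection returns the input
  eye <- new_feature_dictionary(diag(5), patch = patch_config(delta = 1))
  x <- structure(matrix(runif(40), 8, 5), frame_duration_s = 0.02)
  expect_equal(unname(project(x, eye)), unname(unclass(x)))
  expect_equal(attr(project(x, eye), "frame_duration_s"), 0.02)

  # single basis, patch = 3 * basis -> coefficient 3
  b <- c(3, 4, 0) / 5
  d1 <- new_feature_dictionary(matrix(b, 1), patch = patch_config(delta = 1))
  expect_equal(as.numeric(project(matrix(3 * b, 1, 3), d1)), 3)

  # random dictionary, delta = 2: naive double loop over bases and offsets
  M <- 6; delta <- 2; k <- 4; n <- 9
  bases <- matrix(rnorm(k * M * delta), k)
  bases <- bases / sqrt(rowSums(bases^2))
  wt_mat <- matrix(rnorm((M * delta)^2, sd = 0.3), M * delta)
  wt <- structure(list(mean = rnorm(M * delta), matrix = wt_mat, epsilon = 0),
                  class = "whitening_transform")
  dict <- new_feature_dictionary(bases, wt, patch_config(delta = delta))
  xm <- matrix(rnorm(n * M), n, M)
  got <- project(xm, dict)
  expected <- matrix(0, n - delta + 1, k)
  for (t in seq_len(n - delta + 1)) {
    patch <- c(xm[t, ], xm[t + 1, ])
    pw <- as.numeric(wt_mat %*% (patch - wt$mean))
    for (j in seq_len(k)) {
      s <- 0
      for (i in seq_len(M * delta)) s <- s + bases[j, i] * pw[i]
      expected[t, j] <- s
    }
  }
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_error(project(matrix(rnorm(10), 5, 2), dict), "dimension")
})

test_that("projection is linear for zero-mean whitening", {
  set.seed(31)
  wt <- structure(list(mean = rep(0, 6), matrix = matrix(rnorm(36), 6), epsilon = 0),
                  class = "whitening_transform")
  bases <- matrix(rnorm(18), 3); bases <- bases / sqrt(rowSums(bases^2))
  dict <- new_feature_dictionary(bases, wt, patch_config(delta = 1))
  x <- matrix(rnorm(30), 5, 6); y <- matrix(rnorm(30), 5, 6)
  expect_equal(project(2.5 * x, dict), 2.5 * project(x, dict), tolerance = 1e-12)
  expect_equal(project(x + y, dict), project(x, dict) + project(y, dict),
               tolerance = 1e-12)
})

test_that("temporal max-pooling follows the block-max rule with partial tails", {
  set.seed(32)
  x <- matrix(rnorm(16 * 3), 16, 3)
  p <- maxpool_downsample(x, 8)
  expect_equal(dim(p), c(2L, 3L))
  expect_equal(p[1, ], apply(x[1:8, ], 2, max))
  expect_equal(p[2, ], apply(x[9:16, ], 2, max))
  expect_equal(maxpool_downsample(x, 1), x)
  x17 <- rbind(x, rnorm(3))
  p17 <- maxpool_downsample(x17, 8)
  expect_equal(nrow(p17), 3L)
  expect_equal(p17[3, ], x17[17, ])  # final block pools a single frame
  attr(x, "frame_duration_s") <- 0.025
  expect_equal(attr(maxpool_downsample(x, 8), "frame_duration_s"), 0.2)
})

test_that("two-layer learning stacks dimensions as k * delta and stays unit-norm", {
  set.seed(33)
  mels <- lapply(1:6, function(i) random_feature_seq(120, 12, seed = 100 + i))
  tl <- fit_two_layer(mels, patch_config(delta = 4, pool_factor = 8), k = 8,
                      seed = 2, capacity = 5000)
  expect_equal(ncol(tl$layer1$bases), 12L * 4L)
  expect_equal(ncol(tl$layer2$bases), 8L * 4L)
  expect_equal(unname(sqrt(rowSums(tl$layer1$bases^2))), rep(1, 8), tolerance = 1e-6)
  expect_equal(unname(sqrt(rowSums(tl$layer2$bases^2))), rep(1, 8), tolerance = 1e-6)
  s <- project_two_layer(mels[[1]], tl, pool_factor = 8)
  expect_equal(ncol(s), 8L)
})

test_that("layer-2 summaries separate syllable orderings better than layer-1", {
  # Two classes share the same syllables in opposite order (A then B vs B
  # then A). Frame-wise marginals are identical and only the three junction
  # patches differ at layer 1, so at high frame noise layer-1 summaries
  # degrade while the layer-2 patch, whose receptive field spans the whole
  # sequence after 8x pooling, still sees the arrangement. Whitening is
  # disabled: estimating it from a few dozen patches only injects noise.
  set.seed(34)
  dim_f <- 8
  A_syl <- matrix(abs(rnorm(16 * dim_f)) + 0.3, 16, dim_f)
  B_syl <- matrix(abs(rnorm(16 * dim_f)) + 0.3, 16, dim_f)
  make_seq <- function(first, second, seed) {
    set.seed(seed)
    structure(rbind(first, second) + matrix(rnorm(32 * dim_f, sd = 0.6), 32),
              frame_duration_s = 0.025)
  }
  all_seqs <- c(lapply(1:20, function(i) make_seq(A_syl, B_syl, 200 + i)),
                lapply(1:20, function(i) make_seq(B_syl, A_syl, 400 + i)))
  y <- rep(c(1, 0), each = 20)

  tl <- fit_two_layer(all_seqs, patch_config(delta = 4, pool_factor = 8),
                      k = 8, seed = 3, capacity = 5000, whiten = FALSE)
  sum_l1 <- t(vapply(all_seqs, function(s)
    summarise_mean_std(project(s, tl$layer1)), numeric(16)))
  sum_l2 <- t(vapply(all_seqs, function(s)
    summarise_mean_std(project_two_layer(s, tl)), numeric(16)))

  probe_auc <- function(feats) {
    train <- c(1:10, 21:30); test <- setdiff(1:40, train)
    w <- colMeans(feats[1:10, , drop = FALSE]) -
      colMeans(feats[21:30, , drop = FALSE])
    auc_score(feats[test, , drop = FALSE] %*% w, y[test])
  }
  expect_gt(probe_auc(sum_l2), probe_auc(sum_l1))
  expect_gte(probe_auc(sum_l2), 0.9)
})

test_that("random projection is seeded, shaped, and roughly distance-preserving", {
  set.seed(35)
  x <- matrix(rnorm(40 * 52), 40, 52)
  p <- random_projection(x, out_dim = 200, seed = 6)
  expect_equal(dim(p), c(40L, 200L))
  expect_identical(p, random_projection(x, out_dim = 200, seed = 6))
  expect_false(identical(p, random_projection(x, out_dim = 200, seed = 7)))

  # heterogeneous point scales give the distance distribution enough spread
  # for a meaningful correlation check of distance preservation
  big <- matrix(rnorm(60 * 500), 60, 500) * runif(60, 0.3, 3)
  proj <- random_projection(big, out_dim = 200, seed = 8)
  expect_gt(stats::cor(as.numeric(dist(big)), as.numeric(dist(proj))), 0.8)
})
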