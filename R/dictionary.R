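#' Patch configuration for dictionary learning
#'
#' @param delta Number of consecutive frames stacked into one patch.
#' @param layer2 Whether this configuration names the two-layer variant.
#' @param pool_factor Temporal max-pool factor applied between the layers.
#' @return A `patch_config` list.
#' @export
patch_config <- function(delta = 4, layer2 = FALSE, pool_factor = 8) {
  stopifnot(delta >= 1, pool_factor >= 1)
  structure(list(delta = as.integer(delta), layer2 = isTRUE(layer2),
                 pool_factor = as.integer(pool_factor)),
            class = "patch_config")
}

#' Cosine distance between two vectors
#'
#' `1 - cos(theta) = 1 - (A . B) / (||A|| ||B||)`, in \[0, 2\].
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return A scalar in \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("cosine distance undefined for a zero-norm vector")
  1 - sum(a * b) / (na * nb)
}

#' Stack consecutive frames into spectro-temporal patches
#'
#' Row `t` of the result is the concatenation of frames `t .. t + delta - 1`,
#' so a frames x M input yields `n - delta + 1` rows of length `M * delta`.
#' Columns are ordered frame-major (all M bands of offset 0, then offset 1, ...).
#'
#' @param x Frames x features matrix (a `mel_spectrogram` or any feature
#'   sequence).
#' @param delta Number of frames per patch.
#' @return Patch matrix.
#' @export
stack_frames <- function(x, delta) {
  x <- unclass(x)
  n <- nrow(x)
  if (n < delta)
    stopf("need at least delta = %d frames to stack (got %d)", delta, n)
  if (delta == 1L) return(x[, , drop = FALSE])
  out <- do.call(cbind, lapply(seq_len(delta) - 1L, function(d)
    x[(1L + d):(n - delta + 1L + d), , drop = FALSE]))
  out
}

# Per-patch normalisation used before whitening: subtract the patch mean and
# divide by the patch norm. Zero-norm patches come out as zero rows.
normalise_patches <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  ok <- nrm > 0
  x[ok, ] <- x[ok, , drop = FALSE] / nrm[ok]
  attr(x, "n_zero_norm") <- sum(!ok)
  x
}

unit_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  x / pmax(nrm, .Machine$double.eps)
}

#' Fit a PCA whitening transform
#'
#' Eigendecomposition-based whitening: the returned transform maps the fitted
#' sample to zero mean and identity covariance. Eigenvalues are floored by
#' `epsilon` so rank-deficient samples whiten without blow-up (a warning is
#' emitted for degenerate directions).
#'
#' @param sample Rows x dims matrix.
#' @param epsilon Regulariser added to the eigenvalues.
#' @return A `whitening_transform` with fields `mean`, `matrix`, `epsilon`.
#' @export
fit_whitening <- function(sample, epsilon = 1e-8) {
  sample <- unclass(sample)
  if (nrow(sample) < ncol(sample))
    warnf("whitening sample has fewer rows (%d) than dimensions (%d)",
          nrow(sample), ncol(sample))
  m <- colMeans(sample)
  cc <- stats::cov(sample)
  eg <- eigen(cc, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  n_degenerate <- sum(vals <= epsilon)
  if (n_degenerate > 0L)
    warnf("%d whitening direction(s) have near-zero variance; floored by epsilon",
          n_degenerate)
  w <- diag(1 / sqrt(vals + epsilon), length(vals)) %*% t(eg$vectors)
  structure(list(mean = m, matrix = w, epsilon = epsilon),
            class = "whitening_transform")
}

#' Apply a whitening transform
#'
#' @param x Rows x dims matrix.
#' @param wt A `whitening_transform`.
#' @return The whitened matrix.
#' @export
apply_whitening <- function(x, wt) {
  stopifnot(inherits(wt, "whitening_transform"))
  if (ncol(x) != length(wt$mean))
    stopf("whitening dimension mismatch: data has %d columns, transform %d",
          ncol(x), length(wt$mean))
  sweep(unclass(x), 2, wt$mean) %*% t(wt$matrix)
}

identity_whitening <- function(dim) {
  structure(list(mean = rep(0, dim), matrix = diag(dim), epsilon = 0),
            class = "whitening_transform")
}

#' Uniform reservoir sample from a streamed patch source
#'
#' Draws a uniform without-replacement sample of `min(capacity, N)` rows in a
#' single forward pass (classic reservoir sampling), then shuffles the sample.
#' The source is visited one chunk at a time and never materialised.
#'
#' @param stream A matrix, a list of matrices, or a zero-argument function
#'   returning the next chunk (matrix) or `NULL` when exhausted.
#' @param capacity Reservoir size.
#' @param seed Integer seed controlling both the reservoir and the shuffle.
#' @return Sampled (shuffled) rows as a matrix.
#' @export
reservoir_sample_pass <- function(stream, capacity, seed = 1L) {
  stopifnot(capacity >= 1)
  next_chunk <- as_chunk_stream(stream)
  res <- NULL
  t <- 0L
  with_seed(seed, {
    repeat {
      chunk <- next_chunk()
      if (is.null(chunk)) break
      chunk <- unclass(chunk)
      if (is.null(res)) res <- matrix(NA_real_, capacity, ncol(chunk))
      for (r in seq_len(nrow(chunk))) {
        t <- t + 1L
        if (t <= capacity) {
          res[t, ] <- chunk[r, ]
        } else {
          j <- sample.int(t, 1L)
          if (j <= capacity) res[j, ] <- chunk[r, ]
        }
      }
    }
    if (t == 0L) stopf("cannot reservoir-sample an empty stream")
    n_kept <- min(t, capacity)
    res <- res[sample.int(n_kept), , drop = FALSE]
  })
  res
}

as_chunk_stream <- function(stream) {
  if (is.function(stream)) return(stream)
  chunks <- if (is.list(stream)) stream else list(stream)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(chunks)) NULL else chunks[[i]]
  }
}

# Seed k distinct unit directions from unit rows `pool` by k-means++-style
# sampling: each next seed is drawn with probability proportional to its
# cosine distance from the nearest already-chosen seed, so duplicate-cluster
# starts (which the online winner-only update cannot escape) are avoided.
kmeanspp_directions <- function(pool, k) {
  n <- nrow(pool)
  idx <- integer(k)
  idx[1] <- 1L
  d <- pmax(1 - as.numeric(pool %*% pool[1L, ]), 0)
  for (j in seq_len(k)[-1]) {
    if (sum(d) <= 1e-12) {
      cand <- which(d > 1e-12 | !(seq_len(n) %in% idx[seq_len(j - 1L)]))
      if (length(cand) == 0L)
        stopf("fewer than k = %d distinct patch directions available", k)
      idx[j] <- cand[1L]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d)
    }
    d <- pmin(d, pmax(1 - as.numeric(pool %*% pool[idx[j], ]), 0))
  }
  pool[idx, , drop = FALSE]
}

# One online spherical-k-means update sweep over the rows of `patches`
# (already normalised if configured). State (bases, counts) is threaded
# through one patch at a time; cost per patch is one k x d product.
sk_update_sweep <- function(patches, wt, bases, counts, weight_fn) {
  xw <- apply_whitening(patches, wt)
  nrm <- sqrt(rowSums(xw^2))
  skipped <- 0L
  for (r in seq_len(nrow(xw))) {
    if (nrm[r] == 0) { skipped <- skipped + 1L; next }
    x <- xw[r, ] / nrm[r]
    dots <- bases %*% x
    j <- which.max(dots)  # unit vectors: max dot = min cosine distance; ties -> lowest index
    w <- weight_fn(counts[j])
    cj <- bases[j, ] + w * x
    bases[j, ] <- cj / sqrt(sum(cj^2))
    counts[j] <- counts[j] + 1L
  }
  list(bases = bases, counts = counts, skipped = skipped)
}

#' Learn a spherical k-means feature dictionary
#'
#' Two streamed passes over the patch data. Pass 1 reservoir-samples up to
#' `capacity` patches, shuffles them, fits PCA whitening on the sample,
#' initialises `k` unit centroids from distinct sample patches, and runs the
#' online update over the sample. Pass 2 streams every patch through the same
#' update. The online rule is count-weighted Hartigan-style k-means adapted to
#' the sphere: the nearest centroid by cosine distance moves towards the
#' whitened, unit-normalised patch with weight `1 / (n_j + 1)` and is
#' renormalised after every update, so centroids are always unit vectors.
#'
#' @param x A frames x bands matrix, or a list of them (one per recording).
#' @param patch A [patch_config()]; `patch$delta` frames are stacked per patch.
#' @param k Number of basis vectors.
#' @param seed Integer seed (reservoir, shuffle, initialisation).
#' @param capacity Pass-1 reservoir size.
#' @param epsilon Whitening eigenvalue floor.
#' @param patch_normalise Subtract each patch's mean and divide by its norm
#'   before whitening (the convention the learned features follow by default).
#' @param whiten Fit and apply PCA whitening (the default pipeline
#'   behaviour). With `FALSE` the dictionary stores an identity transform and
#'   clustering operates on the raw (optionally patch-normalised) directions,
#'   which is the natural setting when the data are already rays through the
#'   origin.
#' @param weight_fn Online update weight as a function of a centroid's update
#'   tally (default `1/(n + 1)`).
#' @param reset_tallies_pass2 Restart update tallies at the start of pass 2
#'   instead of carrying them over (default carries them over).
#' @return A `feature_dictionary` with unit-norm `bases` (k x M*delta), the
#'   fitted `whitening`, the `patch` config, per-basis `update_counts` and a
#'   count of `skipped` zero-norm patches.
#' @export
fit_dictionary <- function(x, patch = patch_config(), k = 500, seed = 1L,
                           capacity = 100000, epsilon = 1e-8,
                           patch_normalise = TRUE, whiten = TRUE,
                           weight_fn = function(n) 1 / (n + 1),
                           reset_tallies_pass2 = FALSE) {
  mels <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  delta <- patch$delta
  mels <- Filter(function(m) nrow(m) >= delta, mels)  # too-short recordings contribute no patch
  patches_of <- function(m) {
    p <- stack_frames(m, delta)
    if (patch_normalise) p <- normalise_patches(p)
    p
  }
  total <- sum(vapply(mels, function(m) max(0L, nrow(m) - delta + 1L), 0L))
  if (total < k)
    stopf("need at least k = %d patches to fit a dictionary (got %d)", k, total)

  # Pass 1: reservoir sample + shuffle, whitening, init, online sweep.
  i <- 0L
  stream <- function() {
    i <<- i + 1L
    if (i > length(mels)) NULL else patches_of(mels[[i]])
  }
  sample_m <- reservoir_sample_pass(stream, capacity, seed = seed)
  # Per-patch mean subtraction leaves one structurally flat direction, which
  # the epsilon floor handles; only unexpected degeneracy is worth a warning.
  wt <- if (!whiten) {
    identity_whitening(ncol(sample_m))
  } else if (patch_normalise) {
    withCallingHandlers(fit_whitening(sample_m, epsilon = epsilon),
                        warning = function(w) {
                          if (grepl("near-zero variance", conditionMessage(w)))
                            invokeRestart("muffleWarning")
                        })
  } else {
    fit_whitening(sample_m, epsilon = epsilon)
  }

  sw <- apply_whitening(sample_m, wt)
  swn <- sqrt(rowSums(sw^2))
  live <- which(swn > 0)
  pool <- sw[live, , drop = FALSE] / swn[live]
  # k-means++-style seeding under cosine distance (capped pool keeps the
  # O(n k) seeding cost bounded for large reservoirs)
  pool <- pool[seq_len(min(nrow(pool), max(1000L, 10L * k))), , drop = FALSE]
  bases <- with_seed(seed + 1L, kmeanspp_directions(pool, k))
  counts <- rep(0L, k)

  st <- sk_update_sweep(sample_m, wt, bases, counts, weight_fn)
  skipped <- st$skipped

  # Pass 2: stream every patch through the online update.
  if (reset_tallies_pass2) st$counts <- rep(0L, k)
  for (m in mels) {
    st <- sk_update_sweep(patches_of(m), wt, st$bases, st$counts, weight_fn)
    skipped <- skipped + st$skipped
  }
  if (skipped > 0L)
    warnf("skipped %d zero-norm patch(es) during dictionary training", skipped)

  new_feature_dictionary(st$bases, wt, patch,
                         patch_normalise = patch_normalise,
                         update_counts = st$counts, skipped = skipped,
                         seed = seed)
}

#' Construct a feature dictionary from explicit components
#'
#' Mainly useful for tests and for hand-built bases; [fit_dictionary()] is the
#' learning entry point.
#'
#' @param bases k x dims matrix of unit rows.
#' @param whitening A `whitening_transform` (default identity).
#' @param patch A [patch_config()].
#' @param patch_normalise Apply per-patch mean/norm normalisation at
#'   projection time.
#' @param update_counts,skipped,seed Optional training metadata.
#' @return A `feature_dictionary`.
#' @export
new_feature_dictionary <- function(bases, whitening = NULL,
                                   patch = patch_config(delta = 1),
                                   patch_normalise = FALSE,
                                   update_counts = NULL, skipped = 0L,
                                   seed = NA_integer_) {
  bases <- as.matrix(bases)
  if (is.null(whitening)) whitening <- identity_whitening(ncol(bases))
  structure(list(bases = bases, k = nrow(bases), whitening = whitening,
                 patch = patch, patch_normalise = isTRUE(patch_normalise),
                 update_counts = update_counts %||% rep(0L, nrow(bases)),
                 skipped = skipped, seed = seed, schema_version = 1L),
            class = "feature_dictionary")
}

#' Project a spectrogram onto a learned dictionary
#'
#' Each `delta`-frame patch is (optionally patch-normalised and) whitened with
#' the dictionary's stored transform, then dotted with every basis vector.
#' Projections keep their sign (no rectification).
#'
#' @param x Frames x features matrix (`mel_spectrogram` or a pooled layer-1
#'   feature sequence).
#' @param dict A `feature_dictionary`.
#' @return Feature sequence matrix `(n - delta + 1)` x `k`, carrying the
#'   input's `frame_duration_s` attribute.
#' @export
project <- function(x, dict) {
  stopifnot(inherits(dict, "feature_dictionary"))
  p <- stack_frames(x, dict$patch$delta)
  if (ncol(p) != ncol(dict$bases))
    stopf("dictionary expects %d-dimensional patches, got %d",
          ncol(dict$bases), ncol(p))
  if (dict$patch_normalise) p <- normalise_patches(p)
  out <- apply_whitening(p, dict$whitening) %*% t(dict$bases)
  attr(out, "frame_duration_s") <- attr(x, "frame_duration_s")
  out
}

#' Temporal max-pooling of a feature sequence
#'
#' Output frame `t` is the element-wise maximum over input frames
#' `(t-1)*factor + 1 .. t*factor`; a trailing partial block is pooled as-is.
#'
#' @param x Frames x features matrix.
#' @param factor Pooling factor (1 = identity).
#' @return Pooled matrix with `frame_duration_s` scaled by `factor`.
#' @export
maxpool_downsample <- function(x, factor) {
  stopifnot(factor >= 1)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stopf("cannot max-pool an empty sequence")
  fd <- attr(x, "frame_duration_s")
  if (factor == 1L) return(x)
  grp <- (seq_len(nrow(x)) - 1L) %/% factor
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), grp), function(idx) {
    apply(x[idx, , drop = FALSE], 2, max)
  }))
  rownames(out) <- NULL
  if (!is.null(fd)) attr(out, "frame_duration_s") <- fd * factor
  out
}

#' Fit the two-layer dictionary variant
#'
#' Layer 1 is fitted on `delta`-frame Mel patches; every recording is then
#' projected into the layer-1 space and max-pooled by `pool_factor` along
#' time, and layer 2 is fitted on `delta`-frame patches of the pooled
#' features (patch dimension `k * delta`). The second layer can capture
#' regularities over a roughly `pool_factor`-times longer temporal scale.
#'
#' @inheritParams fit_dictionary
#' @param patch A [patch_config()]; `delta` is used for both layers,
#'   `pool_factor` between them.
#' @return List with elements `layer1` and `layer2` (both `feature_dictionary`).
#' @export
fit_two_layer <- function(x, patch = patch_config(delta = 4, pool_factor = 8),
                          k = 500, seed = 1L, capacity = 100000,
                          epsilon = 1e-8, patch_normalise = TRUE,
                          whiten = TRUE) {
  mels <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  l1 <- fit_dictionary(mels, patch = patch_config(delta = patch$delta),
                       k = k, seed = seed, capacity = capacity,
                       epsilon = epsilon, patch_normalise = patch_normalise,
                       whiten = whiten)
  pooled <- lapply(mels, function(m)
    maxpool_downsample(project(m, l1), patch$pool_factor))
  l2 <- fit_dictionary(pooled, patch = patch_config(delta = patch$delta),
                       k = k, seed = seed + 1L, capacity = capacity,
                       epsilon = epsilon, patch_normalise = patch_normalise,
                       whiten = whiten)
  list(layer1 = l1, layer2 = l2)
}

#' Project through both layers of a two-layer dictionary
#'
#' @param x A `mel_spectrogram`.
#' @param layers The list returned by [fit_two_layer()].
#' @param pool_factor Max-pool factor between the layers.
#' @return Layer-2 feature sequence.
#' @export
project_two_layer <- function(x, layers, pool_factor = 8) {
  pooled <- maxpool_downsample(project(x, layers$layer1), pool_factor)
  project(pooled, layers$layer2)
}

#' Random Gaussian projection of summary vectors
#'
#' Projects every row of `x` through a single seeded Gaussian matrix
#' (entries `N(0, 1/out_dim)`), standardising feature dimensionality so the
#' intrinsic character of a feature set can be compared independently of its
#' size.
#'
#' @param x Rows x dims matrix of summary vectors.
#' @param out_dim Output dimensionality.
#' @param seed Integer seed; the same seed yields the same matrix.
#' @return Rows x `out_dim` matrix.
#' @export
random_projection <- function(x, out_dim = 200, seed = 1L) {
  stopifnot(out_dim >= 1)
  x <- as.matrix(x)
  pm <- with_seed(seed, matrix(stats::rnorm(ncol(x) * out_dim), ncol(x), out_dim))
  x %*% (pm / sqrt(out_dim))
}

#' Save / load a feature dictionary archive
#'
#' Single-file archive (RDS) with a versioned schema: bases, whitening
#' transform, patch configuration, update tallies and training seed.
#'
#' @param dict A `feature_dictionary`.
#' @param path Archive path.
#' @return `path` invisibly; `load_dictionary` returns the dictionary.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "feature_dictionary"))
  saveRDS(unclass(dict), path, version = 2)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema_version, 1L))
    stopf("unsupported dictionary schema version: %s", obj$schema_version)
  structure(obj, class = "feature_dictionary")
}
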