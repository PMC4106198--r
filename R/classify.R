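#' Annotation set
#'
#' Per-recording species labels over a fixed class vocabulary.
#'
#' @param recording_id Character vector of recording identifiers.
#' @param labels List (parallel to `recording_id`) of character vectors of
#'   species labels; single-label sets must have exactly one label per item.
#' @param vocabulary Ordered class vocabulary; defaults to the sorted union of
#'   observed labels.
#' @param mode `"single_label"` or `"multilabel"`.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(recording_id, labels,
                           vocabulary = NULL, mode = "multilabel") {
  stopifnot(length(recording_id) == length(labels))
  mode <- match.arg(mode, c("single_label", "multilabel"))
  labels <- lapply(labels, as.character)
  if (mode == "single_label" && any(lengths(labels) != 1L))
    stopf("single-label annotation sets must have exactly one label per item")
  vocabulary <- vocabulary %||% sort(unique(unlist(labels)))
  unknown <- setdiff(unlist(labels), vocabulary)
  if (length(unknown) > 0L)
    stopf("labels outside the vocabulary: %s", paste(unknown, collapse = ", "))
  structure(list(recording_id = as.character(recording_id), labels = labels,
                 vocabulary = vocabulary, mode = mode),
            class = "annotation_set")
}

#' Binary label matrix of an annotation set
#'
#' @param ann An [annotation_set()].
#' @param ids Recording ids (rows); defaults to all annotated recordings.
#' @return 0/1 matrix ids x vocabulary.
#' @export
label_matrix <- function(ann, ids = ann$recording_id) {
  idx <- match(ids, ann$recording_id)
  if (anyNA(idx)) stopf("unannotated recording id(s): %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  out <- matrix(0L, length(ids), length(ann$vocabulary),
                dimnames = list(ids, ann$vocabulary))
  for (r in seq_along(ids)) out[r, ann$labels[[idx[r]]]] <- 1L
  out
}

#' Decision windowing specification
#'
#' @param window_s Window length in seconds, or `"whole"` to treat the entire
#'   recording as one decision unit.
#' @param pool How per-window scores are aggregated per recording
#'   (`"mean"` or `"max"`); ignored for whole-audio windows.
#' @return A `decision_windowing`.
#' @export
decision_windowing <- function(window_s = "whole", pool = "mean") {
  pool <- match.arg(pool, c("mean", "max"))
  if (!identical(window_s, "whole")) {
    stopifnot(is.numeric(window_s), window_s > 0)
  }
  structure(list(window_s = window_s, pool = pool), class = "decision_windowing")
}

# Split a feature sequence into non-overlapping decision windows (lists of
# frame index vectors); a trailing partial window is kept if it has >= 1 frame.
window_indices <- function(n_frames, frame_duration_s, window_s) {
  if (identical(window_s, "whole")) return(list(seq_len(n_frames)))
  wf <- max(1L, floor(window_s / frame_duration_s + 1e-9))
  split(seq_len(n_frames), (seq_len(n_frames) - 1L) %/% wf)
}

#' Build a training table of summarised decision windows
#'
#' Each recording contributes one row per decision window (one row in
#' whole-audio mode); every window row is summarised with `scheme` and
#' inherits the recording's full label set.
#'
#' @param seqs Named list of feature-sequence matrices (frames x width,
#'   carrying a `frame_duration_s` attribute), one per recording.
#' @param ann An [annotation_set()] covering every recording in `seqs`.
#' @param windowing A [decision_windowing()].
#' @param scheme Summarisation scheme, see [summarise_features()].
#' @return A `training_table`: list with `x` (rows x dim matrix),
#'   `recording_id`, `labels` (list column), `vocabulary`, `windowing`.
#' @export
make_training_table <- function(seqs, ann, windowing = decision_windowing(),
                                scheme = "mean_std") {
  stopifnot(inherits(ann, "annotation_set"), inherits(windowing, "decision_windowing"))
  ids <- names(seqs)
  if (is.null(ids)) stopf("`seqs` must be a named list keyed by recording id")
  lab_idx <- match(ids, ann$recording_id)
  if (anyNA(lab_idx))
    stopf("recordings without annotations: %s", paste(ids[is.na(lab_idx)], collapse = ", "))
  rows <- list(); row_id <- character(0); row_labels <- list()
  n_short <- 0L
  for (i in seq_along(seqs)) {
    s <- as.matrix(seqs[[i]])
    fd <- attr(seqs[[i]], "frame_duration_s")
    if (!identical(windowing$window_s, "whole")) {
      if (is.null(fd)) stopf("feature sequence '%s' lacks frame_duration_s", ids[i])
      if (nrow(s) * fd < windowing$window_s) n_short <- n_short + 1L
    }
    for (idx in window_indices(nrow(s), fd, windowing$window_s)) {
      rows[[length(rows) + 1L]] <- summarise_features(s[idx, , drop = FALSE], scheme)
      row_id <- c(row_id, ids[i])
      row_labels[[length(row_labels) + 1L]] <- ann$labels[[lab_idx[i]]]
    }
  }
  if (n_short > 0L)
    warnf("%d recording(s) shorter than one decision window: kept as a single partial window",
          n_short)
  structure(list(x = do.call(rbind, rows), recording_id = row_id,
                 labels = row_labels, vocabulary = ann$vocabulary,
                 windowing = windowing),
            class = "training_table")
}

#' Train the random forest classifier
#'
#' A 200-tree probability random forest (via \pkg{ranger}), applied in one of
#' three label modes: `single_label` (one forest over mutually exclusive
#' classes), `binary_relevance` (one forest per class, positive = label
#' present), or `multilabel` (a single forest trained on label powersets whose
#' per-class probability is the summed probability of the label combinations
#' containing the class). No classifier parameters are tuned beyond tree count.
#'
#' @param table A `training_table`.
#' @param mode `"single_label"`, `"binary_relevance"` or `"multilabel"`.
#' @param seed Integer seed (forests are deterministic given it).
#' @param num_trees Number of trees (default 200).
#' @return A `species_classifier`.
#' @export
train_classifier <- function(table, mode = "multilabel", seed = 1L,
                             num_trees = 200) {
  stopifnot(inherits(table, "training_table"))
  mode <- match.arg(mode, c("single_label", "binary_relevance", "multilabel"))
  vocab <- table$vocabulary
  x <- as.data.frame(table$x)
  names(x) <- paste0("f", seq_len(ncol(x)))
  present <- sort(unique(unlist(table$labels)))
  if (length(present) < 2L)
    stopf("need at least 2 classes with training examples (got %d)", length(present))

  fit_forest <- function(y) {
    # min.node.size = 1 grows trees fully, so probabilities are vote
    # proportions of fully-grown trees rather than shallow-stump priors
    ranger::ranger(x = x, y = y, probability = TRUE, num.trees = num_trees,
                   min.node.size = 1, seed = seed, num.threads = 1)
  }

  if (mode == "single_label") {
    if (any(lengths(table$labels) != 1L))
      stopf("single_label mode requires exactly one label per row (multilabel annotations?)")
    y <- factor(vapply(table$labels, `[[`, "", 1L), levels = vocab)
    model <- list(forest = fit_forest(droplevels(y)))
  } else if (mode == "binary_relevance") {
    forests <- stats::setNames(vector("list", length(vocab)), vocab)
    for (cl in vocab) {
      pos <- vapply(table$labels, function(l) cl %in% l, FALSE)
      if (!any(pos)) {
        warnf("class '%s' has no positive training examples: constant score 0", cl)
        forests[[cl]] <- list(constant = 0)
      } else if (all(pos)) {
        warnf("class '%s' has no negative training examples: constant score 1", cl)
        forests[[cl]] <- list(constant = 1)
      } else {
        forests[[cl]] <- fit_forest(factor(ifelse(pos, "pos", "neg"),
                                           levels = c("neg", "pos")))
      }
    }
    model <- list(forests = forests)
  } else {
    key <- vapply(table$labels, function(l) paste(sort(l), collapse = "|"), "")
    y <- factor(key)
    member <- matrix(0, nlevels(y), length(vocab),
                     dimnames = list(levels(y), vocab))
    for (lv in levels(y)) {
      labs <- strsplit(lv, "|", fixed = TRUE)[[1]]
      member[lv, labs[labs != ""]] <- 1
    }
    model <- list(forest = fit_forest(y), member = member)
  }
  structure(c(model, list(mode = mode, vocabulary = vocab,
                          feature_dim = ncol(table$x), seed = seed)),
            class = "species_classifier")
}

#' Predict per-recording class probabilities
#'
#' Scores every window row of `table`, then pools the per-window probabilities
#' per recording with the table's configured statistic (mean or max); in
#' whole-audio mode the single window passes through.
#'
#' @param model A `species_classifier`.
#' @param table A `training_table` built with the same feature configuration.
#' @return A `prediction_matrix`: numeric matrix recordings x classes in
#'   \[0, 1\], rownames = recording ids, plus a `window_scores` attribute with
#'   the unpooled per-window matrix.
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "species_classifier"), inherits(table, "training_table"))
  if (ncol(table$x) != model$feature_dim)
    stopf("feature dimension mismatch: model trained on %d, table has %d",
          model$feature_dim, ncol(table$x))
  x <- as.data.frame(table$x)
  names(x) <- paste0("f", seq_len(ncol(x)))
  vocab <- model$vocabulary
  n <- nrow(x)
  win <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))

  if (model$mode == "single_label") {
    p <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
    win[, colnames(p)] <- p
  } else if (model$mode == "binary_relevance") {
    for (cl in vocab) {
      f <- model$forests[[cl]]
      if (!is.null(f$constant)) {
        win[, cl] <- f$constant
      } else {
        p <- stats::predict(f, data = x, num.threads = 1)$predictions
        win[, cl] <- p[, "pos"]
      }
    }
  } else {
    p <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
    win <- p[, rownames(model$member), drop = FALSE] %*% model$member
  }

  pool_fn <- if (table$windowing$pool == "max") max else mean
  ids <- unique(table$recording_id)
  out <- matrix(0, length(ids), length(vocab), dimnames = list(ids, vocab))
  for (id in ids) {
    rows <- win[table$recording_id == id, , drop = FALSE]
    out[id, ] <- apply(rows, 2, pool_fn)
  }
  structure(out, class = c("prediction_matrix", "matrix", "array"),
            window_scores = win)
}
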