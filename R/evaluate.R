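#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly random positive item is scored higher than
#' a uniformly random negative item, with tied scores contributing half credit
#' per pair. Computed from midranks, equivalent to the exhaustive pair count.
#' Chance performance is 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), parallel to `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  p <- sum(labels == 1L); n <- sum(labels == 0L)
  if (p == 0L || n == 0L)
    stopf("AUC undefined: need at least one positive and one negative (got %d/%d)", p, n)
  r <- rank(scores)  # midranks handle ties as half credit
  (sum(r[labels == 1L]) - p * (p + 1) / 2) / (p * n)
}

#' Average precision of one ranked item
#'
#' Classes are ranked by decreasing score; precision is evaluated at the rank
#' of each relevant class and averaged over the relevant classes.
#'
#' @param scores Numeric class scores for one item.
#' @param relevant Binary relevance indicator, parallel to `scores`.
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(scores, relevant) {
  relevant <- as.logical(relevant)
  if (!any(relevant)) stopf("average precision undefined for an item with no true labels")
  ord <- order(scores, decreasing = TRUE)
  rel_ranked <- relevant[ord]
  hits <- which(rel_ranked)
  mean(seq_along(hits) / hits)
}

#' Mean average precision over a prediction matrix
#'
#' @param pred Matrix recordings x classes of scores (rownames = ids).
#' @param ann An [annotation_set()]; items with no true labels are excluded
#'   with a warning.
#' @return MAP in \[0, 1\].
#' @export
mean_average_precision <- function(pred, ann) {
  truth <- label_matrix(ann, rownames(pred))[, colnames(pred), drop = FALSE]
  has_lab <- rowSums(truth) > 0
  if (!all(has_lab))
    warnf("%d item(s) with no true labels excluded from MAP", sum(!has_lab))
  if (!any(has_lab)) stopf("MAP undefined: no item has a true label")
  ap <- vapply(which(has_lab), function(r)
    average_precision(pred[r, ], truth[r, ]), 0)
  mean(ap)
}

#' Multilabel AUC over a prediction matrix
#'
#' `"micro"` (default) pools every (item, class) score/label pair into one
#' ranking; `"macro"` averages per-class AUCs over the classes that have both
#' a positive and a negative item.
#'
#' @param pred Matrix recordings x classes (rownames = ids).
#' @param ann An [annotation_set()].
#' @param average `"micro"` or `"macro"`.
#' @return AUC in \[0, 1\].
#' @export
multilabel_auc <- function(pred, ann, average = "micro") {
  average <- match.arg(average, c("micro", "macro"))
  truth <- label_matrix(ann, rownames(pred))[, colnames(pred), drop = FALSE]
  if (average == "micro") {
    return(auc_score(as.numeric(pred), as.numeric(truth)))
  }
  ok <- which(colSums(truth) > 0 & colSums(1 - truth) > 0)
  if (length(ok) == 0L) stopf("macro AUC undefined: no class has both labels")
  mean(vapply(ok, function(j) auc_score(pred[, j], truth[, j]), 0))
}

#' Enumerate the experiment grid
#'
#' Full Cartesian product of the configuration axes: the twelve feature
#' configurations x noise reduction on/off x two classifier modes x decision
#' window x pooling statistic. Restricting the window axis reproduces the
#' per-dataset experiment counts (4 windows: 384; 2: 192; whole-audio only: 96).
#'
#' @param feature_labels Feature configuration labels (default all twelve).
#' @param noise_reduction Logical axis values.
#' @param classifier_modes Classifier mode axis (two entries in the standard
#'   grid: multilabel vs. the dataset-appropriate alternative).
#' @param windows List of window lengths (seconds or `"whole"`).
#' @param pools Pooling statistics.
#' @return data.frame, one row per configuration.
#' @export
enumerate_grid <- function(feature_labels = feature_configs()$label,
                           noise_reduction = c(FALSE, TRUE),
                           classifier_modes = c("multilabel", "binary_relevance"),
                           windows = list(1, 5, 60, "whole"),
                           pools = c("mean", "max")) {
  g <- expand.grid(feature = feature_labels,
                   noise_reduction = noise_reduction,
                   classifier_mode = classifier_modes,
                   window = vapply(windows, function(w) as.character(w), ""),
                   pool = pools,
                   stringsAsFactors = FALSE)
  g
}

# Compute the per-recording feature sequences for one feature configuration.
# `mels` is a named list of mel spectrograms (already noise-reduced if
# configured); dictionaries are fitted on `train_ids` only.
feature_sequences <- function(mels, label, dict_mels, k = 500, seed = 1L,
                              capacity = 100000) {
  cfgs <- feature_configs(k = k)
  i <- match(label, cfgs$label)
  if (is.na(i)) stopf("unknown feature configuration label '%s'", label)
  kind <- cfgs$features[i]
  if (kind == "melspec") {
    seqs <- mels
    dict <- NULL
  } else if (kind == "mfcc") {
    seqs <- lapply(mels, compute_mfcc)
    dict <- NULL
  } else if (cfgs$two_layer[i]) {
    dict <- fit_two_layer(dict_mels, patch_config(delta = cfgs$delta[i]),
                          k = k, seed = seed, capacity = capacity)
    seqs <- lapply(mels, project_two_layer, layers = dict)
  } else {
    dict <- fit_dictionary(dict_mels,
                           patch = patch_config(delta = cfgs$delta[i]),
                           k = k, seed = seed, capacity = capacity)
    seqs <- lapply(mels, project, dict = dict)
  }
  list(seqs = seqs, dictionary = dict, scheme = cfgs$summarisation[i])
}

# Merge two annotation sets over the union vocabulary (used by the
# training-augmentation composition mode).
merge_annotations <- function(a, b) {
  vocab <- sort(union(a$vocabulary, b$vocabulary))
  annotation_set(c(a$recording_id, b$recording_id), c(a$labels, b$labels),
                 vocabulary = vocab, mode = "multilabel")
}

#' Crossvalidated evaluation of one configuration
#'
#' For each fold, feature learning (when the configuration uses learned
#' features) sees only training-fold audio; the classifier is trained on
#' training folds and evaluated on the held-out fold; AUC (micro and macro)
#' and MAP are computed per fold. Headline statistics are the means of the
#' per-fold values; statistics recomputed on the pooled scores are stored
#' separately.
#'
#' @param mels Named list of Mel spectrograms (one per recording, noise
#'   reduction already applied if configured).
#' @param ann An [annotation_set()] covering all recordings.
#' @param folds Named integer vector: recording id -> fold index.
#' @param feature Feature configuration label (see [feature_configs()]).
#' @param mode Classifier mode.
#' @param windowing A [decision_windowing()].
#' @param k Dictionary size for learned features.
#' @param seed Integer seed for feature learning and the forests.
#' @param capacity Reservoir capacity for dictionary learning.
#' @param extra_learning_mels Optional named list of additional Mel
#'   spectrograms used only for dictionary fitting (feature-learning data
#'   augmentation), never for classifier training or testing.
#' @param extra_train Optional list `list(mels = <named list>, ann =
#'   <annotation_set>)` of additional labelled recordings added to the
#'   classifier's training rows (and to dictionary fitting) in every fold.
#' @return An `eval_result`: list with `auc`, `auc_macro`, `map`, `per_fold`
#'   (data.frame), `pooled` (statistics on pooled scores), `predictions`,
#'   `config`, and per-fold bookkeeping `counts` (dictionary recordings and
#'   training rows).
#' @export
run_crossvalidation <- function(mels, ann, folds, feature = "melspec-ms",
                                mode = "multilabel",
                                windowing = decision_windowing(),
                                k = 500, seed = 1L, capacity = 100000,
                                extra_learning_mels = NULL,
                                extra_train = NULL) {
  ids <- names(mels)
  stopifnot(!is.null(ids), all(ids %in% names(folds)))
  fold_of <- folds[ids]
  fold_ids <- sort(unique(fold_of))
  if (length(fold_ids) < 2L) stopf("need at least 2 folds")
  train_ann <- ann
  extra_ids <- character(0)
  all_mels <- mels
  if (!is.null(extra_train)) {
    extra_ids <- names(extra_train$mels)
    all_mels <- c(mels, extra_train$mels)
    train_ann <- merge_annotations(ann, extra_train$ann)
  }

  per_fold <- list()
  pred_all <- NULL
  dict_hashes <- character(0)
  counts <- list()
  for (f in fold_ids) {
    test_ids <- ids[fold_of == f]
    train_ids <- ids[fold_of != f]
    if (length(test_ids) == 0L) stopf("fold %s has no test items", f)
    dict_mels <- c(all_mels[c(train_ids, extra_ids)], extra_learning_mels)
    fs <- feature_sequences(all_mels, feature, dict_mels, k = k,
                            seed = seed + as.integer(f), capacity = capacity)
    if (!is.null(fs$dictionary))
      dict_hashes <- c(dict_hashes, object_fingerprint(fs$dictionary))
    tab_train <- make_training_table(fs$seqs[c(train_ids, extra_ids)],
                                     train_ann, windowing, fs$scheme)
    tab_test <- make_training_table(fs$seqs[test_ids], train_ann, windowing,
                                    fs$scheme)
    model <- train_classifier(tab_train, mode = mode, seed = seed + as.integer(f))
    pred <- predict_scores(model, tab_test)
    pred <- pred[, ann$vocabulary, drop = FALSE]  # evaluate on the target vocabulary
    per_fold[[length(per_fold) + 1L]] <- data.frame(
      fold = f,
      auc = multilabel_auc(pred, ann, "micro"),
      auc_macro = tryCatch(multilabel_auc(pred, ann, "macro"),
                           error = function(e) NA_real_),
      map = mean_average_precision(pred, ann))
    counts[[length(counts) + 1L]] <- data.frame(
      fold = f, n_dictionary_recordings = length(dict_mels),
      n_training_rows = nrow(tab_train$x))
    pred_all <- rbind(pred_all, unclass(pred))
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- list(auc = multilabel_auc(pred_all, ann, "micro"),
                 map = mean_average_precision(pred_all, ann))
  structure(list(auc = mean(per_fold$auc),
                 auc_macro = mean(per_fold$auc_macro),
                 map = mean(per_fold$map),
                 per_fold = per_fold,
                 pooled = pooled,
                 predictions = pred_all,
                 dictionary_fingerprints = dict_hashes,
                 counts = do.call(rbind, counts),
                 config = list(feature = feature, mode = mode,
                               windowing = windowing, k = k, seed = seed)),
            class = "eval_result")
}
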