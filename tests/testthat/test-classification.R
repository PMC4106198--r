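# Small, well-separated two/three-class fixtures built from feature sequences
# whose class means are offset.
make_sep_seqs <- function(n_per_class, classes, width = 6, n_frames = 30,
                          frame_duration_s = 1, sd = 0.3, seed = 50) {
  set.seed(seed)
  seqs <- list(); ids <- character(0); labels <- list()
  for (ci in seq_along(classes)) {
    mu <- rep(0, width); mu[ci] <- 3
    for (r in seq_len(n_per_class)) {
      id <- sprintf("%s_%02d", classes[ci], r)
      seqs[[id]] <- structure(
        matrix(rnorm(n_frames * width, mean = rep(mu, each = n_frames), sd = sd),
               n_frames, width),
        frame_duration_s = frame_duration_s)
      ids <- c(ids, id); labels[[length(labels) + 1L]] <- classes[ci]
    }
  }
  list(seqs = seqs,
       ann = annotation_set(ids, labels, vocabulary = classes,
                            mode = "single_label"))
}

test_that("decision windows split recordings by duration with partial tails", {
  fx <- make_sep_seqs(1, c("a", "b"), n_frames = 120)
  tab <- make_training_table(fx$seqs, fx$ann, decision_windowing(60, "mean"))
  expect_equal(as.integer(table(tab$recording_id)), c(2L, 2L))

  fx130 <- make_sep_seqs(1, c("a", "b"), n_frames = 130)
  tab130 <- make_training_table(fx130$seqs, fx130$ann, decision_windowing(60, "mean"))
  expect_equal(sum(tab130$recording_id == "a_01"), 3L)  # third window covers 10 s

  whole <- make_training_table(fx130$seqs, fx130$ann, decision_windowing("whole"))
  expect_equal(nrow(whole$x), 2L)

  expect_warning(
    make_training_table(make_sep_seqs(1, c("a", "b"), n_frames = 20)$seqs,
                        fx$ann, decision_windowing(60, "mean")),
    "shorter than one decision window")
})

test_that("window rows inherit the recording's full label set", {
  seqs <- list(r1 = random_feature_seq(10, 3, frame_duration_s = 1))
  ann <- annotation_set(c("r1", "r2"), list(c("a", "b"), "a"),
                       vocabulary = c("a", "b"))
  tab <- make_training_table(seqs, ann, decision_windowing(5, "mean"))
  expect_equal(nrow(tab$x), 2L)
  expect_equal(tab$labels, list(c("a", "b"), c("a", "b")))
})

test_that("the three classifier modes obey their contracts", {
  fx <- make_sep_seqs(8, c("a", "b", "c"))
  tab <- make_training_table(fx$seqs, fx$ann, decision_windowing("whole"))

  sl <- train_classifier(tab, "single_label", seed = 1)
  br <- train_classifier(tab, "binary_relevance", seed = 1)
  ml <- train_classifier(tab, "multilabel", seed = 1)

  expect_length(br$forests, 3L)  # one sub-model per class
  p_sl <- predict_scores(sl, tab)
  expect_equal(unname(rowSums(p_sl)), rep(1, nrow(p_sl)), tolerance = 1e-9)
  for (p in list(p_sl, predict_scores(br, tab), predict_scores(ml, tab))) {
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(dim(p), c(24L, 3L))
  }

  # training-set separation on separable classes
  truth <- label_matrix(fx$ann)
  expect_gt(auc_score(as.numeric(p_sl), as.numeric(truth)), 0.99)

  # determinism
  expect_identical(predict_scores(train_classifier(tab, "multilabel", seed = 4), tab),
                   predict_scores(train_classifier(tab, "multilabel", seed = 4), tab))

  # mode mismatch: multilabel annotations in single_label mode
  multi_ann <- annotation_set(fx$ann$recording_id,
                              lapply(fx$ann$labels, function(l) c(l, "extra")),
                              vocabulary = c("a", "b", "c", "extra"))
  tab_multi <- make_training_table(fx$seqs, multi_ann, decision_windowing("whole"))
  expect_error(train_classifier(tab_multi, "single_label"), "exactly one label")
})

test_that("binary relevance emits constant 0 for classes without positives", {
  fx <- make_sep_seqs(6, c("a", "b"))
  ann <- annotation_set(fx$ann$recording_id, fx$ann$labels,
                        vocabulary = c("a", "b", "ghost"))
  tab <- make_training_table(fx$seqs, ann, decision_windowing("whole"))
  expect_warning(m <- train_classifier(tab, "binary_relevance", seed = 2),
                 "no positive training examples")
  p <- predict_scores(m, tab)
  expect_equal(unname(p[, "ghost"]), rep(0, nrow(p)))
})

test_that("per-window scores pool by mean or max exactly", {
  fx <- make_sep_seqs(4, c("a", "b"), n_frames = 40)
  tab_mean <- make_training_table(fx$seqs, fx$ann, decision_windowing(10, "mean"))
  tab_max <- make_training_table(fx$seqs, fx$ann, decision_windowing(10, "max"))
  m <- train_classifier(tab_mean, "multilabel", seed = 3)
  p_mean <- predict_scores(m, tab_mean)
  p_max <- predict_scores(m, tab_max)

  win <- attr(p_mean, "window_scores")
  for (id in rownames(p_mean)) {
    rows <- win[tab_mean$recording_id == id, , drop = FALSE]
    expect_equal(p_mean[id, ], apply(rows, 2, mean))
    expect_equal(p_max[id, ], apply(rows, 2, max))
  }
  expect_true(all(unclass(p_max) >= unclass(p_mean) - 1e-12))

  narrow <- lapply(fx$seqs, function(s)
    structure(s[, 1:3], frame_duration_s = attr(s, "frame_duration_s")))
  bad <- make_training_table(narrow, fx$ann, decision_windowing(10, "mean"),
                             scheme = "mean_std")
  expect_error(predict_scores(m, bad), "dimension mismatch")
})
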