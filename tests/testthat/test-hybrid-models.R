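test_that("the 15 hybrid specifications follow the canonical grid", {
  sp <- hybrid_model_specs()
  expect_equal(nrow(sp), 15)
  expect_equal(sp$alternative, paste0("A", 1:15))
  expect_equal(sp$model[1], "ReF-decision tree")
  expect_equal(sp$model[6], "IG-decision tree")
  expect_equal(sp$model[12], "Chi2-SVM")
  expect_equal(anyDuplicated(sp[, c("fs_technique", "classifier")]), 0L)
})

test_that("feature weighting scales selected columns and drops the rest", {
  pt <- toy_patients(5)
  w <- structure(c(sig = 0.5), technique = "chi2",
                 class = "feature_weights")
  out <- apply_feature_weights(pt, w)
  expect_named(out, c("sig", "severity"))
  expect_equal(out$sig, pt$sig * 0.5)
  w1 <- structure(c(sig = 1, noise = 1), class = "feature_weights")
  out1 <- apply_feature_weights(pt, w1)
  expect_equal(out1$sig, pt$sig)
  w0 <- structure(c(noise = 0), class = "feature_weights")
  expect_true(all(apply_feature_weights(pt, w0)$noise == 0))
  wbad <- structure(c(ghost = 1), class = "feature_weights")
  expect_error(apply_feature_weights(pt, wbad), "absent")
})

test_that("the stratified split partitions each class at the set fraction", {
  pt <- toy_patients(n_per_class = 259)      # 777 balanced rows
  sp <- split_train_test(pt, frac = 0.66, seed = 2)
  expect_equal(nrow(sp$train), 513)          # 3 * round(0.66 * 259)
  expect_equal(nrow(sp$test), 264)
  expect_equal(unname(table(sp$train$severity)), rep(171L, 3),
               ignore_attr = TRUE)
  # partition: no overlap, union is everything
  expect_equal(sort(c(sp$train_idx, setdiff(seq_len(777), sp$train_idx))),
               seq_len(777))
  # determinism
  sp2 <- split_train_test(pt, frac = 0.66, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_train_test(toy_patients(1), frac = 0.66),
               "too small")
})

test_that("confusion-count metrics follow their closed forms", {
  m <- confusion_metrics(tp = 9, tn = 9, fp = 1, fn = 1)
  expect_equal(m[["accuracy"]], 0.9)
  m2 <- confusion_metrics(tp = 8, tn = 0, fp = 2, fn = 4)
  expect_equal(m2[["precision"]], 0.8)
  expect_equal(m2[["recall"]], 2 / 3, tolerance = 1e-9)
  expect_equal(m2[["f1"]], 16 / 22, tolerance = 1e-9)
})

test_that("micro-averaged multiclass metrics collapse to accuracy", {
  set.seed(14)
  for (i in 1:10) {
    truth <- sample(0:2, 60, TRUE)
    pred <- ifelse(runif(60) < 0.7, truth, sample(0:2, 60, TRUE))
    m <- micro_metrics(truth, pred)
    expect_equal(m[["precision"]], m[["accuracy"]], tolerance = 1e-12)
    expect_equal(m[["recall"]], m[["accuracy"]], tolerance = 1e-12)
    expect_equal(m[["f1"]], m[["accuracy"]], tolerance = 1e-12)
    expect_equal(m[["accuracy"]], mean(truth == pred), tolerance = 1e-12)
  }
})

test_that("every classifier evaluates with metrics in range", {
  pt <- toy_patients(n_per_class = 30)
  sp <- split_train_test(pt, seed = 3)
  for (clf in c("decision_tree", "naive_bayes", "knn", "svm", "adaboost")) {
    row <- evaluate_model(clf, sp$train, sp$test, seed = 1, timing = "none")
    expect_true(all(unlist(row[c("C3", "C4", "C5", "C6", "C7")]) >= 0))
    expect_true(all(unlist(row[c("C3", "C4", "C5", "C6", "C7")]) <= 1))
    expect_equal(row$C1, 0)
    expect_equal(row$C4, row$C5)
    # the planted signal is strong: every learner beats chance
    expect_gt(row$C4, 1 / 3)
    # reproducible under a fixed seed
    row2 <- evaluate_model(clf, sp$train, sp$test, seed = 1, timing = "none")
    expect_equal(row, row2)
  }
})

test_that("a perfect classifier scores 1 on every quality criterion", {
  # class is a deterministic step in `sig`, so the tree learns it exactly
  cls <- rep(0:2, each = 20)
  pt <- structure(data.frame(sig = cls / 2, severity = cls),
                  class_col = "severity",
                  class = c("patient_table", "data.frame"))
  sp <- split_train_test(pt, seed = 1)
  row <- evaluate_model("decision_tree", sp$train, sp$test, timing = "none")
  expect_equal(unlist(row[c("C3", "C4", "C5", "C6", "C7")]),
               c(C3 = 1, C4 = 1, C5 = 1, C6 = 1, C7 = 1))
  expect_error(evaluate_model("decision_tree",
                              structure(data.frame(sig = 1:5 / 5,
                                                   severity = rep(1, 5)),
                                        class_col = "severity",
                                        class = c("patient_table",
                                                  "data.frame")),
                              sp$test), "single-class")
})

test_that("decision matrices validate, order and round-trip", {
  dm <- example_decision_matrix()
  expect_s3_class(dm, "decision_matrix")
  expect_equal(dim(dm), c(15L, 9L))
  expect_equal(dm$alternative, paste0("A", 1:15))
  expect_equal(unname(dm_directions(dm)[c("C1", "C2", "C3")]),
               c("cost", "cost", "benefit"))
  expect_true(all(as.matrix(dm[, paste0("C", 3:7)]) >= 0 &
                  as.matrix(dm[, paste0("C", 3:7)]) <= 1))
  # round trip through a file
  path <- withr::local_tempfile(fileext = ".csv")
  write_decision_matrix(dm, path)
  dm2 <- read_decision_matrix(path)
  expect_equal(as.data.frame(dm2), as.data.frame(dm), tolerance = 1e-12)
  expect_equal(dm_directions(dm2), dm_directions(dm))
  # structural errors
  rows <- as.data.frame(dm)
  expect_error(build_decision_matrix(rows[-1, ]), "missing alternative")
  expect_error(build_decision_matrix(rbind(rows, rows[1, ]),
                                     alternatives = rows$alternative),
               "duplicate")
})
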