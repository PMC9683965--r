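#' Hybrid diagnosis models
#'
#' A hybrid model is one (feature-selection technique, classifier) pair
#' trained on the FWZIC-weighted feature subset. Three filter techniques
#' crossed with five classifiers give the 15 alternatives A1-A15; their
#' seven performance criteria (train time, test time, AUC, accuracy, F1,
#' precision, recall) form the decision matrix handed to FDOSM.
#'
#' @name hybrid_models
NULL

.fs_order <- c("relieff", "infogain", "chi2")
.clf_order <- c("decision_tree", "svm", "naive_bayes", "knn", "adaboost")
.criteria <- c("C1", "C2", "C3", "C4", "C5", "C6", "C7")
.criteria_labels <- c(C1 = "train_time", C2 = "test_time", C3 = "auc",
                      C4 = "accuracy", C5 = "f1", C6 = "precision",
                      C7 = "recall")
.directions <- c(C1 = "cost", C2 = "cost", C3 = "benefit", C4 = "benefit",
                 C5 = "benefit", C6 = "benefit", C7 = "benefit")

#' The 15 hybrid model specifications
#'
#' Alternatives A1-A15 in canonical order: feature-selection technique
#' outermost (ReliefF, information gain, chi-square), classifier innermost
#' (decision tree, SVM, naive Bayes, KNN, AdaBoost).
#'
#' @return a data.frame with columns `alternative`, `fs_technique`,
#'   `classifier`, `model`.
#' @export
hybrid_model_specs <- function() {
  g <- expand.grid(classifier = .clf_order, fs_technique = .fs_order,
                   stringsAsFactors = FALSE)[, 2:1]
  short <- c(relieff = "ReF", infogain = "IG", chi2 = "Chi2")
  clf <- c(decision_tree = "decision tree", svm = "SVM",
           naive_bayes = "naive Bayes", knn = "KNN", adaboost = "AdaBoost")
  data.frame(alternative = paste0("A", seq_len(nrow(g))),
             fs_technique = g$fs_technique, classifier = g$classifier,
             model = paste0(short[g$fs_technique], "-", clf[g$classifier]),
             stringsAsFactors = FALSE)
}

#' Inject FWZIC feature weights into a patient table
#'
#' Each weighted feature column is multiplied by its weight; columns
#' without a weight (the unselected features) are dropped; the class column
#' is untouched. This is the bridge between criterion weighting and model
#' training: the classifier sees each feature scaled by its expert-derived
#' importance.
#'
#' @param t a normalized `patient_table`.
#' @param w a `feature_weights` vector (named).
#' @return the weighted table restricted to the selected features + class.
#' @export
apply_feature_weights <- function(t, w) {
  missing <- setdiff(names(w), names(t))
  if (length(missing) > 0) {
    stop("weighted feature(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- t[, c(names(w), pt_class_col(t)), drop = FALSE]
  for (nm in names(w)) out[[nm]] <- out[[nm]] * as.numeric(w[[nm]])
  rebuild_pt(out, t)
}

#' Stratified train/test split
#'
#' Splits by class so each stratum contributes `round(frac * n_class)`
#' training rows; deterministic under `seed`.
#'
#' @param t a `patient_table`.
#' @param frac training fraction (default 0.66).
#' @param seed integer seed.
#' @return a list with data.frames `train` and `test` and the integer
#'   `train_idx`.
#' @export
split_train_test <- function(t, frac = 0.66, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  cls <- t[[pt_class_col(t)]]
  rng <- local_rng(seed)
  train_idx <- integer(0)
  for (lev in sort(unique(cls))) {
    idx <- which(cls == lev)
    n_tr <- round(frac * length(idx))
    if (n_tr < 1 || n_tr >= length(idx)) {
      stop(sprintf("class %s too small to stratify at frac = %g", lev, frac),
           call. = FALSE)
    }
    train_idx <- c(train_idx, idx[rng$sample_int(length(idx), n_tr)])
  }
  train_idx <- sort(train_idx)
  list(train = rebuild_pt(t[train_idx, , drop = FALSE], t),
       test = rebuild_pt(t[-train_idx, , drop = FALSE], t),
       train_idx = train_idx)
}

# ---- classifiers ----------------------------------------------------------

# Multiclass AdaBoost (SAMME) over depth-limited rpart stumps.
fit_adaboost <- function(x, y, n_rounds = 50, maxdepth = 1) {
  n <- nrow(x)
  k <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  dat <- data.frame(x, .y = y, check.names = FALSE)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          xval = 0))
    pred <- stats::predict(fit, dat, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 1 - 1 / k) break          # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break              # perfect stump: converged
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "samme_boost")
}

#' @export
predict.samme_boost <- function(object, newdata, ...) {
  votes <- matrix(0, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (i in seq_along(object$stumps)) {
    pred <- stats::predict(object$stumps[[i]], newdata, type = "class")
    votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] +
      object$alphas[i]
  }
  prob <- votes / pmax(rowSums(votes), .Machine$double.eps)
  list(class = factor(object$levels[max.col(prob, ties.method = "first")],
                      levels = object$levels),
       prob = prob)
}

# Fit one classifier; returns list(predict(newx) -> list(class, prob)).
fit_classifier <- function(classifier, x, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("training set has a single class; cannot fit", call. = FALSE)
  }
  dat <- data.frame(x, .y = y, check.names = FALSE)
  switch(classifier,
    decision_tree = {
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class")
      function(newx) {
        prob <- stats::predict(fit, newx, type = "prob")
        list(class = stats::predict(fit, newx, type = "class"), prob = prob)
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x, y)
      function(newx) {
        prob <- stats::predict(fit, newx, type = "raw")
        colnames(prob) <- levels(y)
        list(class = stats::predict(fit, newx, type = "class"), prob = prob)
      }
    },
    knn = {
      fit <- caret::knn3(as.matrix(x), y, k = 5)
      function(newx) {
        prob <- stats::predict(fit, as.matrix(newx), type = "prob")
        list(class = factor(levels(y)[max.col(prob, ties.method = "first")],
                            levels = levels(y)),
             prob = prob)
      }
    },
    svm = {
      fit <- local_rng(seed)$with(function()
        e1071::svm(x, y, probability = TRUE))
      function(newx) {
        cl <- stats::predict(fit, newx, probability = TRUE)
        prob <- attr(cl, "probabilities")[, levels(y), drop = FALSE]
        list(class = factor(as.character(cl), levels = levels(y)),
             prob = prob)
      }
    },
    adaboost = {
      fit <- fit_adaboost(x, y)
      function(newx) predict(fit, newx)
    },
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE))
}

# ---- metrics --------------------------------------------------------------

#' Micro-averaged classification metrics
#'
#' Per-class true/false positives and false negatives are pooled before
#' forming precision, recall and F1 (micro averaging). For single-label
#' multiclass prediction every misclassification is simultaneously one
#' false positive and one false negative, so micro precision = recall =
#' F1 = accuracy; the identity is asserted on every call.
#'
#' @param truth,pred factors (or vectors) of true and predicted labels.
#' @return named numeric vector: accuracy, precision, recall, f1.
#' @export
micro_metrics <- function(truth, pred) {
  lev <- sort(unique(c(as.character(truth), as.character(pred))))
  truth <- factor(as.character(truth), levels = lev)
  pred <- factor(as.character(pred), levels = lev)
  tp <- fp <- fn <- 0
  for (l in lev) {
    tp <- tp + sum(pred == l & truth == l)
    fp <- fp + sum(pred == l & truth != l)
    fn <- fn + sum(pred != l & truth == l)
  }
  acc <- mean(pred == truth)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  stopifnot(abs(prec - acc) < 1e-12, abs(rec - acc) < 1e-12,
            abs(f1 - acc) < 1e-12)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / (TP + FP + FN + TN)`, recall `TP / (TP + FN)`,
#' precision `TP / (TP + FP)` and F1 `2TP / (2TP + FP + FN)`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named numeric vector: accuracy, precision, recall, f1.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = tp / (tp + fp),
    recall = tp / (tp + fn),
    f1 = 2 * tp / (2 * tp + fp + fn))
}

# Macro one-vs-rest AUC from a class-probability matrix.
macro_auc <- function(truth, prob) {
  lev <- colnames(prob)
  aucs <- vapply(lev, function(l) {
    resp <- as.integer(as.character(truth) == l)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(resp, prob[, l], direction = "<",
                         levels = c(0, 1), quiet = TRUE))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Train and evaluate one hybrid model
#'
#' Fits the classifier on the training rows and measures, on the test rows,
#' the seven decision criteria: wall-clock train and test time (seconds;
#' cost), macro one-vs-rest AUC, and micro-averaged accuracy, F1,
#' precision and recall (benefit). With `timing = "none"` both times are
#' reported as 0 so repeated runs are bit-identical.
#'
#' @param classifier one of `"decision_tree"`, `"svm"`, `"naive_bayes"`,
#'   `"knn"`, `"adaboost"`.
#' @param train,test `patient_table`s sharing the same columns.
#' @param seed seed for stochastic learners.
#' @param timing `"measured"` for wall-clock seconds, `"none"` for zeros.
#' @return a one-row data.frame with columns C1..C7.
#' @export
evaluate_model <- function(classifier, train, test, seed = 1L,
                           timing = c("measured", "none")) {
  timing <- match.arg(timing)
  cc <- pt_class_col(train)
  feats <- pt_features(train)
  ytr <- as.factor(train[[cc]])
  if (nlevels(droplevels(ytr)) < 2) {
    stop("training set is single-class", call. = FALSE)
  }
  t_train <- system.time(
    model <- fit_classifier(classifier, train[, feats, drop = FALSE], ytr,
                            seed = seed))[["elapsed"]]
  t_test <- system.time(
    out <- model(test[, feats, drop = FALSE]))[["elapsed"]]
  mm <- micro_metrics(test[[cc]], out$class)
  auc <- macro_auc(test[[cc]], out$prob)
  data.frame(C1 = if (timing == "measured") t_train else 0,
             C2 = if (timing == "measured") t_test else 0,
             C3 = auc, C4 = mm[["accuracy"]], C5 = mm[["f1"]],
             C6 = mm[["precision"]], C7 = mm[["recall"]])
}

# ---- decision matrix ------------------------------------------------------

#' Assemble the 15-alternative decision matrix
#'
#' @param rows a data.frame with columns `alternative`, `model`, C1..C7 —
#'   one row per hybrid model, any order; rows are reordered to the
#'   canonical A1..A15 sequence.
#' @param directions named character vector over C1..C7 with values
#'   `"cost"` / `"benefit"`.
#' @param alternatives expected alternative ids (default A1..A15).
#' @return a `decision_matrix`: data.frame (alternative, model, C1..C7)
#'   with attribute `directions`.
#' @export
build_decision_matrix <- function(rows, directions = .directions,
                                  alternatives = paste0(
                                    "A", seq_len(nrow(rows)))) {
  req <- c("alternative", "model", .criteria)
  if (!all(req %in% names(rows))) {
    stop("decision-matrix rows need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rows$alternative)) {
    stop("duplicate alternative id in decision matrix", call. = FALSE)
  }
  miss <- setdiff(alternatives, rows$alternative)
  if (length(miss) > 0) {
    stop("missing alternative(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[match(alternatives, rows$alternative), req]
  if (anyNA(rows[, .criteria])) {
    stop("decision matrix has missing cells", call. = FALSE)
  }
  if (!setequal(names(directions), .criteria) ||
      !all(directions %in% c("cost", "benefit"))) {
    stop("directions must map C1..C7 to 'cost'/'benefit'", call. = FALSE)
  }
  rownames(rows) <- NULL
  structure(rows, directions = directions[.criteria],
            class = c("decision_matrix", "data.frame"))
}

#' @export
print.decision_matrix <- function(x, ...) {
  d <- attr(x, "directions")
  cat(sprintf("<decision_matrix: %d alternatives x %d criteria (%s)>\n",
              nrow(x), length(d),
              paste0(names(d), ":", substr(d, 1, 1), collapse = " ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write / read a decision matrix as delimited text
#'
#' The criterion directions are kept in a `# directions:` comment line.
#'
#' @param dm a `decision_matrix`.
#' @param path file path.
#' @export
write_decision_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# directions: %s",
                     paste(attr(dm, "directions"), collapse = ",")), con)
  utils::write.csv(as.data.frame(dm), con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_decision_matrix
#' @export
read_decision_matrix <- function(path) {
  first <- readLines(path, n = 1)
  directions <- .directions
  if (startsWith(first, "# directions:")) {
    d <- strsplit(sub("^# directions:\\s*", "", first), ",")[[1]]
    directions <- stats::setNames(trimws(d), .criteria)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  build_decision_matrix(df, directions, alternatives = df$alternative)
}

#' Criterion directions of a decision matrix
#' @param dm a `decision_matrix`.
#' @return named character vector over C1..C7.
#' @export
dm_directions <- function(dm) attr(dm, "directions")
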