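#' Filter feature selection
#'
#' Three learner-independent scorers of feature-class association, run on
#' the preprocessed (complete, normalized, encoded) patient table:
#' chi-square, information gain, and multiclass ReliefF. Each returns a
#' `feature_scores` table; [select_features()] turns scores into the
#' surviving feature set under a configurable rule.
#'
#' @name feature_selection
NULL

feature_scores <- function(feature, score, technique) {
  ord <- order(-score, feature)  # ties broken by feature name
  df <- data.frame(feature = feature, score = score,
                   stringsAsFactors = FALSE)[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, technique = technique,
            class = c("feature_scores", "data.frame"))
}

# Equal-frequency discretization used by the contingency-based scorers;
# encoded categoricals (few distinct values) pass through unchanged.
discretize_ef <- function(v, bins = 4) {
  u <- unique(v)
  if (length(u) <= bins) return(match(v, sort(u)))
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = br, include.lowest = TRUE))
}

check_class <- function(cls) {
  if (length(unique(cls)) < 2) {
    stop("class column has zero variance; scores are undefined",
         call. = FALSE)
  }
}

#' Chi-square feature scores
#'
#' For each feature, the Pearson chi-square statistic of the feature-class
#' contingency table (no continuity correction). Numeric features are
#' discretized by equal-frequency binning first.
#'
#' @param t a complete `patient_table`.
#' @param bins number of equal-frequency bins for numeric features.
#' @return a `feature_scores` data.frame (feature, score, rank).
#' @export
score_chi2 <- function(t, bins = 4) {
  cls <- t[[pt_class_col(t)]]
  check_class(cls)
  feats <- pt_features(t)
  sc <- vapply(feats, function(nm) {
    f <- discretize_ef(t[[nm]], bins)
    if (length(unique(f)) < 2) return(0)
    tab <- table(f, cls)
    unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
  }, numeric(1))
  feature_scores(feats, sc, "chi2")
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information-gain feature scores
#'
#' Mutual information between feature and class in bits:
#' `H(class) - H(class | feature)`, with numeric features discretized by
#' equal-frequency binning.
#'
#' @inheritParams score_chi2
#' @return a `feature_scores` data.frame.
#' @export
score_infogain <- function(t, bins = 4) {
  cls <- t[[pt_class_col(t)]]
  check_class(cls)
  h_class <- entropy_bits(cls)
  feats <- pt_features(t)
  sc <- vapply(feats, function(nm) {
    f <- discretize_ef(t[[nm]], bins)
    cond <- sum(vapply(split(cls, f), function(g) {
      length(g) / length(cls) * entropy_bits(g)
    }, numeric(1)))
    max(h_class - cond, 0)
  }, numeric(1))
  feature_scores(feats, sc, "infogain")
}

#' Multiclass ReliefF feature scores
#'
#' For each of `m` sampled instances, the weight of every feature is
#' decreased by its mean distance to the instance's `k` nearest same-class
#' neighbours (hits) and increased, for every other class `c`, by the
#' prior-weighted mean distance to the `k` nearest members of `c` (misses):
#' the coefficient is `P(c) / (1 - P(class(x)))`. Distances per feature are
#' normalized absolute differences, so weights land in \[-1, 1\]. With
#' `m = nrow(t)` (the default) every row is used once, in order, and the
#' result is deterministic; smaller `m` samples rows under `seed`.
#'
#' @param t a complete, normalized `patient_table`.
#' @param k neighbour count per class (default 10).
#' @param m number of sampled instances; default all rows.
#' @param seed seed used only when `m < nrow(t)`.
#' @return a `feature_scores` data.frame.
#' @export
score_relieff <- function(t, k = 10, m = nrow(t), seed = 1L) {
  cls <- t[[pt_class_col(t)]]
  check_class(cls)
  counts <- table(cls)
  if (min(counts) < k) {
    stop(sprintf("ReliefF with k = %d needs at least k members per class ",
                 k), "(smallest class has ", min(counts), ")", call. = FALSE)
  }
  k_eff <- k
  feats <- pt_features(t)
  x <- as.matrix(t[, feats, drop = FALSE])
  rngs <- apply(x, 2, function(v) diff(range(v)))
  rngs[rngs == 0] <- 1          # constant feature: all diffs are 0 anyway
  n <- nrow(x)
  idx <- if (m >= n) seq_len(n) else local_rng(seed)$sample_int(n, m)
  priors <- counts / n
  w <- stats::setNames(numeric(length(feats)), feats)
  byclass <- split(seq_len(n), cls)
  for (i in idx) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))  # Euclidean to all rows
    ci <- as.character(cls[i])
    for (lev in names(byclass)) {
      pool <- setdiff(byclass[[lev]], i)
      kk <- min(k_eff, length(pool))
      if (kk < 1) next
      nb <- pool[order(di[pool])[seq_len(kk)]]
      diffs <- colMeans(abs(x[nb, , drop = FALSE] -
                            matrix(x[i, ], kk, ncol(x), byrow = TRUE)) /
                        matrix(rngs, kk, ncol(x), byrow = TRUE))
      if (lev == ci) {
        w <- w - diffs / length(idx)
      } else {
        w <- w + (priors[[lev]] / (1 - priors[[ci]])) * diffs / length(idx)
      }
    }
  }
  feature_scores(feats, unname(w), "relieff")
}

#' Select surviving features from a score table
#'
#' Rules: `"positive"` keeps features with score > 0 (the default),
#' `"top_k"` keeps the `k` best, `"threshold"` keeps scores strictly above
#' `threshold`. Ties at any cutoff are broken by feature-name order, so the
#' selection is deterministic.
#'
#' @param scores a `feature_scores` table.
#' @param rule selection rule.
#' @param k kept-feature count for `"top_k"`.
#' @param threshold score cutoff for `"threshold"`.
#' @return character vector of surviving features, best first.
#' @export
select_features <- function(scores, rule = c("positive", "top_k", "threshold"),
                            k = NULL, threshold = NULL) {
  stopifnot(inherits(scores, "feature_scores"))
  rule <- match.arg(rule)
  kept <- switch(rule,
    positive  = scores$feature[scores$score > 0],
    top_k     = {
      if (is.null(k)) stop("rule 'top_k' needs k", call. = FALSE)
      scores$feature[seq_len(min(k, nrow(scores)))]
    },
    threshold = {
      if (is.null(threshold)) stop("rule 'threshold' needs threshold",
                                   call. = FALSE)
      scores$feature[scores$score > threshold]
    })
  if (length(kept) == 0) {
    stop(sprintf("selection rule '%s' kept no features", rule), call. = FALSE)
  }
  kept
}

#' Write a score table as delimited text
#'
#' Columns: feature, score, rank, selected flag under the given rule.
#'
#' @param scores a `feature_scores` table.
#' @param path output file.
#' @param selected character vector of selected features.
#' @export
write_feature_scores <- function(scores, path,
                                 selected = select_features(scores)) {
  df <- as.data.frame(scores)
  df$selected <- df$feature %in% selected
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
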