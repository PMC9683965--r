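pt_of <- function(df, class_col = "severity") {
  structure(df, class_col = class_col,
            class = c("patient_table", "data.frame"))
}

test_that("chi-square scores match hand-computed contingency statistics", {
  # perfect 2x2 association on n = 20 balanced rows gives chi2 = n
  cls <- rep(0:1, each = 10)
  perfect <- pt_of(data.frame(f = cls, severity = cls))
  expect_equal(score_chi2(perfect)$score, 20)
  # independent feature scores 0
  indep <- pt_of(data.frame(f = rep(c(0, 1), 10), severity = cls))
  expect_equal(score_chi2(indep)$score, 0)
  # contingency [[10,0],[2,8]] -> 13.3333 (sum (O-E)^2 / E by hand)
  f <- c(rep(0, 10), rep(0, 2), rep(1, 8))
  y <- c(rep(0, 10), rep(1, 10))
  expect_equal(score_chi2(pt_of(data.frame(f = f, severity = y)))$score,
               40 / 3, tolerance = 1e-6)
  expect_error(score_chi2(pt_of(data.frame(f = 1:4, severity = rep(1, 4)))),
               "zero variance")
})

test_that("information gain equals H(class) - H(class|feature) in bits", {
  cls <- rep(0:1, each = 10)
  perfect <- pt_of(data.frame(f = cls, severity = cls))
  expect_equal(score_infogain(perfect)$score, 1)   # = H(class) = 1 bit
  const <- pt_of(data.frame(f = rep(1, 20), severity = cls))
  expect_equal(score_infogain(const)$score, 0)
  # class (0,0,1,1), feature (0,1,1,1): 1 - (3/4) * H(1/3) = 0.31128
  t <- pt_of(data.frame(f = c(0, 1, 1, 1), severity = c(0, 0, 1, 1)))
  expect_equal(score_infogain(t)$score, 0.31128, tolerance = 1e-5)
  expect_equal(score_infogain(t)$score,
               oracle_entropy(t$severity) -
                 (1 / 4 * 0 + 3 / 4 * oracle_entropy(c(0, 1, 1))),
               tolerance = 1e-12)
})

test_that("information gain never exceeds the class entropy", {
  set.seed(21)
  for (i in 1:10) {
    df <- data.frame(f1 = runif(30), f2 = sample(0:3, 30, TRUE),
                     severity = sample(0:2, 30, TRUE))
    sc <- score_infogain(pt_of(df))
    expect_true(all(sc$score <= oracle_entropy(df$severity) + 1e-12))
    expect_true(all(sc$score >= 0))
  }
})

test_that("ReliefF reproduces exhaustive traces on toy instances", {
  # perfectly separating feature, 4 rows, k = 1: every update is -0 + 1
  toy <- pt_of(data.frame(f = c(0, 0, 1, 1), severity = c(0, 0, 1, 1)))
  expect_equal(score_relieff(toy, k = 1)$score, 1)
  # constant feature keeps weight 0
  toy2 <- pt_of(data.frame(f = c(0, 0, 1, 1), g = rep(0.5, 4),
                           severity = c(0, 0, 1, 1)))
  sc <- score_relieff(toy2, k = 1)
  expect_equal(sc$score[sc$feature == "g"], 0)
  # 6-point 3-class exhaustive oracle, k = 1: for each row the nearest
  # hit/miss diffs are enumerable by hand on a 1-d feature
  x <- c(0.0, 0.1, 0.5, 0.6, 0.9, 1.0)
  y <- c(0, 0, 1, 1, 2, 2)
  t3 <- pt_of(data.frame(f = x, severity = y))
  w <- 0
  for (i in seq_along(x)) {
    hits <- which(y == y[i] & seq_along(x) != i)
    w <- w - abs(x[hits[which.min(abs(x[hits] - x[i]))]] - x[i]) / 6
    for (cl in setdiff(unique(y), y[i])) {
      miss <- which(y == cl)
      d <- abs(x[miss[which.min(abs(x[miss] - x[i]))]] - x[i])
      w <- w + ((2 / 6) / (1 - 2 / 6)) * d / 6
    }
  }
  expect_equal(score_relieff(t3, k = 1)$score, w, tolerance = 1e-12)
  expect_error(score_relieff(t3, k = 3), "at least k members")
})

test_that("duplicated feature columns earn identical ReliefF weights", {
  pt <- toy_patients(15)
  dup <- pt_of(data.frame(sig = pt$sig, sig2 = pt$sig, noise = pt$noise,
                          severity = pt$severity))
  sc <- score_relieff(dup, k = 3)
  expect_equal(sc$score[sc$feature == "sig"], sc$score[sc$feature == "sig2"],
               tolerance = 1e-12)
})

test_that("scores are invariant to row order", {
  pt <- toy_patients(10)
  perm <- pt_of(as.data.frame(pt)[sample(nrow(pt)), ])
  for (f in list(score_chi2, score_infogain)) {
    expect_equal(f(perm)$score, f(pt)$score, tolerance = 1e-12)
  }
})

test_that("adding an independent feature leaves other scores unchanged", {
  pt <- toy_patients(10)
  set.seed(33)
  aug <- pt_of(data.frame(sig = pt$sig, noise = pt$noise,
                          extra = runif(nrow(pt)), severity = pt$severity))
  for (f in list(score_chi2, score_infogain)) {
    a <- f(pt); b <- f(aug)
    expect_equal(b$score[match(c("sig", "noise"), b$feature)],
                 a$score[match(c("sig", "noise"), a$feature)],
                 tolerance = 1e-12)
  }
})

test_that("selection rules are deterministic with name-order tie-breaks", {
  sc <- structure(data.frame(feature = c("a", "b", "c"),
                             score = c(2, 2, 0), rank = 1:3),
                  technique = "chi2",
                  class = c("feature_scores", "data.frame"))
  expect_equal(select_features(sc), c("a", "b"))
  expect_equal(select_features(sc, "top_k", k = 3), c("a", "b", "c"))
  expect_equal(select_features(sc, "top_k", k = 1), "a")
  expect_equal(select_features(sc, "threshold", threshold = 1), c("a", "b"))
  expect_error(select_features(sc, "threshold", threshold = 5),
               "kept no features")
  # ties at the cutoff resolved alphabetically by the scorer's ordering
  pt <- toy_patients(10)
  sc2 <- score_chi2(pt)
  expect_equal(sc2$rank, seq_len(nrow(sc2)))
})
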