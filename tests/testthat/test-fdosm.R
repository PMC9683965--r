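test_that("the ideal solution takes column extrema by direction", {
  dm <- example_decision_matrix()
  ideal <- ideal_solution(dm)
  expect_equal(ideal[["C1"]], 0.134)      # cheapest train time (naive Bayes)
  expect_equal(ideal[["C2"]], 0.00001)    # cheapest test time (decision tree)
  expect_equal(ideal[["C3"]], 0.99312)    # best AUC
  expect_equal(ideal[["C4"]], max(dm$C4))
  # critical value overrides the extremum
  ideal2 <- ideal_solution(dm, critical = c(C4 = 0.9))
  expect_equal(ideal2[["C4"]], 0.9)
  expect_equal(ideal2[["C1"]], 0.134)
  # single-alternative matrix is its own ideal
  one <- build_decision_matrix(as.data.frame(dm)[1, ], alternatives = "A1")
  expect_equal(unname(ideal_solution(one)),
               unname(unlist(dm[1, paste0("C", 1:7)])))
})

test_that("surrogate opinions bin normalized gaps into the five terms", {
  dm <- example_decision_matrix()
  op <- auto_opinions(dm)
  expect_equal(dim(op), c(15L, 7L))
  # the ideal cell itself is "No difference"; the worst is "Huge difference"
  expect_equal(unclass(op)["A3", "C1"], "No difference")
  expect_equal(unclass(op)["A12", "C1"], "Huge difference")
  # g = 0.2 with default edges lands in "Slight difference"
  rows <- data.frame(alternative = c("A1", "A2", "A3"), model = "m",
                     C1 = c(0, 0.2, 1), C2 = 0, C3 = 1, C4 = 1, C5 = 1,
                     C6 = 1, C7 = 1)
  dm3 <- build_decision_matrix(rows, alternatives = rows$alternative)
  op3 <- auto_opinions(dm3)
  expect_equal(unclass(op3)[, "C1"],
               c(A1 = "No difference", A2 = "Slight difference",
                 A3 = "Huge difference"))
  # constant columns judge as "No difference" everywhere
  expect_true(all(unclass(op3)[, "C2"] == "No difference"))
  expect_error(opinion_matrix(matrix("no idea", 1, 1)), "unknown term")
})

test_that("opinion scores are centroid means with exact bounds", {
  all_nd <- opinion_matrix(matrix("No difference", 2, 7,
                                  dimnames = list(c("A1", "A2"), NULL)))
  expect_equal(unname(score_alternatives(all_nd)), rep(0.4 / 3, 2),
               tolerance = 1e-12)
  all_hd <- opinion_matrix(matrix("Huge difference", 1, 7))
  expect_equal(unname(score_alternatives(all_hd)), 2.65 / 3,
               tolerance = 1e-12)
  # numeric codes are accepted in place of labels
  coded <- opinion_matrix(matrix(c("1", "3", "5"), 1))
  lab <- opinion_matrix(matrix(c("No difference", "Difference",
                                 "Huge difference"), 1))
  expect_equal(score_alternatives(coded), score_alternatives(lab))
})

test_that("scores are permutation invariant and strictly monotone", {
  terms <- scale_difference5()$terms$label
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(sample(terms, 21, TRUE), 3, 7,
                dimnames = list(paste0("A", 1:3), NULL))
    s <- score_alternatives(opinion_matrix(m))
    # criteria order never matters
    s2 <- score_alternatives(opinion_matrix(m[, sample(7)]))
    expect_equal(unname(s2), unname(s), tolerance = 1e-12)
    # one harsher opinion strictly raises that alternative's score
    ij <- c(sample(3, 1), sample(7, 1))
    cur <- match(m[ij[1], ij[2]], terms)
    if (cur < 5) {
      m2 <- m; m2[ij[1], ij[2]] <- terms[cur + 1]
      expect_gt(score_alternatives(opinion_matrix(m2))[ij[1]], s[ij[1]])
    }
  }
})

test_that("group aggregation equals flat averaging and handles ties", {
  terms <- scale_difference5()$terms$label
  set.seed(17)
  ops <- lapply(1:3, function(e) {
    opinion_matrix(matrix(sample(terms, 28, TRUE), 4, 7,
                          dimnames = list(paste0("A", 1:4), NULL)),
                   expert = paste0("E", e))
  })
  rr <- group_rank(ops)
  # group score = mean of per-expert scores = flat mean over experts x criteria
  for (i in 1:4) {
    flat <- unlist(lapply(ops, function(o) unclass(o)[i, ]))
    expect_equal(rr$score[i], defuzzify(tfn_mean(term_to_tfn(flat))),
                 tolerance = 1e-12)
  }
  expect_setequal(rr$rank, 1:4)
  # single expert: group equals individual; identical experts too
  one <- group_rank(ops[[1]])
  expect_equal(one$score, unname(score_alternatives(ops[[1]])))
  same <- group_rank(list(ops[[1]], ops[[1]]))
  expect_equal(same$score, one$score)
  # tied scores share a dense rank but keep ordinal ranks by index
  tied <- opinion_matrix(matrix("Slight difference", 2, 3,
                                dimnames = list(c("A1", "A2"), NULL)))
  tr <- group_rank(tied)
  expect_equal(tr$rank, c(1L, 2L))
  expect_equal(tr$dense_rank, c(1L, 1L))
  # shape mismatch across experts is rejected
  small <- opinion_matrix(matrix("Difference", 3, 7,
                                 dimnames = list(paste0("A", 1:3), NULL)))
  expect_error(group_rank(list(ops[[1]], small)), "shape")
})

test_that("uniformly less severe opinions rank strictly better", {
  mild <- matrix("Slight difference", 1, 7)
  harsh <- matrix("Big difference", 1, 7)
  m <- rbind(mild, harsh)
  rownames(m) <- c("A1", "A2")
  rr <- group_rank(opinion_matrix(m))
  expect_equal(rr$rank[rr$alternative == "A1"], 1L)
})

test_that("opinion matrices and rank reports round-trip through files", {
  dm <- example_decision_matrix()
  op <- auto_opinions(dm, expert = "E9")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(alternative = rownames(unclass(op)), unclass(op),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  op2 <- read_opinion_matrix(path, expert = "E9")
  expect_equal(unclass(op2), unclass(op), ignore_attr = TRUE)
  rr <- group_rank(op, models = setNames(dm$model, dm$alternative))
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_rank_report(rr, rpath)
  back <- read.csv(rpath)
  expect_equal(back$alternative, rr$alternative)
  expect_equal(back$score, rr$score, tolerance = 1e-9)
})
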