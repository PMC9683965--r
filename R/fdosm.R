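#' Fuzzy decision by opinion score method (FDOSM)
#'
#' FDOSM ranks the alternatives of a decision matrix in three blocks:
#' the transformation unit extracts a per-criterion ideal solution (column
#' minimum for cost criteria, maximum for benefit, or a configured critical
#' value) and asks experts to describe each cell's distance from the ideal
#' in a five-term linguistic vocabulary; the processing unit converts each
#' opinion to its TFN, averages per alternative, and centroid-defuzzifies;
#' group ranking averages the per-expert scores. Lower scores are better —
#' an alternative whose every cell is "No difference" from the ideal scores
#' the vocabulary's floor, 0.1333.
#'
#' @name fdosm
NULL

#' Extract the ideal solution from a decision matrix
#'
#' Per criterion: the column minimum for cost criteria, the maximum for
#' benefit criteria; a `critical` entry overrides either with a fixed
#' reference value (for criteria whose optimum is interior, e.g. blood
#' pressure).
#'
#' @param dm a `decision_matrix`.
#' @param critical optional named numeric vector of critical values, keyed
#'   by criterion id.
#' @return named numeric vector, one reference value per criterion.
#' @export
ideal_solution <- function(dm, critical = NULL) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (nrow(dm) == 0) stop("empty decision matrix", call. = FALSE)
  dirs <- dm_directions(dm)
  out <- vapply(names(dirs), function(cn) {
    if (!is.null(critical) && cn %in% names(critical)) {
      return(as.numeric(critical[[cn]]))
    }
    v <- dm[[cn]]
    if (dirs[[cn]] == "cost") min(v) else max(v)
  }, numeric(1))
  out
}

#' Automatic surrogate opinion matrix
#'
#' In the original method a human panel judges each cell's difference from
#' the ideal; this surrogate makes unattended pipelines possible. Each
#' cell's normalized gap `g = |v - ideal| / (column max - column min)` is
#' mapped through `bin_edges` to the five difference terms: g in
#' \[0, e1\] -> "No difference", (e1, e2\] -> "Slight difference", ...,
#' (e4, 1\] -> "Huge difference". A constant column has no gap to judge
#' and maps to "No difference" everywhere.
#'
#' @param dm a `decision_matrix`.
#' @param ideal the [ideal_solution()]; recomputed when omitted.
#' @param bin_edges four increasing cut points on \[0, 1\].
#' @param expert id recorded on the matrix.
#' @return an `opinion_matrix`: character matrix alternatives x criteria
#'   with attributes `expert` and `alternatives`.
#' @export
auto_opinions <- function(dm, ideal = ideal_solution(dm),
                          bin_edges = c(0.1, 0.3, 0.55, 0.8),
                          expert = "auto") {
  stopifnot(length(bin_edges) == 4, !is.unsorted(bin_edges))
  terms <- scale_difference5()$terms$label
  crit <- names(dm_directions(dm))
  m <- matrix(NA_character_, nrow(dm), length(crit),
              dimnames = list(dm$alternative, crit))
  for (cn in crit) {
    v <- dm[[cn]]
    rng <- diff(range(v))
    if (rng == 0) {
      m[, cn] <- terms[1]
    } else {
      g <- abs(v - ideal[[cn]]) / rng
      idx <- findInterval(pmin(g, 1), bin_edges, left.open = TRUE) + 1L
      m[, cn] <- terms[idx]
    }
  }
  opinion_matrix(m, expert = expert)
}

#' Construct / read an opinion matrix
#'
#' @param m character matrix (alternatives x criteria) of difference terms
#'   from the [scale_difference5()] vocabulary (case-insensitive; numeric
#'   codes 1-5 also accepted).
#' @param expert expert identifier.
#' @param scale the opinion vocabulary.
#' @return an `opinion_matrix`.
#' @export
opinion_matrix <- function(m, expert = "E1", scale = scale_difference5()) {
  m <- as.matrix(m)
  term_to_tfn(as.vector(m), scale)  # validates every cell
  structure(m, expert = expert, class = "opinion_matrix")
}

#' @rdname opinion_matrix
#' @param path comma-separated file: first column `alternative`, remaining
#'   columns one per criterion, cells linguistic terms.
#' @export
read_opinion_matrix <- function(path, expert = NULL,
                                scale = scale_difference5()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  alt <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- alt
  opinion_matrix(m, expert = expert %||% basename(path), scale = scale)
}

#' Score alternatives from one opinion matrix
#'
#' Each linguistic opinion becomes its TFN; per alternative the TFNs are
#' averaged componentwise over criteria and collapsed by centroid
#' defuzzification. By linearity of the centroid this equals the mean of
#' the individual term centroids.
#'
#' @param op an `opinion_matrix`.
#' @param scale the opinion vocabulary.
#' @return named numeric vector of scores (lower = closer to ideal).
#' @export
score_alternatives <- function(op, scale = scale_difference5()) {
  stopifnot(inherits(op, "opinion_matrix"))
  m <- unclass(op)
  vapply(seq_len(nrow(m)), function(i) {
    defuzzify(tfn_mean(term_to_tfn(m[i, ], scale)))
  }, numeric(1)) |> stats::setNames(rownames(m))
}

#' Group FDOSM ranking
#'
#' Scores each expert's opinion matrix independently, averages the scores
#' per alternative (external aggregation), and ranks ascending — rank 1 is
#' the alternative closest to the ideal. Ordinal ranks break score ties by
#' alternative order; dense ranks give tied alternatives the same rank.
#'
#' @param opinions a single `opinion_matrix` or a list of them (one per
#'   expert) with identical dimensions and alternative order.
#' @param scale the opinion vocabulary.
#' @param models optional named character vector of model labels keyed by
#'   alternative id.
#' @return a `rank_result` data.frame: alternative, model, score, rank,
#'   dense_rank, plus one score column per expert.
#' @export
group_rank <- function(opinions, scale = scale_difference5(),
                       models = NULL) {
  if (inherits(opinions, "opinion_matrix")) opinions <- list(opinions)
  stopifnot(length(opinions) >= 1)
  dims <- lapply(opinions, dim)
  alts <- rownames(unclass(opinions[[1]]))
  for (op in opinions) {
    if (!identical(dim(op), dims[[1]]) ||
        !identical(rownames(unclass(op)), alts)) {
      stop("expert opinion matrices differ in shape or alternative order",
           call. = FALSE)
    }
  }
  per_expert <- vapply(opinions, score_alternatives, numeric(length(alts)),
                       scale = scale)
  per_expert <- matrix(per_expert, nrow = length(alts),
                       dimnames = list(alts, vapply(opinions, function(o)
                         as.character(attr(o, "expert")), character(1))))
  score <- rowMeans(per_expert)
  ord <- order(score, seq_along(score))      # ties by alternative order
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  dense <- match(score, sort(unique(score)))
  out <- data.frame(alternative = alts,
                    model = if (is.null(models)) NA_character_
                            else unname(models[alts]),
                    score = score, rank = rank, dense_rank = dense,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(per_expert))
  rownames(out) <- NULL
  structure(out, class = c("rank_result", "data.frame"))
}

#' Write a rank report as delimited text
#'
#' Columns: alternative, model, score (9 decimals), rank, dense_rank.
#'
#' @param rr a `rank_result`.
#' @param path output file.
#' @export
write_rank_report <- function(rr, path) {
  df <- data.frame(alternative = rr$alternative, model = rr$model,
                   score = sprintf("%.9f", rr$score), rank = rr$rank,
                   dense_rank = rr$dense_rank)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
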