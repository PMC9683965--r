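#' Expert decision matrix
#'
#' An EDM records, for a panel of m experts and n criteria (here: patient
#' features), each expert's Likert importance rating of each criterion.
#' Every cell must be an integer code on the rating scale; FWZIC needs no
#' pairwise comparisons, which is what makes it inconsistency-free by
#' construction.
#'
#' @param ratings an m-by-n integer matrix (or data.frame) of Likert codes;
#'   column names are the criterion/feature names, row names the expert ids
#'   (defaults E1..Em).
#' @param scale the rating [linguistic_scale()].
#' @return an object of class `expert_decision_matrix`.
#' @export
expert_decision_matrix <- function(ratings, scale = scale_importance5()) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) storage.mode(m) <- "numeric"
  if (nrow(m) < 1 || ncol(m) < 1) {
    stop("EDM needs at least one expert and one criterion", call. = FALSE)
  }
  if (anyNA(m)) stop("EDM must have no missing ratings", call. = FALSE)
  if (any(m != round(m)) || !all(m %in% scale$terms$code)) {
    stop(sprintf("EDM ratings must be integer codes on scale '%s' (%s)",
                 scale$name,
                 paste(range(scale$terms$code), collapse = "-")),
         call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("E", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  structure(list(ratings = m, scale = scale),
            class = "expert_decision_matrix")
}

#' @export
print.expert_decision_matrix <- function(x, ...) {
  cat(sprintf("<expert_decision_matrix: %d experts x %d criteria, scale '%s'>\n",
              nrow(x$ratings), ncol(x$ratings), x$scale$name))
  print(x$ratings)
  invisible(x)
}

#' Read an expert-rating file
#'
#' One row per expert, one column per feature, integer Likert cells;
#' comma-separated with a header of feature names. An optional first column
#' named `expert` supplies expert ids.
#'
#' @param path file path.
#' @param scale the rating scale.
#' @return an [expert_decision_matrix()].
#' @export
read_expert_ratings <- function(path, scale = scale_importance5()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(df)[1]) == "expert") {
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
    rownames(df) <- ids
  }
  expert_decision_matrix(df, scale)
}

#' Fuzzify an expert decision matrix
#'
#' FWZIC's fuzzification: each rating becomes its scale TFN, and each cell
#' is divided (fuzzy quotient) by the fuzzy sum of that expert's TFNs over
#' all criteria, expressing the rating as the expert's relative share of
#' importance. The result is an m-by-n array of TFNs.
#'
#' @param edm an [expert_decision_matrix()].
#' @return a `fuzzy_edm`: an array of dim (experts, criteria, 3) with the
#'   TFN components in the third margin.
#' @export
fuzzify_edm <- function(edm) {
  stopifnot(inherits(edm, "expert_decision_matrix"))
  r <- edm$ratings
  out <- array(NA_real_, dim = c(nrow(r), ncol(r), 3),
               dimnames = list(rownames(r), colnames(r), c("a", "b", "c")))
  for (i in seq_len(nrow(r))) {
    cells <- likert_to_tfn(r[i, ], edm$scale)
    cm <- as_tfn_matrix(cells)
    rowsum <- tfn(sum(cm[, 1]), sum(cm[, 2]), sum(cm[, 3]))
    if (any(as_tfn_matrix(rowsum) <= 0)) {
      stop("expert row fuzzy sum has a non-positive component; ",
           "cannot fuzzify", call. = FALSE)
    }
    out[i, , ] <- as_tfn_matrix(tfn_combine(cells, rowsum, "divide"))
  }
  structure(out, class = "fuzzy_edm")
}

#' Aggregate a fuzzy EDM into per-criterion fuzzy weights
#'
#' The componentwise arithmetic mean over experts, giving one TFN weight
#' per criterion.
#'
#' @param fedm a `fuzzy_edm` from [fuzzify_edm()].
#' @return a `tfn` vector, one row per criterion, named by criterion.
#' @export
aggregate_fuzzy_weights <- function(fedm) {
  stopifnot(inherits(fedm, "fuzzy_edm"))
  m <- apply(unclass(fedm), c(2, 3), mean)
  out <- tfn(m[, "a"], m[, "b"], m[, "c"])
  attr(out, "criteria") <- dimnames(fedm)[[2]]
  out
}

#' Defuzzify and rescale fuzzy weights to a unit-sum weight set
#'
#' Each per-criterion TFN is collapsed by centroid defuzzification and the
#' crisp values are rescaled by their total, so the final weights sum to 1
#' for any panel.
#'
#' @param fuzzy_weights per-criterion TFNs from [aggregate_fuzzy_weights()].
#' @param technique optional provenance tag (e.g. the feature-selection
#'   method whose surviving features these are).
#' @return a `feature_weights` object: a named numeric vector summing to 1,
#'   with attribute `technique`.
#' @export
finalize_weights <- function(fuzzy_weights, technique = NA_character_) {
  crisp <- defuzzify(fuzzy_weights)
  names(crisp) <- attr(fuzzy_weights, "criteria")
  tot <- sum(crisp)
  if (tot <= 0) stop("defuzzified weights sum to zero", call. = FALSE)
  structure(crisp / tot, technique = technique, class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights: %d features, technique %s>\n", length(x),
              attr(x, "technique")))
  print(round(unclass(x), 6))
  invisible(x)
}

#' Fuzzy-weighted zero-inconsistency (FWZIC) criterion weighting
#'
#' Turns a panel of independent expert Likert importance ratings into
#' normalized per-criterion weights in five steps: (1-3) assemble the
#' expert decision matrix, (4) fuzzify each rating against the expert's own
#' rating total and average over experts, (5) centroid-defuzzify and
#' rescale to unit sum. Because experts rate criteria directly rather than
#' by pairwise comparison, no consistency ratio exists to violate.
#'
#' @param edm an [expert_decision_matrix()], or a plain matrix/data.frame of
#'   integer ratings.
#' @param technique optional provenance tag carried on the result.
#' @return a `feature_weights` vector summing to 1.
#' @examples
#' edm <- expert_decision_matrix(rbind(c(5, 3, 1), c(4, 4, 2)))
#' fwzic(edm)
#' @export
fwzic <- function(edm, technique = NA_character_) {
  if (!inherits(edm, "expert_decision_matrix")) {
    edm <- expert_decision_matrix(edm)
  }
  finalize_weights(aggregate_fuzzy_weights(fuzzify_edm(edm)), technique)
}

#' Write / read a feature-weight set
#'
#' Two-column comma-separated text (`feature,weight`); the provenance tag is
#' kept in a sidecar `<path>.meta` key-value file.
#'
#' @param w a `feature_weights` object.
#' @param path output file path.
#' @return `write_feature_weights` returns `path` invisibly;
#'   `read_feature_weights` returns a `feature_weights` object.
#' @export
write_feature_weights <- function(w, path) {
  stopifnot(inherits(w, "feature_weights"))
  utils::write.csv(data.frame(feature = names(w), weight = as.numeric(w)),
                   path, row.names = FALSE, quote = TRUE)
  writeLines(sprintf("technique: %s", attr(w, "technique")),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_feature_weights
#' @export
read_feature_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tech <- NA_character_
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    tech <- sub("^technique:\\s*", "", readLines(meta)[1])
  }
  structure(stats::setNames(df$weight, df$feature), technique = tech,
            class = "feature_weights")
}
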