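#' Linguistic scales
#'
#' A linguistic scale binds an ordered set of terms to numeric codes and
#' TFNs. Two five-term scales are built in:
#' \describe{
#'   \item{`importance5`}{the Likert importance vocabulary used when experts
#'     rate features (Not important ... Very important, codes 1-5).}
#'   \item{`difference5`}{the FDOSM opinion vocabulary describing how far a
#'     decision-matrix cell sits from the ideal solution (No difference ...
#'     Huge difference, codes 1-5).}
#' }
#' Both scales share the same TFN supports on \[0, 1\]; only the labels
#' differ. Additional scales can be loaded from a file with
#' [read_scale_registry()].
#'
#' @param name scale identifier.
#' @param terms a data.frame with columns `label`, `code`, `a`, `b`, `c`,
#'   one row per term, ordered by code.
#' @return an object of class `linguistic_scale`.
#' @export
linguistic_scale <- function(name, terms) {
  req <- c("label", "code", "a", "b", "c")
  if (!all(req %in% names(terms))) {
    stop("scale terms need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  terms <- terms[order(terms$code), req]
  terms$label <- as.character(terms$label)
  terms$code <- as.integer(terms$code)
  if (anyDuplicated(terms$code) || anyDuplicated(tolower(terms$label))) {
    stop("scale codes and labels must be unique", call. = FALSE)
  }
  tf <- tfn(terms$a, terms$b, terms$c)  # validates each triple
  if (any(diff(as_tfn_matrix(tf)[, "b"]) <= 0)) {
    stop("scale TFN modes must strictly increase with code", call. = FALSE)
  }
  structure(list(name = name, terms = terms), class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat(sprintf("<linguistic_scale '%s'>\n", x$name))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

.scale5 <- function(name, labels) {
  linguistic_scale(name, data.frame(
    label = labels,
    code = 1:5,
    a = c(0.00, 0.10, 0.30, 0.50, 0.75),
    b = c(0.10, 0.30, 0.50, 0.75, 0.90),
    c = c(0.30, 0.50, 0.75, 0.90, 1.00)))
}

#' @rdname linguistic_scale
#' @export
scale_importance5 <- function() {
  .scale5("importance5", c("Not important", "Slight important",
                           "Moderately important", "Important",
                           "Very important"))
}

#' @rdname linguistic_scale
#' @export
scale_difference5 <- function() {
  .scale5("difference5", c("No difference", "Slight difference", "Difference",
                           "Big difference", "Huge difference"))
}

#' Convert Likert levels to TFNs
#'
#' Looks up the TFN bound to each integer code of a linguistic scale.
#'
#' @param level integer vector of codes on the scale (1-5 for the built-in
#'   scales).
#' @param scale a [linguistic_scale()]; default the importance scale.
#' @return a `tfn` vector, one row per level.
#' @examples
#' likert_to_tfn(5)  # (0.75, 0.90, 1.00)
#' @export
likert_to_tfn <- function(level, scale = scale_importance5()) {
  stopifnot(inherits(scale, "linguistic_scale"))
  lv <- suppressWarnings(as.numeric(level))
  if (any(is.na(lv)) || any(lv != round(lv))) {
    stop("Likert levels must be integers", call. = FALSE)
  }
  idx <- match(as.integer(lv), scale$terms$code)
  if (anyNA(idx)) {
    bad <- lv[is.na(idx)][1]
    stop(sprintf("level %g is not on scale '%s' (codes %s)", bad, scale$name,
                 paste(range(scale$terms$code), collapse = "-")),
         call. = FALSE)
  }
  t <- scale$terms[idx, , drop = FALSE]
  tfn(t$a, t$b, t$c)
}

#' Map linguistic labels (or codes) to TFNs
#'
#' Case-insensitive label lookup; numeric strings are accepted as codes.
#'
#' @param label character vector of term labels or codes.
#' @param scale a [linguistic_scale()].
#' @return a `tfn` vector.
#' @export
term_to_tfn <- function(label, scale = scale_difference5()) {
  stopifnot(inherits(scale, "linguistic_scale"))
  lab <- trimws(as.character(label))
  idx <- match(tolower(lab), tolower(scale$terms$label))
  num <- suppressWarnings(as.integer(lab))
  idx[is.na(idx)] <- match(num[is.na(idx)], scale$terms$code)
  if (anyNA(idx)) {
    stop(sprintf("unknown term '%s' on scale '%s'", lab[is.na(idx)][1],
                 scale$name), call. = FALSE)
  }
  t <- scale$terms[idx, , drop = FALSE]
  tfn(t$a, t$b, t$c)
}

#' Load a registry of linguistic scales from a file
#'
#' The file is comma-separated with header `scale,label,code,a,b,c`; each
#' distinct `scale` value becomes one [linguistic_scale()].
#'
#' @param path file path.
#' @return a named list of `linguistic_scale` objects.
#' @export
read_scale_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("scale", "label", "code", "a", "b", "c")
  if (!all(req %in% names(df))) {
    stop("scale registry needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$scale), function(d) {
    linguistic_scale(d$scale[1], d[, c("label", "code", "a", "b", "c")])
  })
  out[unique(df$scale)]
}
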