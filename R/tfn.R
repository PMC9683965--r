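#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is a fuzzy set on the real line whose
#' membership function rises linearly from the lower support `a` to 1 at the
#' mode `b`, then falls linearly to 0 at the upper support `c`, with
#' `a <= b <= c`. TFNs are the atom of both the FWZIC weighting method and
#' the FDOSM ranking method: linguistic Likert/opinion terms are mapped to
#' TFNs, combined with fuzzy arithmetic, and finally collapsed to a crisp
#' value by centroid defuzzification.
#'
#' `tfn()` builds a vector of TFNs, stored as an n-by-3 numeric matrix with
#' columns `a`, `b`, `c`. All arguments are recycled to a common length.
#' The library is restricted to non-negative TFNs: every linguistic scale it
#' works with lives in \[0, 1\], and the extension-principle product and
#' quotient rules used here only preserve `a <= b <= c` for non-negative
#' operands.
#'
#' @param a,b,c numeric vectors: lower support, mode, upper support.
#' @return an object of class `tfn`: an n-by-3 matrix, one TFN per row.
#' @examples
#' x <- tfn(0, 0.1, 0.3)
#' defuzzify(x)
#' @export
tfn <- function(a, b, c) {
  m <- cbind(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
  if (any(!is.finite(m))) {
    stop("TFN components must be finite", call. = FALSE)
  }
  if (any(m[, "a"] < 0)) {
    stop("TFN lower support must be non-negative ",
         "(this library is restricted to non-negative TFNs)", call. = FALSE)
  }
  tol <- 1e-9
  bad <- m[, "a"] > m[, "b"] + tol | m[, "b"] > m[, "c"] + tol
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("TFN must satisfy a <= b <= c; got (%g, %g, %g)",
                 m[i, 1], m[i, 2], m[i, 3]), call. = FALSE)
  }
  structure(m, class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("<tfn[%d]>\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
`[.tfn` <- function(x, i, ...) {
  tfn_from_matrix(unclass(x)[i, , drop = FALSE])
}

#' @export
length.tfn <- function(x) nrow(unclass(x))

is_tfn <- function(x) inherits(x, "tfn")

tfn_from_matrix <- function(m) tfn(m[, 1], m[, 2], m[, 3])

as_tfn_matrix <- function(x) {
  if (!is_tfn(x)) stop("expected a 'tfn' object", call. = FALSE)
  unclass(x)
}

recycle2 <- function(x, y) {
  n <- max(nrow(x), nrow(y))
  list(x = x[rep_len(seq_len(nrow(x)), n), , drop = FALSE],
       y = y[rep_len(seq_len(nrow(y)), n), , drop = FALSE])
}

#' Fuzzy arithmetic on triangular fuzzy numbers
#'
#' Extension-principle arithmetic for non-negative TFNs, componentwise on
#' the (a, b, c) triples:
#' \itemize{
#'   \item addition: `(a1 + a2, b1 + b2, c1 + c2)`
#'   \item subtraction: `(a1 - c2, b1 - b2, c1 - a2)`
#'   \item scalar multiple by `alpha >= 0`: `(alpha a, alpha b, alpha c)`
#'   \item inverse: `(1/c, 1/b, 1/a)` (all components must be > 0)
#'   \item product: `(a1 a2, b1 b2, c1 c2)`
#'   \item quotient: `(a1/c2, b1/b2, c1/a2)` (divisor components must be > 0)
#' }
#' The product and quotient rules are the usual first-order approximations;
#' they are exact at the mode and at the support endpoints for non-negative
#' operands. Subtraction may produce a negative lower support, which falls
#' outside this library's non-negative domain and raises an error.
#'
#' @param x,y `tfn` vectors (recycled to a common length).
#' @param op one of `"add"`, `"subtract"`, `"multiply"`, `"divide"`.
#' @return a `tfn` vector.
#' @examples
#' tfn_combine(tfn(0, 0.1, 0.3), tfn(0.1, 0.3, 0.5), "add")
#' @export
tfn_combine <- function(x, y, op = c("add", "subtract", "multiply", "divide")) {
  op <- match.arg(op)
  p <- recycle2(as_tfn_matrix(x), as_tfn_matrix(y))
  x <- p$x; y <- p$y
  if (op == "divide" && any(y <= 0)) {
    stop("fuzzy division requires all divisor components > 0", call. = FALSE)
  }
  m <- switch(op,
    add      = x + y,
    subtract = cbind(x[, 1] - y[, 3], x[, 2] - y[, 2], x[, 3] - y[, 1]),
    multiply = x * y,
    divide   = cbind(x[, 1] / y[, 3], x[, 2] / y[, 2], x[, 3] / y[, 1]))
  tfn(m[, 1], m[, 2], m[, 3])
}

#' @rdname tfn_combine
#' @param alpha a non-negative scalar.
#' @export
tfn_scale <- function(alpha, x) {
  stopifnot(length(alpha) == 1, is.finite(alpha))
  if (alpha < 0) stop("scalar multiplier must be non-negative", call. = FALSE)
  m <- alpha * as_tfn_matrix(x)
  tfn(m[, 1], m[, 2], m[, 3])
}

#' @rdname tfn_combine
#' @export
tfn_inverse <- function(x) {
  m <- as_tfn_matrix(x)
  if (any(m <= 0)) {
    stop("fuzzy inverse requires all components > 0", call. = FALSE)
  }
  tfn(1 / m[, 3], 1 / m[, 2], 1 / m[, 1])
}

#' @export
Ops.tfn <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/")) {
    if (is.numeric(e1) && .Generic == "*") return(tfn_scale(e1, e2))
    if (is.numeric(e2) && .Generic == "*") return(tfn_scale(e2, e1))
    op <- c("+" = "add", "-" = "subtract", "*" = "multiply", "/" = "divide")
    return(tfn_combine(e1, e2, op[[.Generic]]))
  }
  stop(sprintf("operator '%s' is not defined for TFNs", .Generic),
       call. = FALSE)
}

#' Componentwise mean of a TFN vector
#'
#' The arithmetic mean of n TFNs, taken separately on each of the three
#' components; this is the aggregation operator used by both FWZIC (over
#' experts) and FDOSM (over criteria and experts).
#'
#' @param x a `tfn` vector.
#' @return a single `tfn`.
#' @export
tfn_mean <- function(x) {
  m <- as_tfn_matrix(x)
  tfn(mean(m[, 1]), mean(m[, 2]), mean(m[, 3]))
}

#' Triangular membership degree
#'
#' Degree to which a crisp value `x` belongs to the fuzzy set described by a
#' TFN: 0 outside `[a, c]`, rising linearly on `[a, b]`, falling on
#' `[b, c]`, exactly 1 at the mode. Degenerate edges (`b == a` or
#' `b == c`) are treated as steps, so membership at the mode stays 1 — the
#' continuity limit of shrinking the edge.
#'
#' @param x numeric vector of crisp values.
#' @param t a single `tfn`.
#' @return membership degrees in \[0, 1\], one per element of `x`.
#' @export
membership_degree <- function(x, t) {
  m <- as_tfn_matrix(t)
  if (nrow(m) != 1) stop("'t' must be a single TFN", call. = FALSE)
  a <- unname(m[1, 1]); b <- unname(m[1, 2]); cc <- unname(m[1, 3])
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (cc > b) (cc - x) / (cc - b) else as.numeric(x <= b)
  out <- ifelse(x < a | x > cc, 0, pmin(up, dn))
  pmin(pmax(out, 0), 1)
}

#' Centroid defuzzification
#'
#' Collapses each TFN to the crisp value `(a + b + c) / 3`, the centroid of
#' the triangle. This is linear in the TFN components, so the mean of
#' defuzzified values equals the defuzzified componentwise mean — the
#' identity FDOSM's aggregation relies on.
#'
#' @param x a `tfn` vector.
#' @return a numeric vector of crisp values, each within its TFN's support.
#' @export
defuzzify <- function(x) {
  m <- as_tfn_matrix(x)
  unname(rowMeans(m))
}
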