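#' Phase 1 preprocessing
#'
#' The preprocessing pipeline takes a raw delimited patient table — mixed
#' categorical and numeric features plus a 3-level `severity` class — and
#' produces a complete, normalized, class-balanced numeric table ready for
#' feature scoring and model training. The fixed order is clean/encode,
#' mean imputation, min-max normalization, then SMOTE balancing: SMOTE's
#' nearest-neighbour distances require complete data on a common scale.
#'
#' @name data_prep
NULL

.sentinels <- c("?", "/", "-", "")

#' Clean a raw patient table and encode categoricals
#'
#' Whole-cell sentinel symbols (`?`, `/`, `-`, empty) become missing.
#' Columns whose remaining values all parse as numbers stay numeric; other
#' columns are treated as categorical and mapped to integer codes 0, 1, ...
#' in alphabetical order of their observed levels, recorded in a codebook so
#' the encoding is deterministic and invertible. The class column is encoded
#' light = 0, medium = 1, intense = 2.
#'
#' @param raw a data.frame as read from the delimited input (character or
#'   mixed columns).
#' @param class_col name of the class column (default `"severity"`).
#' @return a `patient_table`: a numeric data.frame with attributes
#'   `codebook` (named list of level vectors, code = position - 1) and
#'   `class_col`.
#' @export
clean_and_encode <- function(raw, class_col = "severity") {
  if (!class_col %in% names(raw)) {
    stop(sprintf("class column '%s' not found in table", class_col),
         call. = FALSE)
  }
  class_levels <- c("light", "medium", "intense")  # codes 0, 1, 2
  out <- raw
  codebook <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) {
      v <- trimws(v)
      v[v %in% .sentinels] <- NA_character_
    }
    if (nm == class_col) {
      lab <- tolower(as.character(v))
      if (anyNA(lab)) stop("class column has missing labels", call. = FALSE)
      code <- match(lab, class_levels) - 1L
      if (anyNA(code)) {
        stop(sprintf("unknown class label '%s' (expected %s)",
                     lab[is.na(code)][1],
                     paste(class_levels, collapse = "/")), call. = FALSE)
      }
      out[[nm]] <- code
      codebook[[nm]] <- class_levels
      next
    }
    if (is.numeric(v)) {
      out[[nm]] <- as.numeric(v)
      next
    }
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) {      # fully numeric after cleaning
      out[[nm]] <- num
    } else {                                # categorical: alphabetical codes
      lev <- sort(unique(v[!is.na(v)]))
      codebook[[nm]] <- lev
      out[[nm]] <- as.numeric(match(v, lev) - 1L)
    }
  }
  structure(out, codebook = codebook, class_col = class_col,
            class = c("patient_table", "data.frame"))
}

pt_class_col <- function(t) {
  cc <- attr(t, "class_col")
  if (is.null(cc)) "severity" else cc
}

pt_features <- function(t) setdiff(names(t), pt_class_col(t))

rebuild_pt <- function(df, template) {
  structure(df, codebook = attr(template, "codebook"),
            class_col = pt_class_col(template),
            class = c("patient_table", "data.frame"))
}

#' Mean imputation of missing cells
#'
#' Every missing cell (numeric and encoded-categorical alike) is replaced
#' by the arithmetic mean of the observed values in its column, leaving the
#' observed values — and hence the column mean — untouched.
#'
#' @param t a `patient_table` from [clean_and_encode()].
#' @return the table with no missing cells.
#' @export
impute_mean <- function(t) {
  for (nm in pt_features(t)) {
    v <- t[[nm]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0) {
        stop(sprintf("column '%s' is fully missing; cannot impute", nm),
             call. = FALSE)
      }
      v[is.na(v)] <- mean(obs)
      t[[nm]] <- v
    }
  }
  if (anyNA(t[[pt_class_col(t)]])) {
    stop("class column has missing values", call. = FALSE)
  }
  rebuild_pt(t, t)
}

#' Min-max normalization
#'
#' Rescales each feature column to `(x - min) / (max - min)` on \[0, 1\];
#' constant columns map to 0 and the class column is untouched.
#'
#' @param t a complete `patient_table`.
#' @return the normalized table.
#' @export
minmax_normalize <- function(t) {
  if (anyNA(t)) stop("normalize requires a complete table; impute first",
                     call. = FALSE)
  for (nm in pt_features(t)) {
    v <- t[[nm]]
    rng <- range(v)
    t[[nm]] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
               else rep(0, length(v))
  }
  rebuild_pt(t, t)
}

#' SMOTE class balancing
#'
#' Upsamples every minority class to the majority-class count by the
#' synthetic minority oversampling technique: each synthetic row is a
#' convex combination `x + u (nn - x)`, `u ~ Uniform(0, 1)`, of a randomly
#' chosen minority row `x` and one of its `k` nearest same-class neighbours
#' (Euclidean distance over the feature columns). Original rows are
#' preserved and synthetic rows are appended, so every synthetic value lies
#' inside the componentwise range of its class.
#'
#' @param t a complete, normalized `patient_table`.
#' @param k number of nearest neighbours (default 5).
#' @param seed integer seed making the interpolation reproducible.
#' @return the balanced table.
#' @export
smote_balance <- function(t, k = 5, seed = 1L) {
  if (anyNA(t)) stop("SMOTE requires a complete table", call. = FALSE)
  cls <- t[[pt_class_col(t)]]
  counts <- table(cls)
  target <- max(counts)
  feats <- pt_features(t)
  if (all(counts == target)) return(t)
  rng <- local_rng(seed)
  synth <- list()
  for (lev in names(counts)[counts < target]) {
    idx <- which(cls == as.numeric(lev))
    if (length(idx) < 2) {
      stop(sprintf("class %s has fewer than 2 rows; no neighbour available",
                   lev), call. = FALSE)
    }
    kk <- min(k, length(idx) - 1)
    x <- as.matrix(t[idx, feats, drop = FALSE])
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(kk)])
    nnidx <- if (kk == 1) matrix(nn, ncol = 1) else t(nn)
    need <- target - length(idx)
    base <- rng$sample_int(length(idx), need, replace = TRUE)
    pick <- rng$sample_int(kk, need, replace = TRUE)
    u <- rng$runif(need)
    newx <- x[base, , drop = FALSE] +
      u * (x[cbind(nnidx[cbind(base, pick)]), , drop = FALSE] -
             x[base, , drop = FALSE])
    df <- as.data.frame(newx)
    names(df) <- feats
    df[[pt_class_col(t)]] <- as.numeric(lev)
    synth[[lev]] <- df[names(t)]
  }
  out <- rbind(as.data.frame(t), do.call(rbind, synth))
  rownames(out) <- NULL
  rebuild_pt(out, t)
}

#' Run the full Phase 1 pipeline
#'
#' clean/encode, impute, normalize, SMOTE — in that order.
#'
#' @param raw raw data.frame.
#' @param class_col class column name.
#' @param k SMOTE neighbour count.
#' @param seed SMOTE seed.
#' @return a balanced, normalized `patient_table`.
#' @export
prepare_patients <- function(raw, class_col = "severity", k = 5, seed = 1L) {
  smote_balance(minmax_normalize(impute_mean(
    clean_and_encode(raw, class_col))), k = k, seed = seed)
}

#' Persist / restore the categorical codebook
#'
#' Key-value text: `column<TAB>code<TAB>level`, one line per level.
#'
#' @param t a `patient_table`.
#' @param path output file.
#' @export
write_codebook <- function(t, path) {
  cb <- attr(t, "codebook")
  lines <- unlist(lapply(names(cb), function(nm) {
    sprintf("%s\t%d\t%s", nm, seq_along(cb[[nm]]) - 1L, cb[[nm]])
  }))
  writeLines(lines, path)
  invisible(path)
}
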