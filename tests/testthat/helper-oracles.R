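# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's TFN class and vectorized paths:
# every fuzzy operation is expanded on plain scalars.

# Likert code -> (a, b, c) triple of the five-term scale.
oracle_scale <- list(c(0.00, 0.10, 0.30), c(0.10, 0.30, 0.50),
                     c(0.30, 0.50, 0.75), c(0.50, 0.75, 0.90),
                     c(0.75, 0.90, 1.00))

# Brute-force FWZIC on a plain integer matrix, scalar by scalar.
oracle_fwzic <- function(ratings) {
  m <- nrow(ratings); n <- ncol(ratings)
  cells <- array(NA_real_, c(m, n, 3))
  for (i in seq_len(m)) {
    sa <- sb <- sc <- 0
    for (j in seq_len(n)) {
      t <- oracle_scale[[ratings[i, j]]]
      sa <- sa + t[1]; sb <- sb + t[2]; sc <- sc + t[3]
    }
    for (j in seq_len(n)) {
      t <- oracle_scale[[ratings[i, j]]]
      cells[i, j, ] <- c(t[1] / sc, t[2] / sb, t[3] / sa)
    }
  }
  crisp <- numeric(n)
  for (j in seq_len(n)) {
    wa <- mean(cells[, j, 1]); wb <- mean(cells[, j, 2])
    wc <- mean(cells[, j, 3])
    crisp[j] <- (wa + wb + wc) / 3
  }
  crisp / sum(crisp)
}

# Entropy in bits from a label vector, by direct enumeration.
oracle_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Random EDM whose every row contains at least one rating above 1: a row of
# all-minimum ratings has a fuzzy sum with zero lower support, which the
# fuzzification guard rejects by design.
rand_edm <- function(m, n) {
  repeat {
    r <- matrix(sample(1:5, m * n, replace = TRUE), m, n)
    if (all(apply(r, 1, max) > 1)) return(r)
  }
}

# A tiny raw clinical table with sentinels, categoricals and numerics.
tiny_raw <- function() {
  data.frame(
    sex = c("male", "female", "female", "male", "female", "male"),
    marker = c("1.5", "?", "3.5", "2.0", "-", "4.0"),
    mood = c("bad", "good", "good", "bad", "good", "bad"),
    age = c(20, 30, 40, 25, 35, 45),
    severity = c("light", "medium", "intense", "light", "medium", "intense"),
    stringsAsFactors = FALSE)
}

# A balanced, normalized numeric patient table with a planted signal:
# feature `sig` separates the classes, `noise` does not.
toy_patients <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  cls <- rep(0:2, each = n_per_class)
  sig <- (cls / 2) * 0.8 + runif(length(cls), 0, 0.2)
  noise <- runif(length(cls))
  structure(data.frame(sig = sig, noise = noise, severity = cls),
            class_col = "severity",
            class = c("patient_table", "data.frame"))
}

# Small deterministic EDM builder.
toy_edm <- function(ratings) {
  expert_decision_matrix(ratings)
}
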