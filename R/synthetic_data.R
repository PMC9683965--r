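#' Synthetic ASD-severity study data
#'
#' The study this framework emulates collected 48 mixed
#' categorical/numeric clinical and sociodemographic features for 538
#' patients with a 3-level autism severity label (241 light / 259 medium /
#' 38 intense) and missing values in several medical-test columns; the
#' original records are not public. This generator reproduces the schema,
#' shape, value ranges and missingness of that table, with a configurable
#' planted class signal, so every stage of the framework is testable.
#'
#' @name synthetic_data
NULL

.yn <- c("no", "yes")
.blood <- c("A-", "A+", "B-", "B+", "O-", "O+", "AB-", "AB+")

#' Default 48-feature schema
#'
#' One row per feature: `feature` (column name), `kind`
#' (`"categorical"` / `"numeric"`), `categories` (comma-joined levels, "" for
#' numeric), `min`, `max` (numeric ranges, NA for categorical), and
#' `missing_rate` (sentinel-injection probability; non-zero by default for
#' the medical-test columns that carry missing values in the emulated
#' study).
#'
#' @return a data.frame with 48 rows.
#' @export
default_schema <- function() {
  cat_f <- function(feature, categories, missing_rate = 0) {
    data.frame(feature = feature, kind = "categorical",
               categories = paste(categories, collapse = ","),
               min = NA_real_, max = NA_real_, missing_rate = missing_rate,
               stringsAsFactors = FALSE)
  }
  num_f <- function(feature, min, max, missing_rate = 0) {
    data.frame(feature = feature, kind = "numeric", categories = "",
               min = min, max = max, missing_rate = missing_rate,
               stringsAsFactors = FALSE)
  }
  rbind(
    cat_f("sex", c("male", "female")),
    cat_f("blood_type_patient", .blood),
    cat_f("blood_type_mother", .blood, 0.05),
    cat_f("blood_type_father", .blood, 0.05),
    cat_f("relative_relation", .yn),
    cat_f("toxoplasmosis", .yn, 0.05),
    cat_f("unnatural_medicines_mother", .yn),
    cat_f("folic_acid_mother", .yn),
    cat_f("birth_complications_mother", .yn),
    cat_f("premature_baby", .yn),
    cat_f("jaundice", .yn),
    cat_f("smell_the_food", .yn),
    cat_f("taste_the_food", .yn),
    cat_f("afraid_of_loud_sounds", .yn),
    num_f("degree", 85, 609, 0.05),
    cat_f("crying_for_no_reason", .yn),
    cat_f("kisses_with_a_sound", .yn),
    cat_f("escaping_home_open_doors", .yn),
    cat_f("notice_sound_of_bell", .yn),
    cat_f("diapers", .yn),
    cat_f("bathroom_skills", .yn),
    cat_f("responds_when_called", .yn),
    cat_f("mind_wandering", .yn),
    num_f("vitamin_d3", 2.90, 102.1, 0.05),
    num_f("vitamin_b12", 0.01, 2050, 0.05),
    num_f("vitamin_zinc", 0.9, 292, 0.05),
    cat_f("marital_relationship_parents",
          c("not good", "yes", "separate", "dead")),
    cat_f("blood_match", .yn, 0.05),
    cat_f("maternal_diseases_pregnancy", .yn),
    cat_f("birth_complications_child", .yn),
    cat_f("chewing_food", .yn),
    cat_f("annoyed_by_clothing_tag", .yn),
    cat_f("waves", .yn),
    cat_f("patient_moving_at_home", .yn),
    cat_f("patient_moves_around_itself", .yn),
    cat_f("carry_out_orders", .yn),
    cat_f("laughing_for_no_reason", .yn),
    cat_f("play_with_children", .yn),
    cat_f("is_there_language_now", .yn),
    cat_f("pointing_with_index_finger", .yn),
    cat_f("notice_his_name", .yn),
    cat_f("arrange_things_in_one_row", .yn),
    cat_f("nodded", c("previously", "no", "yes")),
    num_f("parent_age_difference", 1, 28),
    num_f("premature_duration", 0, 39, 0.05),
    cat_f("plays_with_circle_things", c("previously", "no", "yes")),
    num_f("father_age", 22, 83),
    num_f("mother_age", 16, 79))
}

#' Default generator configuration
#'
#' 538 rows with class counts light 241 / medium 259 / intense 38, the
#' [default_schema()], and a planted signal on ten behavioural/medical
#' features: informative categorical features have class-dependent level
#' probabilities, informative numeric features class-shifted means; the
#' remaining features are class-independent noise. `effect` in \[0, 1\]
#' scales the separation (0 = no signal).
#'
#' @param n_rows total rows.
#' @param class_counts named counts over light/medium/intense.
#' @param schema a [default_schema()]-shaped data.frame.
#' @param informative features carrying the planted signal.
#' @param effect effect size in \[0, 1\].
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_rows = 538,
                             class_counts = c(light = 241, medium = 259,
                                              intense = 38),
                             schema = default_schema(),
                             informative = c(
                               "carry_out_orders", "laughing_for_no_reason",
                               "mind_wandering", "play_with_children",
                               "is_there_language_now",
                               "pointing_with_index_finger",
                               "notice_his_name", "bathroom_skills",
                               "degree", "vitamin_d3"),
                             effect = 0.8, seed = 1L) {
  if (sum(class_counts) != n_rows) {
    stop("class counts must sum to n_rows", call. = FALSE)
  }
  if (!all(c("light", "medium", "intense") %in% names(class_counts))) {
    stop("class_counts must name light, medium and intense", call. = FALSE)
  }
  bad <- setdiff(informative, schema$feature)
  if (length(bad) > 0) {
    stop("informative feature(s) not in schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_rows = n_rows, class_counts = class_counts,
                 schema = schema, informative = informative,
                 effect = effect, seed = seed),
            class = "generator_config")
}

#' Generate a raw synthetic patient table
#'
#' Emits the raw-input format of the preprocessing contract: character
#' cells with categorical labels, formatted numerics, sentinel symbols
#' (`?` / `-`) at each feature's configured missing rate, and a `severity`
#' column of light/medium/intense labels with exactly the configured
#' counts. Byte-identical output under a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @return a data.frame of character columns (features + `severity`).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  rng <- local_rng(cfg$seed)
  cls <- rep(c("light", "medium", "intense"),
             times = cfg$class_counts[c("light", "medium", "intense")])
  n <- cfg$n_rows
  # class-conditional position on the feature's own scale, pulled towards
  # the midpoint as effect -> 0
  pos <- c(light = 0.2, medium = 0.5, intense = 0.8)
  pos <- 0.5 + cfg$effect * (pos - 0.5)
  out <- list()
  for (i in seq_len(nrow(cfg$schema))) {
    s <- cfg$schema[i, ]
    informative <- s$feature %in% cfg$informative
    if (s$kind == "categorical") {
      levs <- strsplit(s$categories, ",")[[1]]
      v <- character(n)
      if (informative) {
        for (lab in names(pos)) {
          sel <- cls == lab
          # ramp category probabilities along the level order
          p <- stats::dbeta(seq(0.05, 0.95, length.out = length(levs)),
                            1 + 4 * pos[[lab]], 1 + 4 * (1 - pos[[lab]]))
          p <- p / sum(p)
          v[sel] <- levs[rng$sample_int(length(levs), sum(sel),
                                        replace = TRUE, prob = p)]
        }
      } else {
        v <- levs[rng$sample_int(length(levs), n, replace = TRUE)]
      }
    } else {
      mid <- (s$min + s$max) / 2
      sd <- (s$max - s$min) / 6
      v <- numeric(n)
      if (informative) {
        for (lab in names(pos)) {
          sel <- cls == lab
          mu <- s$min + pos[[lab]] * (s$max - s$min)
          v[sel] <- rng$rnorm(sum(sel), mu, sd)
        }
      } else {
        v <- rng$rnorm(n, mid, sd)
      }
      v <- pmin(pmax(v, s$min), s$max)    # truncate to the declared range
      v <- format(round(v, 3), trim = TRUE, scientific = FALSE)
    }
    if (s$missing_rate > 0) {
      miss <- rng$runif(n) < s$missing_rate
      v[miss] <- c("?", "-")[1 + (seq_len(n)[miss] %% 2)]
    }
    out[[s$feature]] <- v
  }
  out$severity <- cls
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate an expert rating panel
#'
#' Each feature gets a latent Likert importance in 1-5; each expert
#' reports the latent value, perturbed by +/-1 with probability
#' `1 - concordance` (clipped to the 1-5 scale). `concordance = 1` gives a
#' perfectly agreeing panel.
#'
#' @param features feature names (the EDM criteria).
#' @param n_experts panel size (default 4).
#' @param concordance agreement probability in \[0, 1\].
#' @param seed integer seed.
#' @return an [expert_decision_matrix()].
#' @export
simulate_expert_panel <- function(features, n_experts = 4,
                                  concordance = 0.8, seed = 1L) {
  stopifnot(n_experts >= 1)
  if (concordance < 0 || concordance > 1) {
    stop("concordance must be in [0, 1]", call. = FALSE)
  }
  rng <- local_rng(seed)
  latent <- rng$sample_int(5, length(features), replace = TRUE)
  m <- matrix(NA_integer_, n_experts, length(features),
              dimnames = list(paste0("E", seq_len(n_experts)), features))
  for (e in seq_len(n_experts)) {
    flip <- rng$runif(length(features)) < (1 - concordance)
    shift <- ifelse(rng$runif(length(features)) < 0.5, -1L, 1L)
    r <- latent + ifelse(flip, shift, 0L)
    m[e, ] <- pmin(pmax(r, 1L), 5L)
  }
  expert_decision_matrix(m)
}
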