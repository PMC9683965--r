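#' Run configuration
#'
#' Gathers every tunable of the three-phase pipeline. Paths may be `NULL`
#' to request synthetic inputs; the YAML form mirrors this list.
#'
#' @param dataset path to a raw patient table (CSV), or `NULL` to generate
#'   one from `generator`.
#' @param expert_ratings path to an expert-rating CSV, or `NULL` to
#'   simulate a panel.
#' @param expert_opinions character vector of opinion-matrix CSV paths
#'   (one per expert), or `NULL`.
#' @param auto_opinions use the surrogate opinion generator when no
#'   opinion files are given.
#' @param out_dir output directory for artifacts, or `NULL` for none.
#' @param split_frac training fraction.
#' @param smote_k SMOTE neighbour count.
#' @param fs_rule,fs_k,fs_threshold feature-selection rule and parameters.
#' @param relieff_k ReliefF neighbour count.
#' @param bins discretization bins for chi-square / information gain.
#' @param classifiers classifier subset (default all five).
#' @param timing `"none"` (deterministic zero times, the reproducible
#'   default) or `"measured"` (wall-clock seconds).
#' @param bin_edges opinion-surrogate cut points.
#' @param n_experts,concordance simulated-panel shape.
#' @param generator a [generator_config()], or `NULL` for the default.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(dataset = NULL, expert_ratings = NULL,
                       expert_opinions = NULL, auto_opinions = TRUE,
                       out_dir = NULL, split_frac = 0.66, smote_k = 5,
                       fs_rule = "positive", fs_k = NULL,
                       fs_threshold = NULL, relieff_k = 10, bins = 4,
                       classifiers = .clf_order,
                       timing = c("none", "measured"),
                       bin_edges = c(0.1, 0.3, 0.55, 0.8),
                       n_experts = 4, concordance = 0.8,
                       generator = NULL, seed = 1L) {
  stopifnot(split_frac > 0, split_frac < 1)
  timing <- match.arg(timing)
  if (!all(classifiers %in% .clf_order)) {
    stop("unknown classifier in config", call. = FALSE)
  }
  if (is.null(expert_opinions) && !isTRUE(auto_opinions)) {
    stop("no expert opinion files given and auto opinions disabled",
         call. = FALSE)
  }
  structure(list(dataset = dataset, expert_ratings = expert_ratings,
                 expert_opinions = expert_opinions,
                 auto_opinions = auto_opinions, out_dir = out_dir,
                 split_frac = split_frac, smote_k = smote_k,
                 fs_rule = fs_rule, fs_k = fs_k,
                 fs_threshold = fs_threshold, relieff_k = relieff_k,
                 bins = bins, classifiers = classifiers, timing = timing,
                 bin_edges = bin_edges, n_experts = n_experts,
                 concordance = concordance, generator = generator,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# deterministic per-stage sub-seeds, kept within 32-bit range
sub_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2000000011L

#' Run the three-phase pipeline end to end
#'
#' Phase 1 prepares the patient table (clean/encode, impute, normalize,
#' SMOTE). Phase 2, once per filter technique, scores and selects
#' features, derives FWZIC weights for the surviving set from the expert
#' panel, injects the weights, and trains/evaluates each configured
#' classifier on a stratified split; the 7 criteria of every hybrid model
#' form the decision matrix. Phase 3 extracts the ideal solution, obtains
#' opinion matrices (files or the auto surrogate), and produces the group
#' FDOSM ranking.
#'
#' When `cfg$out_dir` is set, every intermediate artifact is written there
#' (prepared table, per-technique score tables, weight sets, weighted
#' datasets, decision matrix, rank report, and a manifest of seeds and
#' parameters).
#'
#' @param cfg a [run_config()].
#' @return a list: `prepared`, `scores`, `selected`, `weights`,
#'   `decision_matrix`, `ideal`, `opinions`, `ranking`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  od <- cfg$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)
  art <- function(name) if (is.null(od)) NULL else file.path(od, name)

  # ---- inputs
  raw <- if (is.null(cfg$dataset)) {
    gen <- cfg$generator %||% generator_config(seed = sub_seed(cfg$seed, 1L))
    stage_log("simulate", "generating %d synthetic rows", gen$n_rows)
    generate_dataset(gen)
  } else {
    utils::read.csv(cfg$dataset, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }

  # ---- phase 1
  pt <- clean_and_encode(raw)
  pt <- impute_mean(pt)
  pt <- minmax_normalize(pt)
  stage_log("prep", "%d rows, %d features, class counts %s", nrow(pt),
            length(pt_features(pt)),
            paste(table(pt[[pt_class_col(pt)]]), collapse = "/"))
  balanced <- smote_balance(pt, k = cfg$smote_k,
                            seed = sub_seed(cfg$seed, 2L))
  stage_log("smote", "balanced to %s rows per class",
            paste(unique(table(balanced[[pt_class_col(balanced)]])),
                  collapse = "/"))
  if (!is.null(od)) {
    utils::write.csv(as.data.frame(balanced), art("prepared.csv"),
                     row.names = FALSE)
    write_codebook(balanced, art("codebook.tsv"))
  }

  # ---- expert panel
  edm <- if (is.null(cfg$expert_ratings)) {
    simulate_expert_panel(pt_features(balanced), n_experts = cfg$n_experts,
                          concordance = cfg$concordance,
                          seed = sub_seed(cfg$seed, 3L))
  } else {
    read_expert_ratings(cfg$expert_ratings)
  }
  missing <- setdiff(pt_features(balanced), colnames(edm$ratings))
  if (length(missing) > 0) {
    stop("expert ratings missing feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }

  # ---- phase 2: per technique
  split <- split_train_test(balanced, frac = cfg$split_frac,
                            seed = sub_seed(cfg$seed, 4L))
  specs <- hybrid_model_specs()
  specs <- specs[specs$classifier %in% cfg$classifiers, ]
  scorers <- list(
    chi2 = function(t) score_chi2(t, bins = cfg$bins),
    infogain = function(t) score_infogain(t, bins = cfg$bins),
    relieff = function(t) score_relieff(t, k = cfg$relieff_k,
                                        seed = sub_seed(cfg$seed, 5L)))
  scores <- list(); selected <- list(); weights <- list(); rows <- list()
  for (tech in unique(specs$fs_technique)) {
    sc <- scorers[[tech]](balanced)
    sel <- select_features(sc, rule = cfg$fs_rule, k = cfg$fs_k,
                           threshold = cfg$fs_threshold)
    stage_log("select", "%s kept %d/%d features", tech, length(sel),
              nrow(sc))
    sub_edm <- expert_decision_matrix(
      edm$ratings[, sel, drop = FALSE], edm$scale)
    w <- fwzic(sub_edm, technique = tech)
    weighted <- apply_feature_weights(balanced, w)
    scores[[tech]] <- sc; selected[[tech]] <- sel; weights[[tech]] <- w
    if (!is.null(od)) {
      write_feature_scores(sc, art(sprintf("scores_%s.csv", tech)), sel)
      write_feature_weights(w, art(sprintf("weights_%s.csv", tech)))
      utils::write.csv(as.data.frame(weighted),
                       art(sprintf("weighted_%s.csv", tech)),
                       row.names = FALSE)
    }
    tr <- apply_feature_weights(split$train, w)
    te <- apply_feature_weights(split$test, w)
    for (i in which(specs$fs_technique == tech)) {
      res <- evaluate_model(specs$classifier[i], tr, te,
                            seed = sub_seed(cfg$seed, 6L),
                            timing = cfg$timing)
      stage_log("evaluate", "%s (%s): accuracy %.4f",
                specs$alternative[i], specs$model[i], res$C4)
      rows[[specs$alternative[i]]] <-
        cbind(data.frame(alternative = specs$alternative[i],
                         model = specs$model[i]), res)
    }
  }
  dm <- build_decision_matrix(do.call(rbind, rows),
                              alternatives = specs$alternative)
  if (!is.null(od)) write_decision_matrix(dm, art("decision_matrix.csv"))

  # ---- phase 3
  ideal <- ideal_solution(dm)
  opinions <- if (!is.null(cfg$expert_opinions)) {
    lapply(cfg$expert_opinions, read_opinion_matrix)
  } else {
    list(auto_opinions(dm, ideal, bin_edges = cfg$bin_edges))
  }
  ranking <- group_rank(opinions,
                        models = stats::setNames(dm$model, dm$alternative))
  stage_log("rank", "best alternative %s (score %.6f)",
            ranking$alternative[ranking$rank == 1],
            min(ranking$score))
  if (!is.null(od)) {
    write_rank_report(ranking, art("rank_report.csv"))
    yaml::write_yaml(list(
      seed = cfg$seed, split_frac = cfg$split_frac, smote_k = cfg$smote_k,
      fs_rule = cfg$fs_rule, relieff_k = cfg$relieff_k, bins = cfg$bins,
      timing = cfg$timing, classifiers = cfg$classifiers,
      package_version = as.character(utils::packageVersion("fuzzybench"))),
      art("manifest.yaml"))
  }
  list(prepared = balanced, scores = scores, selected = selected,
       weights = weights, decision_matrix = dm, ideal = ideal,
       opinions = opinions, ranking = ranking)
}
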