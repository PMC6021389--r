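#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow.  Supply either a
#' cohort `table` or a simulation `sim_spec` (the default simulates the
#' standard synthetic cohort).
#'
#' @param table a [cohort_table()], or `NULL` to simulate.
#' @param sim_spec a [cohort_sim_spec()] used when `table` is `NULL`.
#' @param target target variable (default `"CDR"`).
#' @param features candidate predictor names (default: all dictionary
#'   predictors).
#' @param holdout_fraction independent test fraction (default 0.1).
#' @param folds cross-validation folds (>= 2).
#' @param keep top-k size for the entropy filters.
#' @param smote_k SMOTE neighbourhood size.
#' @param smote_policy `"fold"` applies SMOTE inside training folds during
#'   cross-validation (leakage-safe default); `"development"` balances the
#'   whole development set before cross-validation.
#' @param score structure score, or `"auto"` for CV log-likelihood selection.
#' @param ess equivalent sample size for Dirichlet scores.
#' @param constraints a [structure_constraints()] or `NULL` for the default
#'   clinical tiers.
#' @param seed master seed for every stage.
#' @param out_dir optional directory for artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, sim_spec = NULL, target = "CDR",
                            features = NULL, holdout_fraction = 0.1,
                            folds = 10L, keep = 8L, smote_k = 5L,
                            smote_policy = c("fold", "development"),
                            score = "auto", ess = 10, constraints = NULL,
                            seed = 1L, out_dir = NULL) {
  smote_policy <- match.arg(smote_policy)
  bad <- character()
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    bad <- c(bad, "holdout_fraction")
  if (folds < 2L) bad <- c(bad, "folds")
  if (keep < 1L) bad <- c(bad, "keep")
  if (!score %in% c("auto", "k2", "bde", "mbde", "bic")) bad <- c(bad, "score")
  if (length(bad))
    stop_adbn("adbn_validation_error", "invalid config field(s): %s",
              paste(bad, collapse = ", "))
  structure(list(table = table, sim_spec = sim_spec, target = target,
                 features = features, holdout_fraction = holdout_fraction,
                 folds = as.integer(folds), keep = as.integer(keep),
                 smote_k = as.integer(smote_k), smote_policy = smote_policy,
                 score = score, ess = ess, constraints = constraints,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), c("table", "out_dir"))]
  fnv1a_hex(paste(deparse(keep), collapse = "\n"))
}

# which discretized columns behave as ordered interval codes (for SMOTE)
ordinal_level_map <- function(schemes, dict) {
  out <- list()
  for (s in schemes) {
    f <- s$feature
    ordered_like <- !is.null(s$cut_points) ||
      (!is.null(dict[[f]]) && dict[[f]]$kind == "ordinal")
    if (ordered_like) out[[f]] <- s$interval_labels
  }
  out
}

# score selection with SMOTE applied inside each training fold
select_score_fold_balanced <- function(data, target, constraints, folds, seed,
                                       ess, smote_k, ordinal_levels) {
  scores <- c("k2", "bde", "mbde", "bic")
  fold_id <- kfold_indices(nrow(data), folds, substream_seed(seed, "score_cv"))
  losses <- sapply(scores, function(sc) {
    per_fold <- vapply(seq_len(folds), function(k) {
      train <- data[fold_id != k, , drop = FALSE]
      valid <- data[fold_id == k, , drop = FALSE]
      bal <- balance_classes(train[setdiff(names(train), target)],
                             train[[target]], k_neighbors = smote_k,
                             seed = substream_seed(seed, paste0("fold", k)),
                             ordinal_levels = ordinal_levels)
      bt <- cbind(bal$data[setdiff(names(bal$data), "is_synthetic")],
                  stats::setNames(data.frame(bal$target), target))
      m <- hill_climb(bt, constraints, score = sc, ess = ess)
      m <- fit_cpts(m, bt, smoothing = 1)
      loglik_loss(m, valid)
    }, numeric(1))
    mean(per_fold)
  })
  list(losses = losses, chosen = scores[which.min(losses)])
}

#' Run the full severity-classification pipeline
#'
#' Executes, in order: correlation validation of the CDR target against the
#' clinical diagnosis; complete-case filtering and stratified hold-out
#' split; CAIM/fixed discretization fitted on the development set;
#' entropy-filter feature selection under k-fold CV; SMOTE balancing (per
#' the configured leakage policy); scoring-function selection by CV
#' log-likelihood loss; constrained hill-climb structure learning; CPT
#' fitting; and test-set evaluation.  The held-out test set is only ever
#' read in the final evaluation stage, which the manifest audits.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: the run `manifest` (stages with row counts,
#'   seed, config hash, test-set access audit) and the artifacts
#'   (`correlation`, `schemes`, `selection`, `score_selection`, `model`,
#'   `evaluation`, `selected_features`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dict <- default_dictionary()
  target <- config$target
  features <- config$features %||% setdiff(names(dict), target)
  stages <- list()
  touches <- character()
  note <- function(name, rows_in, rows_out) {
    stages[[length(stages) + 1L]] <<- list(stage = name, rows_in = rows_in,
                                           rows_out = rows_out,
                                           status = "complete")
  }
  table <- config$table %||% generate_cohort(
    config$sim_spec %||% cohort_sim_spec(seed = config$seed))

  # 1. correlation validation of the severity index
  df <- as.data.frame(table)
  pairs <- !is.na(df$diagnosis) & !is.na(df[[target]])
  diag_code <- match(df$diagnosis[pairs], c("HC", "MCI", "AD"))
  corr <- list(pearson = pearson_correlation(diag_code, df[[target]][pairs]),
               n_pairs = sum(pairs))
  note("correlation_validation", nrow(df), sum(pairs))

  # 2. complete-case filter + stratified hold-out split
  complete <- complete_case_filter(table, c(features, target))
  strat <- merge_cdr(as.data.frame(complete)[[target]])
  split <- holdout_split(as.data.frame(complete), config$holdout_fraction,
                         stratify_by = strat, seed = config$seed)
  note("holdout_split", nrow(complete), nrow(split$development))

  # 3. discretization, fitted on the development set only
  dev <- split$development
  schemes <- fit_schemes(cohort_table(dev, dict), features)
  dev_disc <- apply_schemes(cohort_table(dev, dict), schemes)
  note("discretization", nrow(dev), nrow(dev_disc))

  # 4. entropy-filter feature selection (development set only)
  selection <- select_features(dev_disc[features], dev_disc[[target]],
                               folds = config$folds, keep = config$keep,
                               seed = config$seed)
  selected <- selection$final_set
  if (!length(selected)) {
    # no feature reached full stability; fall back to the most stable ones
    ord <- order(-selection$selection_frequency)
    selected <- names(selection$selection_frequency)[ord][seq_len(config$keep)]
  }
  note("feature_selection", nrow(dev_disc), length(selected))

  # 5. SMOTE balancing of the development set
  model_cols <- c(selected, target)
  ord_levels <- ordinal_level_map(schemes[model_cols], dict)
  dev_model <- dev_disc[model_cols]
  if (config$smote_policy == "development") {
    bal <- balance_classes(dev_model[selected], dev_model[[target]],
                           k_neighbors = config$smote_k,
                           seed = config$seed, ordinal_levels = ord_levels)
    cv_data <- cbind(bal$data[selected],
                     stats::setNames(data.frame(bal$target), target))
  } else {
    cv_data <- dev_model
  }
  note("smote_balancing", nrow(dev_model), nrow(cv_data))

  # 6. scoring-function selection by CV log-likelihood loss
  constraints <- config$constraints %||% default_constraints(model_cols)
  score_sel <- if (config$score == "auto") {
    if (config$smote_policy == "fold") {
      select_score_fold_balanced(cv_data, target, constraints, config$folds,
                                 config$seed, config$ess, config$smote_k,
                                 ord_levels)
    } else {
      select_scoring_function(cv_data, constraints, folds = config$folds,
                              seed = config$seed, ess = config$ess)
    }
  } else {
    list(losses = NULL, chosen = config$score)
  }
  note("score_selection", nrow(cv_data), nrow(cv_data))

  # final training table: balanced development set
  train <- if (config$smote_policy == "development") cv_data else {
    bal <- balance_classes(dev_model[selected], dev_model[[target]],
                           k_neighbors = config$smote_k, seed = config$seed,
                           ordinal_levels = ord_levels)
    cbind(bal$data[selected],
          stats::setNames(data.frame(bal$target), target))
  }

  # 7. constrained structure learning
  model <- hill_climb(train, constraints, score = score_sel$chosen,
                      ess = config$ess, seed = config$seed)
  note("structure_learning", nrow(train), nrow(model$edges))

  # 8. CPT fitting (Laplace smoothing for prediction)
  model <- fit_cpts(model, train, smoothing = 1)
  note("cpt_fitting", nrow(train), nrow(train))

  # 9. single-touch evaluation on the held-out test set
  touches <- c(touches, "evaluation")
  test_disc <- apply_schemes(cohort_table(split$test, dict),
                             schemes[model_cols])
  post <- predict_table(model, test_disc[selected], target)
  evaluation <- evaluation_report(test_disc[[target]], post,
                                  split = sprintf("holdout %.0f%%",
                                                  100 * config$holdout_fraction),
                                  seed = config$seed)
  arc <- arc_strength(model, train, method = "ci_test")
  note("evaluation", nrow(split$test), nrow(split$test))

  manifest <- list(stages = stages, seed = config$seed,
                   config_hash = config_hash(config),
                   test_set_touches = touches,
                   n_stages = length(stages))
  result <- structure(list(manifest = manifest, correlation = corr,
                           schemes = schemes, selection = selection,
                           selected_features = selected,
                           score_selection = score_sel, model = model,
                           arc_strength = arc, evaluation = evaluation,
                           constraints = constraints),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_schemes(result$schemes, file.path(out_dir, "schemes.json"))
  write_bn_json(result$model, file.path(out_dir, "model.json"))
  write_bn_dot(result$model, file.path(out_dir, "model.dot"))
  report <- list(
    manifest = result$manifest,
    correlation = result$correlation,
    selected_features = result$selected_features,
    selection_frequency = as.list(result$selection$selection_frequency),
    score_selection = result$score_selection,
    evaluation = list(mca = result$evaluation$mca,
                      mca_ci = result$evaluation$mca_ci,
                      auc = result$evaluation$auc,
                      per_class = result$evaluation$per_class,
                      n_test = result$evaluation$n_test))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(out_dir)
}

#' Learn and compare severity networks at two time points
#'
#' Builds one Bayesian network per time slice (baseline records vs the
#' earliest complete later visit per subject) on the same feature set and
#' returns the paired models, their evaluations (30\% hold-out, following
#' the smaller longitudinal samples) and the structural diff.  Under the
#' paired-subject convention (`group = 2`) the time-invariant ApoE genotype
#' is dropped from the node set.
#'
#' @param config a [pipeline_config()]; `config$features` defaults to the
#'   eight signal features.
#' @param group 1 (overlapping subject sets) or 2 (same subjects at both
#'   times).
#' @return list with `baseline`, `later` (each: `model`, `evaluation`,
#'   `n`), `diff` from [compare_networks()], and the feature set used.
#' @export
run_longitudinal_experiment <- function(config = pipeline_config(), group = 2L) {
  stopifnot(group %in% c(1L, 2L))
  dict <- default_dictionary()
  target <- config$target
  features <- config$features %||%
    c("age", "ApoE", "GM", "CSF", "PiB_PET", "MMSE", "LMIR", "LMDR")
  if (group == 2L) features <- setdiff(features, "ApoE")
  if (!length(features))
    stop_adbn("adbn_validation_error", "feature set empty after drops")
  table <- config$table %||% generate_cohort(
    config$sim_spec %||% cohort_sim_spec(seed = config$seed))
  groups <- assemble_groups(table, c(features, target))
  g <- groups[[group]]
  if (!length(g$baseline_rows) || !length(g$later_rows))
    stop_adbn("adbn_validation_error", "a time slice is empty after filtering")

  slice_fit <- function(rows, tag) {
    slice <- cohort_table(as.data.frame(table)[rows, , drop = FALSE], dict)
    strat <- merge_cdr(as.data.frame(slice)[[target]])
    # a slice can be too small to stratify its rarest severity class
    if (min(table(strat)) < 4L) strat <- NULL
    split <- holdout_split(as.data.frame(slice), 0.3, stratify_by = strat,
                           seed = substream_seed(config$seed, tag))
    schemes <- fit_schemes(cohort_table(split$development, dict), features)
    dev <- apply_schemes(cohort_table(split$development, dict), schemes)
    cols <- c(features, target)
    cons <- config$constraints %||% default_constraints(cols)
    sc <- if (config$score == "auto") "bic" else config$score
    model <- hill_climb(dev[cols], cons, score = sc, ess = config$ess)
    model <- fit_cpts(model, dev[cols], smoothing = 1)
    test <- apply_schemes(cohort_table(split$test, dict), schemes)
    post <- predict_table(model, test[features], target)
    list(model = model,
         evaluation = evaluation_report(test[[target]], post,
                                        split = "holdout 30%",
                                        seed = config$seed),
         n = nrow(slice))
  }
  baseline <- slice_fit(g$baseline_rows, "longitudinal_bl")
  later <- slice_fit(g$later_rows, "longitudinal_later")
  list(baseline = baseline, later = later,
       diff = compare_networks(baseline$model, later$model),
       features = features, group = group)
}
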