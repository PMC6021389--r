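#' Stratified hold-out split
#'
#' Disjoint, exhaustive partition of a table's rows into a model-development
#' set and an independent test set.  With stratification the per-stratum
#' test counts are `round(fraction * n_s)`, so stratum proportions are
#' preserved within rounding; a stratum that would leave either side empty
#' is an error.
#'
#' @param table data.frame (or cohort_table).
#' @param fraction test fraction in (0, 1).
#' @param stratify_by optional column name (or vector) defining strata.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `development` and `test` (row subsets of `table`) and
#'   `test_rows` (the integer test indices).
#' @export
holdout_split <- function(table, fraction, stratify_by = NULL, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_adbn("adbn_input_error", "fraction must lie in (0, 1)")
  n <- nrow(table)
  set.seed(substream_seed(seed, "holdout_split"))
  if (is.null(stratify_by)) {
    n_test <- round(fraction * n)
    if (n_test < 1 || n_test >= n)
      stop_adbn("adbn_input_error", "fraction leaves an empty side")
    test_rows <- sort(sample.int(n, n_test))
  } else {
    strata <- if (length(stratify_by) == 1L && is.character(stratify_by))
      table[[stratify_by]] else stratify_by
    strata <- factor(strata)
    test_rows <- integer()
    for (s in levels(strata)) {
      rows <- which(strata == s)
      k <- round(fraction * length(rows))
      if (k < 1 || k >= length(rows))
        stop_adbn("adbn_stratification_error",
                  "stratum '%s' too small for fraction %.3f", s, fraction)
      test_rows <- c(test_rows, sample(rows, k))
    }
    test_rows <- sort(test_rows)
  }
  list(development = table[-test_rows, , drop = FALSE],
       test = table[test_rows, , drop = FALSE],
       test_rows = test_rows)
}

#' Random k-fold assignment
#'
#' Every record lands in exactly one fold; fold sizes differ by at most one.
#'
#' @param n number of records.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1:k`.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k > n) stop_adbn("adbn_input_error", "k exceeds the number of records")
  if (k < 1) stop_adbn("adbn_input_error", "k must be positive")
  set.seed(seed)
  fold <- rep(seq_len(k), length.out = n)
  fold[sample.int(n)]
}

#' Multi-class classification accuracy with exact binomial CI
#'
#' Proportion of correct hard predictions with a Clopper-Pearson
#' (exact binomial) 95\% confidence interval.
#'
#' @param truth,predicted equal-length label vectors.
#' @return list with `mca`, `ci` (length-2), `n`.
#' @export
multiclass_accuracy <- function(truth, predicted) {
  if (!length(truth)) stop_adbn("adbn_input_error", "empty input")
  if (length(truth) != length(predicted))
    stop_adbn("adbn_input_error", "length mismatch")
  x <- sum(as.character(truth) == as.character(predicted))
  n <- length(truth)
  bt <- stats::binom.test(x, n)
  list(mca = x / n, ci = as.vector(bt$conf.int), n = n)
}

# midrank (Mann-Whitney) AUC of scores for a binary indicator
binary_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multi-class AUC from posterior probabilities
#'
#' Default is the macro average of one-vs-rest AUCs, each computed from the
#' posterior probability of the positive class with midrank tie handling.
#' `method = "hand_till"` gives the pairwise class-conditional average
#' instead.  Classes absent from the truth are excluded with a warning.
#'
#' @param truth label vector.
#' @param posterior matrix of per-record class probabilities, columns named
#'   by class; rows must sum to 1 within 1e-6.
#' @param method `"macro_ovr"` or `"hand_till"`.
#' @return AUC in \[0, 1\].
#' @export
multiclass_auc <- function(truth, posterior, method = "macro_ovr") {
  posterior <- as.matrix(posterior)
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stop_adbn("adbn_input_error", "posterior rows must sum to 1")
  classes <- colnames(posterior)
  truth <- as.character(truth)
  present <- classes[classes %in% truth]
  if (!length(present))
    stop_adbn("adbn_input_error", "no posterior class present in truth")
  if (length(present) < length(classes))
    warning(sprintf("class(es) absent from truth excluded from AUC: %s",
                    paste(setdiff(classes, present), collapse = ", ")),
            call. = FALSE)
  if (method == "macro_ovr") {
    aucs <- vapply(present, function(cl) {
      binary_auc(posterior[, cl], truth == cl)
    }, numeric(1))
    return(mean(aucs))
  }
  if (method != "hand_till")
    stop_adbn("adbn_input_error", "unknown AUC method '%s'", method)
  pairs <- utils::combn(present, 2, simplify = FALSE)
  vals <- vapply(pairs, function(p) {
    sel <- truth %in% p
    a_ij <- binary_auc(posterior[sel, p[1]], truth[sel] == p[1])
    a_ji <- binary_auc(posterior[sel, p[2]], truth[sel] == p[2])
    (a_ij + a_ji) / 2
  }, numeric(1))
  mean(vals)
}

#' Confusion matrix (rows = truth, columns = prediction)
#'
#' @param truth,predicted label vectors.
#' @param labels class label order (default: union, sorted by first
#'   appearance in `labels(truth)` factor levels or sort order).
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  labels <- labels %||% (if (is.factor(truth)) levels(truth)
                         else sort(unique(c(as.character(truth),
                                            as.character(predicted)))))
  m <- table(factor(as.character(truth), levels = labels),
             factor(as.character(predicted), levels = labels))
  structure(unclass(m), class = "confusion_matrix")
}

#' Per-class sensitivity and specificity (one-vs-rest)
#'
#' For each class c: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#' Undefined ratios (zero denominators) are reported as `NA`, never as 0.
#'
#' @param confusion a [confusion_matrix()].
#' @return data.frame with columns `class`, `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(confusion) {
  m <- unclass(confusion)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- sum(m) - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(class = rownames(m),
             sensitivity = safe(tp, tp + fn),
             specificity = safe(tn, tn + fp),
             row.names = NULL)
}

#' Pearson correlation with Fisher-z CI and t-test p-value
#'
#' @param x,y equal-length complete numeric vectors, n >= 3, both with
#'   nonzero variance.
#' @return list with `r`, `ci` (95\%), `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_adbn("adbn_input_error", "length mismatch")
  if (length(x) < 3) stop_adbn("adbn_input_error", "need n >= 3")
  if (anyNA(x) || anyNA(y))
    stop_adbn("adbn_input_error", "complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_adbn("adbn_undefined_correlation", "zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), ci = as.vector(ct$conf.int),
       p_value = ct$p.value, n = length(x))
}

# posterior argmax with ties broken toward the more severe class, i.e. the
# later column (class columns are ordered by increasing severity)
argmax_severe <- function(posterior) {
  colnames(posterior)[max.col(posterior, ties.method = "last")]
}

#' Evaluation report from a posterior matrix
#'
#' @param truth factor of true classes (levels in increasing severity).
#' @param posterior per-record posterior matrix.
#' @param split free-text descriptor of the split used.
#' @param seed seed recorded for provenance.
#' @return an `evaluation_report`: `mca` (+ CI), `auc`, `per_class`
#'   sensitivity/specificity, `confusion`, `n_test`, `split`, `seed`.
#' @export
evaluation_report <- function(truth, posterior, split = "holdout", seed = NA) {
  predicted <- argmax_severe(posterior)
  acc <- multiclass_accuracy(truth, predicted)
  auc <- suppressWarnings(multiclass_auc(truth, posterior))
  conf <- confusion_matrix(truth, predicted, labels = colnames(posterior))
  structure(list(mca = acc$mca, mca_ci = acc$ci, auc = auc,
                 per_class = sensitivity_specificity(conf),
                 confusion = conf, n_test = length(truth),
                 split = split, seed = seed),
            class = "evaluation_report")
}

#' Learn/fit/predict/evaluate over several feature subsets
#'
#' For each subset, on one identical stratified split, learn the structure
#' over subset + target under the constraints, fit CPTs (Laplace
#' smoothing 1), predict the target posterior on the test rows, and report
#' the evaluation metrics — making the reports comparable across subsets.
#'
#' @param data fully discretized data.frame of factors including the target
#'   column.
#' @param subsets named list of character feature sets (non-empty).
#' @param target target column name.
#' @param constraints a [structure_constraints()] (defaults to the clinical
#'   tier order restricted to each subset).
#' @param score structure score name.
#' @param seed integer seed (split + learning).
#' @param fraction test fraction (default 0.1).
#' @param ess equivalent sample size for Dirichlet scores.
#' @return named list of `evaluation_report`s.
#' @export
evaluate_feature_subsets <- function(data, subsets, target = "CDR",
                                     constraints = NULL, score = "bic",
                                     seed = 1L, fraction = 0.1, ess = 10) {
  if (!length(subsets) || any(!vapply(subsets, length, 1L)))
    stop_adbn("adbn_input_error", "subsets must be non-empty feature sets")
  unknown <- setdiff(unique(unlist(subsets)), names(data))
  if (length(unknown))
    stop_adbn("adbn_lookup_error", "unknown feature(s): %s",
              paste(unknown, collapse = ", "))
  split <- holdout_split(data, fraction, stratify_by = target, seed = seed)
  lapply(subsets, function(fs) {
    cols <- c(fs, target)
    cons <- constraints %||% default_constraints(cols)
    model <- hill_climb(split$development[cols], cons, score = score, ess = ess)
    model <- fit_cpts(model, split$development[cols], smoothing = 1)
    post <- predict_table(model, split$test[fs], target)
    rep <- evaluation_report(split$test[[target]], post,
                             split = sprintf("holdout %.0f%%", 100 * fraction),
                             seed = seed)
    rep$model <- model
    rep
  })
}
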