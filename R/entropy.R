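#' Shannon entropy of a discrete distribution
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \cdot \log 0 = 0}.  Base-2 logarithms throughout, so entropies are
#' in bits.
#'
#' @param p non-negative probabilities summing to 1 (tolerance 1e-9).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop_adbn("adbn_input_error", "negative probability")
  if (abs(sum(p) - 1) > 1e-9)
    stop_adbn("adbn_input_error", "probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

empirical_entropy <- function(x) {
  shannon_entropy(as.vector(table(x)) / length(x))
}

joint_entropy <- function(x, y) {
  shannon_entropy(as.vector(table(x, y)) / length(x))
}

check_paired <- function(classes, attribute) {
  if (length(classes) != length(attribute))
    stop_adbn("adbn_input_error", "classes and attribute differ in length")
  if (anyNA(classes) || anyNA(attribute))
    stop_adbn("adbn_input_error", "missing values are not allowed here")
}

#' Information gain between a class and a discrete attribute
#'
#' \eqn{IG = H(Class) + H(Attribute) - H(Class, Attribute)}, evaluated on
#' empirical plug-in distributions without smoothing.
#'
#' @param classes,attribute equal-length label vectors, no missing values.
#' @return information gain in bits (non-negative up to rounding).
#' @export
information_gain <- function(classes, attribute) {
  check_paired(classes, attribute)
  h <- empirical_entropy(classes) + empirical_entropy(attribute) -
    joint_entropy(classes, attribute)
  max(h, 0)
}

#' Information gain ratio
#'
#' Information gain divided by the attribute entropy.  A constant attribute
#' has zero entropy and an undefined ratio; this is an error (such features
#' are reported as excluded from rankings, never as zero).
#'
#' @inheritParams information_gain
#' @return dimensionless gain ratio.
#' @export
gain_ratio <- function(classes, attribute) {
  check_paired(classes, attribute)
  ha <- empirical_entropy(attribute)
  if (ha <= 0)
    stop_adbn("adbn_undefined_ratio", "gain ratio undefined for a constant attribute")
  information_gain(classes, attribute) / ha
}

#' Symmetrical uncertainty
#'
#' \eqn{SU = 2 \, IG / (H(Class) + H(Attribute))}, a symmetric dependence
#' measure in \[0, 1\].
#'
#' @inheritParams information_gain
#' @return symmetrical uncertainty in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(classes, attribute) {
  check_paired(classes, attribute)
  denom <- empirical_entropy(classes) + empirical_entropy(attribute)
  if (denom <= 0)
    stop_adbn("adbn_undefined_ratio", "symmetrical uncertainty undefined: both entropies zero")
  min(1, 2 * information_gain(classes, attribute) / denom)
}

#' Entropy profile of every feature against a target
#'
#' @param data data.frame of discrete feature columns.
#' @param target discrete target vector.
#' @return data.frame with columns `feature`, `ig`, `igr`, `su`; features
#'   with an undefined gain ratio carry `NA` there.
#' @export
entropy_profile <- function(data, target) {
  res <- lapply(names(data), function(f) {
    x <- data[[f]]
    igr <- tryCatch(gain_ratio(target, x), adbn_undefined_ratio = function(e) NA_real_)
    data.frame(feature = f,
               ig = information_gain(target, x),
               igr = igr,
               su = symmetrical_uncertainty(target, x))
  })
  do.call(rbind, res)
}

# rank features descending by a criterion; NA (undefined) sorts last;
# ties break by column order for determinism
rank_features <- function(values, features) {
  ord <- order(ifelse(is.na(values), Inf, -values), seq_along(values))
  features[ord]
}

# gain-ratio ranking with the C4.5 eligibility gate: the ratio is unstable
# for near-constant attributes (tiny denominator), so features below the
# median information gain rank after those above it
rank_features_igr <- function(igr, ig, features) {
  eligible <- !is.na(igr) & ig >= stats::median(ig)
  c(rank_features(igr[eligible], features[eligible]),
    rank_features(igr[!eligible], features[!eligible]))
}

#' Cross-validated entropy-filter feature selection
#'
#' In each of `folds` cross-validation folds the training portion is ranked
#' by information gain, gain ratio and symmetrical uncertainty against the
#' target; a feature counts as selected in a fold when it lies in the top
#' `keep` of all three rankings simultaneously.  The selection frequency of
#' a feature is the percentage of folds in which it was selected; the final
#' set contains the features at 100\% frequency.
#'
#' @param data fully discretized predictor data.frame (factors, no missing).
#' @param target discretized target vector.
#' @param folds number of CV folds (>= 2).
#' @param keep size of each filter's top list.
#' @param seed integer seed controlling the fold assignment.
#' @return a `selection_report`: list with `per_fold` rankings,
#'   `selection_frequency` (named percentages), `final_set`, and the call
#'   parameters.
#' @export
select_features <- function(data, target, folds = 10L, keep = 8L, seed = 1L) {
  if (keep > ncol(data))
    stop_adbn("adbn_input_error", "keep exceeds the number of features")
  if (folds < 2L) stop_adbn("adbn_input_error", "folds must be >= 2")
  fold_id <- kfold_indices(nrow(data), folds, substream_seed(seed, "select_features"))
  feats <- names(data)
  per_fold <- vector("list", folds)
  selected <- matrix(FALSE, folds, length(feats), dimnames = list(NULL, feats))
  for (k in seq_len(folds)) {
    train <- fold_id != k
    prof <- entropy_profile(data[train, , drop = FALSE], target[train])
    tops <- list(
      ig = utils::head(rank_features(prof$ig, prof$feature), keep),
      igr = utils::head(rank_features_igr(prof$igr, prof$ig, prof$feature),
                        keep),
      su = utils::head(rank_features(prof$su, prof$feature), keep))
    per_fold[[k]] <- tops
    selected[k, Reduce(intersect, tops)] <- TRUE
  }
  freq <- colMeans(selected) * 100
  structure(list(per_fold = per_fold,
                 selection_frequency = freq,
                 final_set = feats[freq >= 100],
                 folds = folds, keep = keep, seed = seed),
            class = "selection_report")
}

#' Correlation between two ordinal codings, Pearson and Spearman
#'
#' Validation utility: Pearson product-moment correlation with Fisher-z 95\%
#' confidence interval and two-sided t-test p-value, together with the
#' Spearman rank correlation, on integer-coded ordinal variables.
#'
#' @param x,y equal-length complete ordinal codes (numeric), n >= 3.
#' @return list with `pearson` (as returned by [pearson_correlation()]) and
#'   `spearman` (`rho`, `p_value`).
#' @export
correlation_filter <- function(x, y) {
  pear <- pearson_correlation(x, y)
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson = pear,
       spearman = list(rho = unname(sp$estimate), p_value = sp$p.value))
}
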