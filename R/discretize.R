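#' Build a class-by-interval quanta matrix
#'
#' The quanta matrix is the contingency table that underlies the CAIM
#' criterion: rows are target classes, columns the intervals induced by a
#' set of cut points.  Interval r is the half-open cell (b[r-1], b[r]] with
#' infinite outer bounds, so the binning is total on any real input.
#'
#' @param values numeric vector (no missing values).
#' @param classes class label per value.
#' @param boundaries strictly increasing numeric cut points (may be empty).
#' @return an object of class `quanta_matrix` with elements `counts`
#'   (class x interval), `class_labels`, `boundaries`, `column_totals`,
#'   `column_maxima` and `n` (number of intervals).
#' @export
build_quanta_matrix <- function(values, classes, boundaries = numeric()) {
  if (length(values) != length(classes))
    stop_adbn("adbn_input_error", "values and classes differ in length")
  if (anyNA(values) || anyNA(classes))
    stop_adbn("adbn_input_error", "missing values are not allowed here")
  if (length(boundaries) && any(diff(boundaries) <= 0))
    stop_adbn("adbn_input_error", "boundaries must be strictly increasing")
  breaks <- c(-Inf, boundaries, Inf)
  bin <- cut(values, breaks = breaks, right = TRUE, labels = FALSE)
  cls <- factor(classes)
  counts <- table(class = cls, interval = factor(bin, levels = seq_len(length(breaks) - 1L)))
  counts <- unclass(counts)
  structure(list(counts = counts,
                 class_labels = levels(cls),
                 boundaries = boundaries,
                 column_totals = colSums(counts),
                 column_maxima = apply(counts, 2L, max),
                 n = ncol(counts)),
            class = "quanta_matrix")
}

#' CAIM criterion of a quanta matrix
#'
#' The class-attribute interdependence maximization score
#' \deqn{CAIM = \frac{1}{n} \sum_{r=1}^{n} \frac{max_r^2}{M_{+r}}}
#' where \eqn{max_r} is the largest class count in interval r, \eqn{M_{+r}}
#' the interval total and n the number of intervals.  Larger is better; a
#' single pure interval of N samples scores N.
#'
#' @param q a [build_quanta_matrix()] result.
#' @return the CAIM score (non-negative real).
#' @export
caim_score <- function(q) {
  stopifnot(inherits(q, "quanta_matrix"))
  if (any(q$column_totals == 0))
    stop_adbn("adbn_degenerate_error", "empty interval in quanta matrix")
  sum(q$column_maxima^2 / q$column_totals) / q$n
}

#' Supervised CAIM discretization of a continuous feature
#'
#' Greedy boundary insertion: candidate cut points are midpoints between
#' consecutive distinct sorted values; each step adds the candidate that
#' maximizes the CAIM score of the augmented scheme (ties break toward the
#' smaller cut point).  A new boundary is accepted while it strictly improves
#' the score, or while the scheme still has fewer intervals than there are
#' target classes; the search also stops at `max_intervals`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param classes target class per value; at least two classes present.
#' @param max_intervals optional cap on the number of intervals (default:
#'   number of classes present, mirroring the convention that features
#'   without explicit categories get as many intervals as the severity
#'   target has).
#' @param feature feature name recorded in the returned scheme.
#' @return a `discretization_scheme` (mode `"caim"`) with elements `feature`,
#'   `cut_points`, `interval_labels` and `achieved_caim`.
#' @export
caim_discretize <- function(values, classes, max_intervals = NULL,
                            feature = "feature") {
  keep <- !(is.na(values) | is.na(classes))
  values <- values[keep]; classes <- classes[keep]
  distinct <- sort(unique(values))
  if (length(distinct) < 2L)
    stop_adbn("adbn_degenerate_error", "feature '%s' has < 2 distinct values", feature)
  n_classes <- length(unique(classes))
  if (n_classes < 2L)
    stop_adbn("adbn_degenerate_error", "only one class present")
  max_intervals <- max_intervals %||% n_classes
  candidates <- (distinct[-1] + distinct[-length(distinct)]) / 2

  chosen <- numeric()
  current_score <- caim_score(build_quanta_matrix(values, classes, chosen))
  repeat {
    if (length(chosen) + 1L >= max_intervals) break
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(b) {
      caim_score(build_quanta_matrix(values, classes, sort(c(chosen, b))))
    }, numeric(1))
    best <- which.max(scores)        # ties: which.max takes the first, i.e.
    best_score <- scores[best]       # the smaller cut point (sorted order)
    grow_forced <- (length(chosen) + 1L) < n_classes
    if (best_score > current_score || grow_forced) {
      chosen <- sort(c(chosen, remaining[best]))
      current_score <- best_score
    } else break
  }
  new_scheme(feature, mode = "caim", cut_points = chosen,
             interval_labels = interval_labels_for(chosen),
             achieved_caim = current_score)
}

interval_labels_for <- function(cuts) {
  lo <- c(-Inf, cuts); hi <- c(cuts, Inf)
  sprintf("(%s,%s]", formatC(lo, format = "g"), formatC(hi, format = "g"))
}

new_scheme <- function(feature, mode, cut_points = NULL, category_map = NULL,
                       interval_labels, achieved_caim = NA_real_) {
  structure(list(feature = feature, mode = mode,
                 cut_points = cut_points, category_map = category_map,
                 interval_labels = interval_labels,
                 achieved_caim = achieved_caim),
            class = "discretization_scheme")
}

#' Fixed clinical discretization schemes
#'
#' Three features carry conventional category structures rather than learned
#' cut points: the CDR severity target collapses to three classes (normal /
#' very mild / mild-moderate, the severe class being outside the supported
#' range), the MMSE uses the common clinical bands 24-30 / 19-23 / 10-18 /
#' 0-9, and the ApoE genotype keeps its five allele combinations.
#'
#' @param feature one of `"CDR"`, `"MMSE"`, `"ApoE"`.
#' @return a `discretization_scheme` (mode `"fixed"`).
#' @export
fixed_scheme <- function(feature) {
  switch(feature,
    CDR = new_scheme("CDR", "fixed",
                     category_map = c("0" = "normal", "0.5" = "very mild",
                                      "1" = "mild/moderate", "2" = "mild/moderate"),
                     interval_labels = c("normal", "very mild", "mild/moderate")),
    MMSE = new_scheme("MMSE", "fixed", cut_points = c(9.5, 18.5, 23.5),
                      interval_labels = c("0-9", "10-18", "19-23", "24-30")),
    ApoE = new_scheme("ApoE", "fixed",
                      category_map = stats::setNames(apoe_genotypes(),
                                                     apoe_genotypes()),
                      interval_labels = apoe_genotypes()),
    stop_adbn("adbn_lookup_error", "no fixed scheme for feature '%s'", feature)
  )
}

#' Identity scheme for an already-categorical feature
#' @param feature feature name.
#' @param categories its category labels.
#' @return a `discretization_scheme` mapping each category to itself.
#' @export
identity_scheme <- function(feature, categories) {
  new_scheme(feature, "fixed",
             category_map = stats::setNames(categories, categories),
             interval_labels = unique(unname(categories)))
}

#' Apply a discretization scheme to raw values
#'
#' Total on its input: cut-point schemes assign any real to a half-open
#' interval (a value equal to a cut point falls in the lower interval);
#' missing values stay missing.  Fixed category maps raise an out-of-support
#' error for unlisted values (e.g. a CDR of 3, outside the supported
#' severity range).
#'
#' @param values numeric or character vector.
#' @param scheme a `discretization_scheme`.
#' @return a factor of interval codes with the scheme's `interval_labels`.
#' @export
apply_scheme <- function(values, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (!is.null(scheme$cut_points) || (scheme$mode == "caim")) {
    breaks <- c(-Inf, scheme$cut_points, Inf)
    idx <- cut(as.numeric(values), breaks = breaks, right = TRUE, labels = FALSE)
    return(factor(scheme$interval_labels[idx], levels = scheme$interval_labels))
  }
  vals <- as.character(values)
  known <- is.na(vals) | vals %in% names(scheme$category_map)
  if (!all(known))
    stop_adbn("adbn_support_error",
              "value(s) outside the support of the '%s' scheme: %s",
              scheme$feature, paste(unique(vals[!known]), collapse = ", "))
  factor(unname(scheme$category_map[vals]), levels = scheme$interval_labels)
}

#' Fit discretization schemes for a cohort table
#'
#' CDR, MMSE and ApoE receive their fixed clinical schemes; other
#' categorical features keep their categories; continuous features are
#' CAIM-discretized against the (merged, three-class) CDR target.  Schemes
#' are meant to be fitted on the model-development set and applied frozen to
#' held-out data.
#'
#' @param table a [cohort_table()], complete in `features` and CDR.
#' @param features predictor names to fit schemes for.
#' @param max_intervals cap for CAIM schemes (default 3, the number of
#'   merged severity classes).
#' @return named list of schemes, including the CDR target scheme.
#' @export
fit_schemes <- function(table, features, max_intervals = 3L) {
  dict <- attr(table, "dictionary")
  features <- lookup_features(table, features)
  df <- as.data.frame(table)
  target <- apply_scheme(df$CDR, fixed_scheme("CDR"))
  schemes <- list(CDR = fixed_scheme("CDR"))
  for (f in features) {
    spec <- dict[[f]]
    schemes[[f]] <-
      if (f %in% c("MMSE", "ApoE")) fixed_scheme(f)
      else if (spec$kind != "continuous") identity_scheme(f, spec$categories)
      else caim_discretize(df[[f]], target, max_intervals = max_intervals,
                           feature = f)
  }
  schemes
}

#' Apply fitted schemes to a cohort table
#'
#' @param table a [cohort_table()].
#' @param schemes result of [fit_schemes()].
#' @return a data.frame of factors, one column per scheme, same row order.
#' @export
apply_schemes <- function(table, schemes) {
  df <- as.data.frame(table)
  out <- lapply(schemes, function(s) apply_scheme(df[[s$feature]], s))
  names(out) <- vapply(schemes, `[[`, "", "feature")
  as.data.frame(out, check.names = FALSE)
}

#' Serialize / restore discretization schemes
#'
#' Plain-text key-value representation so a saved model is self-describing.
#'
#' @param schemes named list of schemes.
#' @param path output file.
#' @return `path` (write) or the scheme list (read).
#' @export
write_schemes <- function(schemes, path) {
  payload <- lapply(schemes, function(s) {
    s <- unclass(s)
    if (!is.null(s$category_map)) s$category_map <- as.list(s$category_map)
    s
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(s) {
    new_scheme(s$feature, s$mode,
               cut_points = if (length(s$cut_points)) as.numeric(s$cut_points),
               category_map = if (length(s$category_map)) unlist(s$category_map),
               interval_labels = as.character(s$interval_labels),
               achieved_caim = s$achieved_caim %||% NA_real_)
  })
}
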