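# Mixed-type distance matrix for SMOTE on discretized records:
# squared Euclidean over numeric/ordinal coordinates (interval codes treated
# as integers) plus a unit penalty per mismatching nominal coordinate.
smote_distances <- function(num, nom) {
  n <- if (!is.null(num)) nrow(num) else nrow(nom)
  d2 <- matrix(0, n, n)
  if (!is.null(num) && ncol(num)) {
    d2 <- as.matrix(stats::dist(num))^2
  }
  if (!is.null(nom) && ncol(nom)) {
    for (j in seq_len(ncol(nom))) {
      d2 <- d2 + outer(nom[[j]], nom[[j]], FUN = `!=`)
    }
  }
  d2
}

split_kinds <- function(rows, ordinal_levels) {
  is_factor <- vapply(rows, is.factor, TRUE)
  ord <- names(rows)[names(rows) %in% names(ordinal_levels)]
  nominal <- setdiff(names(rows)[is_factor], ord)
  numeric_cols <- setdiff(names(rows), nominal)
  list(numeric = numeric_cols, nominal = nominal, ordinal = ord)
}

#' SMOTE oversampling of a minority class
#'
#' Generates `ceil(amount/100 * nrow(rows))` synthetic records.  Each one
#' takes a minority record x and one of its `k_neighbors` nearest minority
#' neighbours z (mixed-type distance: Euclidean over numeric and ordinal
#' coordinates, a unit penalty per nominal mismatch) and interpolates:
#' numeric coordinates become `x + u (z - x)` with u uniform on \[0, 1\]
#' (ordinal coordinates are then rounded to the nearest valid code); nominal
#' coordinates take the majority value among the k nearest neighbours, ties
#' resolving to x's value.
#'
#' @param rows data.frame of minority records over the modelling features
#'   (numeric columns interpolate; factor columns listed in
#'   `ordinal_levels` are treated as integer codes, other factors as
#'   nominal).
#' @param amount oversampling percentage (0 gives no rows).
#' @param k_neighbors number of nearest neighbours (must be < nrow(rows)).
#' @param seed integer seed.
#' @param ordinal_levels named list: for each ordinal factor column, its
#'   ordered level set.
#' @return data.frame of synthetic records with the same columns.
#' @export
smote_oversample <- function(rows, amount, k_neighbors = 5L, seed = 1L,
                             ordinal_levels = list()) {
  n_syn <- ceiling(amount / 100 * nrow(rows))
  smote_synthesize(rows, n_syn, k_neighbors, seed, ordinal_levels)
}

smote_synthesize <- function(rows, n_syn, k_neighbors, seed, ordinal_levels) {
  n <- nrow(rows)
  if (n < 2L)
    stop_adbn("adbn_neighbors_error",
              "SMOTE needs at least 2 minority records, got %d", n)
  if (k_neighbors >= n) k_neighbors <- n - 1L
  if (n_syn <= 0) return(rows[0, , drop = FALSE])

  kinds <- split_kinds(rows, ordinal_levels)
  # integer-code view of ordinal factors for distance + interpolation
  num <- rows[kinds$numeric]
  for (f in kinds$ordinal) num[[f]] <- as.integer(rows[[f]])
  num <- as.data.frame(lapply(num, as.numeric))
  nom <- rows[kinds$nominal]

  d2 <- smote_distances(if (ncol(num)) num else NULL,
                        if (ncol(nom)) nom else NULL)
  diag(d2) <- Inf
  nn_raw <- apply(d2, 1L, function(d) order(d)[seq_len(k_neighbors)])
  nn <- if (k_neighbors == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)

  set.seed(seed)
  seed_idx <- rep(sample.int(n), length.out = n_syn)
  pick <- sample.int(k_neighbors, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)

  out <- rows[seed_idx, , drop = FALSE]
  z_idx <- nn[cbind(seed_idx, pick)]
  for (f in c(kinds$numeric, kinds$ordinal)) {
    xi <- num[[f]][seed_idx]
    zi <- num[[f]][z_idx]
    val <- xi + u * (zi - xi)
    if (f %in% kinds$ordinal) {
      code <- pmin(pmax(round(val), 1L), length(levels(rows[[f]])))
      out[[f]] <- factor(levels(rows[[f]])[code], levels = levels(rows[[f]]))
    } else {
      out[[f]] <- val
    }
  }
  for (f in kinds$nominal) {
    vals <- rows[[f]]
    out[[f]] <- vapply(seq_len(n_syn), function(i) {
      neigh <- vals[nn[seed_idx[i], ]]
      tab <- table(neigh)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) winners else as.character(vals[seed_idx[i]])
    }, character(1))
    out[[f]] <- factor(out[[f]], levels = levels(vals))
  }
  rownames(out) <- NULL
  out
}

#' Balance class counts by SMOTE oversampling
#'
#' Every class is oversampled up to the majority-class count.  Original rows
#' are preserved verbatim; synthetic rows are appended with
#' `is_synthetic = 1`, so removing flagged rows restores the input exactly.
#'
#' @param data data.frame of modelling features (discretized or numeric).
#' @param target class label per row.
#' @param k_neighbors SMOTE neighbourhood size.
#' @param seed integer seed.
#' @param ordinal_levels see [smote_oversample()].
#' @return list with `data` (balanced feature table plus `is_synthetic`
#'   column) and `target` (extended class vector).
#' @export
balance_classes <- function(data, target, k_neighbors = 5L, seed = 1L,
                            ordinal_levels = list()) {
  target <- factor(target)
  counts <- table(target)
  if (length(counts) < 2L)
    stop_adbn("adbn_input_error", "need at least 2 classes to balance")
  goal <- max(counts)
  out <- cbind(data, is_synthetic = 0L)
  out_target <- as.character(target)
  for (cl in names(counts)) {
    need <- goal - counts[[cl]]
    if (need == 0L) next
    if (counts[[cl]] < 2L)
      stop_adbn("adbn_neighbors_error",
                "class '%s' has a single record; cannot SMOTE", cl)
    rows <- data[target == cl, , drop = FALSE]
    syn <- smote_synthesize(rows, need, k_neighbors,
                            substream_seed(seed, paste0("smote_", cl)),
                            ordinal_levels)
    syn <- cbind(syn, is_synthetic = 1L)
    out <- rbind(out, syn)
    out_target <- c(out_target, rep(cl, need))
  }
  rownames(out) <- NULL
  list(data = out, target = factor(out_target, levels = levels(target)))
}
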