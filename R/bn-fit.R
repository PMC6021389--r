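#' Fit conditional probability tables on a DAG
#'
#' Maximum-likelihood multinomial estimates with optional additive
#' (Laplace) smoothing: each CPT row is `(count + s) / (N_j + r s)`.
#' Parent configurations never observed receive the uniform row.
#'
#' @param model a `bn_model` (structure), or a bare edge matrix together
#'   with `data` supplying the node universe.
#' @param data complete data.frame of factors.
#' @param smoothing non-negative additive pseudo-count (default 0).
#' @return the `bn_model` with `cpts` filled: one array per node, first
#'   dimension the node's states, remaining dimensions its parents' states
#'   (dimension names carry the variable names).
#' @export
fit_cpts <- function(model, data, smoothing = 0) {
  if (!inherits(model, "bn_model")) {
    model <- structure(list(nodes = lapply(data, levels),
                            edges = as_edge_matrix(model), cpts = NULL,
                            score_used = NA_character_,
                            score_value = NA_real_),
                       class = "bn_model")
  }
  model$edges <- as_edge_matrix(model$edges)
  nodes <- names(model$nodes)
  if (!is_acyclic(nodes, model$edges))
    stop_adbn("adbn_graph_error", "structure is cyclic")
  model$cpts <- lapply(nodes, function(v) {
    parents <- parents_of(model$edges, v)
    fc <- family_counts(v, parents, data)
    probs <- fc$counts + smoothing
    tot <- colSums(probs)
    empty <- tot == 0
    if (any(empty)) {                 # unseen parent configuration: uniform
      probs[, empty] <- 1
      tot[empty] <- fc$r
    }
    probs <- sweep(probs, 2L, tot, "/")
    dn <- c(list(model$nodes[[v]]),
            lapply(parents, function(p) model$nodes[[p]]))
    names(dn) <- c(v, parents)
    array(probs, dim = c(fc$r, fc$dims), dimnames = dn)
  })
  names(model$cpts) <- nodes
  model$smoothing <- smoothing
  model
}

# linear CPT lookup of P(node = value | parents = values) for every record
cpt_lookup <- function(model, node, data) {
  cpt <- model$cpts[[node]]
  vars <- names(dimnames(cpt))
  parents <- vars[-1]
  r <- dim(cpt)[1]
  idx <- as.integer(factor(as.character(data[[node]]),
                           levels = model$nodes[[node]]))
  if (length(parents)) {
    mult <- r
    for (p in parents) {
      pi <- as.integer(factor(as.character(data[[p]]), levels = model$nodes[[p]]))
      idx <- idx + (pi - 1L) * mult
      mult <- mult * length(model$nodes[[p]])
    }
  }
  as.vector(cpt)[idx]
}

#' Negative mean log-likelihood of data under a fitted network
#'
#' The joint probability of each record factorizes over the network's
#' families; the loss is the negative mean log joint probability (natural
#' log).  A record with zero probability (possible with smoothing 0) makes
#' the loss infinite, with a warning.
#'
#' @param model a fitted `bn_model`.
#' @param data data.frame of factors over the model's nodes.
#' @return non-negative real (possibly `Inf`).
#' @export
loglik_loss <- function(model, data) {
  if (is.null(model$cpts))
    stop_adbn("adbn_input_error", "model has no fitted CPTs")
  lp <- rep(0, nrow(data))
  for (v in names(model$nodes)) lp <- lp + log(cpt_lookup(model, v, data))
  if (any(!is.finite(lp))) {
    warning("zero-probability record(s); log-likelihood loss is infinite",
            call. = FALSE)
    return(Inf)
  }
  -mean(lp)
}

#' Choose the structure score by cross-validated log-likelihood loss
#'
#' For each candidate scoring function, a k-fold cross-validation learns the
#' structure and CPTs on the training folds and measures the log-likelihood
#' loss on the held-out fold; the function with the smallest mean loss wins
#' (ties resolve in the order k2, bde, mbde, bic).
#'
#' @param data complete data.frame of factors.
#' @param constraints a [structure_constraints()].
#' @param folds number of CV folds.
#' @param seed integer seed (controls fold assignment only).
#' @param ess equivalent sample size for the Dirichlet scores.
#' @param smoothing CPT smoothing used when measuring validation loss
#'   (default 1, so losses stay finite).
#' @return list with `losses` (named mean losses) and `chosen`.
#' @export
select_scoring_function <- function(data, constraints = structure_constraints(),
                                    folds = 10L, seed = 1L, ess = 10,
                                    smoothing = 1) {
  scores <- c("k2", "bde", "mbde", "bic")
  fold_id <- kfold_indices(nrow(data), folds, substream_seed(seed, "score_cv"))
  losses <- sapply(scores, function(sc) {
    per_fold <- vapply(seq_len(folds), function(k) {
      train <- data[fold_id != k, , drop = FALSE]
      valid <- data[fold_id == k, , drop = FALSE]
      m <- hill_climb(train, constraints, score = sc, ess = ess)
      m <- fit_cpts(m, train, smoothing = smoothing)
      loglik_loss(m, valid)
    }, numeric(1))
    mean(per_fold)
  })
  list(losses = losses, chosen = scores[which.min(losses)])
}

#' Arc strength of a learned network
#'
#' Three notions of the strength of each arc:
#' * `score_delta` — the drop in network score when the arc is removed
#'   (larger is stronger; no p-value).
#' * `ci_test` — a G-squared conditional-independence test of the child
#'   against the parent given the child's other parents; the p-value
#'   quantifies the arc (smaller is stronger).
#' * `bootstrap` — the fraction of nonparametric bootstrap relearns (same
#'   constraints and score) whose structure contains the arc.
#'
#' @param model a learned `bn_model`.
#' @param data the learning data.
#' @param method `"score_delta"`, `"ci_test"` or `"bootstrap"`.
#' @param replicates bootstrap replicate count.
#' @param seed integer seed (bootstrap only).
#' @param constraints constraints used for bootstrap relearning.
#' @return data.frame with columns `from`, `to`, `strength`, `p_value`.
#' @export
arc_strength <- function(model, data, method = "ci_test", replicates = 100L,
                         seed = 1L, constraints = structure_constraints()) {
  edges <- as_edge_matrix(model$edges)
  if (!method %in% c("score_delta", "ci_test", "bootstrap"))
    stop_adbn("adbn_input_error", "unknown arc-strength method '%s'", method)
  if (!nrow(edges))
    return(data.frame(from = character(), to = character(),
                      strength = numeric(), p_value = numeric()))
  if (method == "bootstrap") {
    hits <- matrix(0, nrow(edges), 1)
    set.seed(substream_seed(seed, "arc_bootstrap"))
    for (b in seq_len(replicates)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      m <- hill_climb(data[idx, , drop = FALSE], constraints,
                      score = model$score_used %||% "bic",
                      ess = model$ess %||% 10)
      for (e in seq_len(nrow(edges)))
        if (has_edge(m$edges, edges[e, "from"], edges[e, "to"]))
          hits[e] <- hits[e] + 1
    }
    return(data.frame(from = edges[, "from"], to = edges[, "to"],
                      strength = as.vector(hits) / replicates,
                      p_value = NA_real_))
  }
  res <- lapply(seq_len(nrow(edges)), function(e) {
    u <- edges[e, "from"]; v <- edges[e, "to"]
    others <- setdiff(parents_of(edges, v), u)
    if (method == "score_delta") {
      sc <- model$score_used %||% "bic"
      delta <- family_score(v, parents_of(edges, v), data, sc, model$ess %||% 10) -
        family_score(v, others, data, sc, model$ess %||% 10)
      data.frame(from = u, to = v, strength = delta, p_value = NA_real_)
    } else {
      g2 <- g2_test(data[[v]], data[[u]],
                    if (length(others)) data[others] else NULL)
      data.frame(from = u, to = v, strength = g2$statistic,
                 p_value = g2$p_value)
    }
  })
  do.call(rbind, res)
}

# G-squared conditional independence test of x against y given the columns
# of z (NULL for a marginal test); asymptotic chi-squared reference
g2_test <- function(x, y, z = NULL) {
  x <- factor(x); y <- factor(y)
  if (is.null(z) || !length(z)) {
    strata <- factor(rep(1, length(x)))
  } else {
    strata <- interaction(z, drop = TRUE)
  }
  g2 <- 0
  for (s in levels(strata)) {
    sel <- strata == s
    tab <- table(x[sel], y[sel])
    n <- sum(tab)
    if (n == 0) next
    expct <- outer(rowSums(tab), colSums(tab)) / n
    pos <- tab > 0
    g2 <- g2 + 2 * sum(tab[pos] * log(tab[pos] / expct[pos]))
  }
  df <- (nlevels(x) - 1) * (nlevels(y) - 1) * nlevels(strata)
  list(statistic = g2, df = df,
       p_value = stats::pchisq(g2, df, lower.tail = FALSE))
}
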