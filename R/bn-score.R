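# ---- counting helpers -------------------------------------------------------

# Contingency counts of a node against its parent configurations.
# Columns enumerate parent configurations with the FIRST parent varying
# fastest, matching R's column-major array layout used for CPTs.
family_counts <- function(node, parents, data) {
  child <- data[[node]]
  r <- nlevels(child)
  if (!length(parents)) {
    cnt <- tabulate(as.integer(child), nbins = r)
    return(list(counts = matrix(cnt, nrow = r), r = r, q = 1L, dims = integer()))
  }
  dims <- vapply(parents, function(p) nlevels(data[[p]]), integer(1))
  idx <- as.integer(data[[parents[1]]])
  mult <- dims[1]
  for (p in parents[-1]) {
    idx <- idx + (as.integer(data[[p]]) - 1L) * mult
    mult <- mult * nlevels(data[[p]])
  }
  q <- as.integer(prod(dims))
  cnt <- tabulate((idx - 1L) * r + as.integer(child), nbins = r * q)
  list(counts = matrix(cnt, nrow = r, ncol = q), r = r, q = q, dims = dims)
}

#' Decomposable family score of a node given a parent set
#'
#' Log-space local scores for discrete Bayesian-network structure learning:
#' * `k2` — Cooper-Herskovits marginal likelihood with an all-ones Dirichlet
#'   prior.
#' * `bde` — Bayesian Dirichlet equivalent (BDeu): an equivalent sample size
#'   `ess` spread uniformly over the family's joint configurations.
#' * `mbde` — a BDe variant whose per-parent-row prior mass is proportional
#'   to the observed parent-configuration frequency, `ess * N_j / N`,
#'   divided uniformly over the child's states (an interpretation; rows
#'   never observed carry no prior mass and contribute nothing).
#' * `bic` — maximized multinomial log-likelihood minus
#'   `(d / 2) log N` with `d = (r - 1) q` free parameters.
#'
#' Natural logarithms throughout.
#'
#' @param node column name of the child variable.
#' @param parents character vector of parent column names (may be empty).
#' @param data complete data.frame of factors.
#' @param score one of `"k2"`, `"bde"`, `"mbde"`, `"bic"`.
#' @param ess equivalent sample size for `bde` / `mbde` (positive).
#' @return the log family score.
#' @export
family_score <- function(node, parents, data, score = "bic", ess = 10) {
  if (!score %in% c("k2", "bde", "mbde", "bic"))
    stop_adbn("adbn_input_error", "unknown score '%s'", score)
  if (score %in% c("bde", "mbde") && ess <= 0)
    stop_adbn("adbn_input_error", "ess must be positive for %s", score)
  if (node %in% parents)
    stop_adbn("adbn_input_error", "node cannot be its own parent")
  fc <- family_counts(node, parents, data)
  counts <- fc$counts; r <- fc$r; q <- fc$q
  Nj <- colSums(counts)
  N <- sum(Nj)
  switch(score,
    k2 = sum(lgamma(r) - lgamma(Nj + r)) + sum(lgamma(counts + 1)),
    bde = {
      a_jk <- ess / (r * q); a_j <- ess / q
      sum(lgamma(a_j) - lgamma(a_j + Nj)) +
        sum(lgamma(a_jk + counts) - lgamma(a_jk))
    },
    mbde = {
      keep <- Nj > 0
      a_j <- ess * Nj[keep] / N
      a_jk <- matrix(rep(a_j / r, each = r), nrow = r)
      sum(lgamma(a_j) - lgamma(a_j + Nj[keep])) +
        sum(lgamma(a_jk + counts[, keep, drop = FALSE]) - lgamma(a_jk))
    },
    bic = {
      pos <- counts > 0
      ll <- sum(counts[pos] * log(counts[pos] / rep(Nj, each = r)[pos]))
      ll - 0.5 * (r - 1) * q * log(N)
    })
}

#' Total network score of a DAG (sum of family scores)
#'
#' @param edges two-column character matrix (`from`, `to`); may have zero
#'   rows.
#' @param data complete data.frame of factors over the network's nodes.
#' @inheritParams family_score
#' @return the log network score.
#' @export
network_score <- function(edges, data, score = "bic", ess = 10) {
  nodes <- names(data)
  edges <- as_edge_matrix(edges)
  if (!is_acyclic(nodes, edges))
    stop_adbn("adbn_graph_error", "edge set contains a cycle")
  sum(vapply(nodes, function(v) {
    family_score(v, parents_of(edges, v), data, score, ess)
  }, numeric(1)))
}

# ---- graph utilities --------------------------------------------------------

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) || !length(edges))
    return(matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  m <- matrix(as.character(edges), ncol = 2)
  colnames(m) <- c("from", "to")
  m
}

parents_of <- function(edges, node) {
  edges[edges[, "to"] == node, "from"]
}

has_edge <- function(edges, u, v) {
  any(edges[, "from"] == u & edges[, "to"] == v)
}

# TRUE when a directed path from `from` to `to` exists
reaches <- function(edges, from, to) {
  frontier <- from
  seen <- character()
  while (length(frontier)) {
    if (to %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    nxt <- unique(edges[edges[, "from"] %in% frontier, "to"])
    frontier <- setdiff(nxt, seen)
  }
  FALSE
}

is_acyclic <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in edges[, "to"]) indeg[v] <- indeg[v] + 1
  queue <- names(indeg)[indeg == 0]
  removed <- 0L
  active <- rep(TRUE, nrow(edges))
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    out <- which(active & edges[, "from"] == u)
    for (e in out) {
      active[e] <- FALSE
      v <- edges[e, "to"]
      indeg[v] <- indeg[v] - 1
      if (indeg[v] == 0) queue <- c(queue, v)
    }
  }
  removed == length(nodes)
}

topological_order <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  order <- character()
  indeg <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in edges[, "to"]) indeg[v] <- indeg[v] + 1
  active <- rep(TRUE, nrow(edges))
  queue <- names(indeg)[indeg == 0]
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    order <- c(order, u)
    out <- which(active & edges[, "from"] == u)
    for (e in out) {
      active[e] <- FALSE
      v <- edges[e, "to"]
      indeg[v] <- indeg[v] - 1
      if (indeg[v] == 0) queue <- c(queue, v)
    }
  }
  if (length(order) != length(nodes))
    stop_adbn("adbn_graph_error", "graph is cyclic; no topological order")
  order
}
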