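#' Structural constraints for network learning
#'
#' Encodes prior clinical knowledge: arcs that must appear, arcs that must
#' not, and an ordering of variable blocks (tiers) such that arcs may only
#' point from an earlier or the same block towards a later block.
#'
#' @param required,forbidden two-column matrices (or vectors coercible to
#'   them) of directed arcs.
#' @param tiers list of character vectors: variable blocks in causal order;
#'   variables not listed are unconstrained by tiers.
#' @return an object of class `structure_constraints`.
#' @export
structure_constraints <- function(required = NULL, forbidden = NULL,
                                  tiers = NULL) {
  required <- as_edge_matrix(required)
  forbidden <- as_edge_matrix(forbidden)
  if (nrow(required) && nrow(forbidden)) {
    key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
    if (length(intersect(key(required), key(forbidden))))
      stop_adbn("adbn_constraint_error", "required and forbidden arcs overlap")
  }
  obj <- structure(list(required = required, forbidden = forbidden,
                        tiers = tiers),
                   class = "structure_constraints")
  if (nrow(required)) {
    nodes <- unique(c(required))
    if (!is_acyclic(nodes, required))
      stop_adbn("adbn_constraint_error", "required arcs contain a cycle")
    bad <- !apply(required, 1L, function(e) tier_allows(obj, e[1], e[2]))
    if (any(bad))
      stop_adbn("adbn_constraint_error", "required arc(s) violate the tier order")
  }
  obj
}

tier_of <- function(constraints, node) {
  if (is.null(constraints$tiers)) return(NA_integer_)
  for (i in seq_along(constraints$tiers))
    if (node %in% constraints$tiers[[i]]) return(i)
  NA_integer_
}

tier_allows <- function(constraints, u, v) {
  tu <- tier_of(constraints, u); tv <- tier_of(constraints, v)
  is.na(tu) || is.na(tv) || tu <= tv
}

edge_legal <- function(constraints, u, v) {
  if (nrow(constraints$forbidden) && has_edge(constraints$forbidden, u, v))
    return(FALSE)
  tier_allows(constraints, u, v)
}

#' Default tier constraints for severity modelling
#'
#' Predisposing indicators (age, ApoE) may influence imaging biomarkers
#' (GM, CSF, PiB-PET), which may influence the severity target (CDR), which
#' in turn may influence the psychological/functional assessments (MMSE,
#' LMIR, LMDR).  Arcs within a block are allowed; arcs against the block
#' order are not.  Features outside the four blocks are placed in the
#' biomarker block.
#'
#' @param features the node set the constraints must cover.
#' @return a [structure_constraints()] object.
#' @export
default_constraints <- function(features) {
  blocks <- list(c("age", "ApoE"),
                 c("GM", "WM", "CSF", "PiB_PET"),
                 "CDR",
                 c("MMSE", "LMIR", "LMDR"))
  extra <- setdiff(features, unlist(blocks))
  blocks[[2]] <- c(blocks[[2]], extra)
  blocks <- lapply(blocks, function(b) b[b %in% features])
  structure_constraints(tiers = blocks)
}

#' Constrained hill-climbing structure search
#'
#' Greedy local search over single-arc additions, deletions and reversals,
#' starting from the graph of required arcs.  Every move must keep the graph
#' acyclic, respect forbidden arcs and the tier order, and never delete a
#' required arc.  At each iteration the move with the largest strictly
#' positive score gain is applied (ties resolve to the first move in a fixed
#' deterministic enumeration: additions, then deletions, then reversals, in
#' node order), so the score trajectory is non-decreasing.  Family scores
#' are cached so that only the families changed by a move are re-scored.
#'
#' @param data complete data.frame of factors (the node universe).
#' @param constraints a [structure_constraints()] object.
#' @inheritParams family_score
#' @param max_iter iteration cap.
#' @param seed integer seed (reserved for optional random restarts; the
#'   default search is deterministic and does not consume randomness).
#' @param restarts number of random-restart repetitions (default 0).
#' @return a `bn_model` with `nodes`, `edges`, `score_used`, `score_value`,
#'   the per-iteration `trajectory`, and bookkeeping attributes
#'   `n_family_evals` (family scores actually computed) and `n_moves`.
#' @export
hill_climb <- function(data, constraints = structure_constraints(),
                       score = "bic", ess = 10, max_iter = 100L, seed = 1L,
                       restarts = 0L) {
  nodes <- names(data)
  req <- constraints$required
  if (nrow(req)) {
    bad <- !apply(req, 1L, function(e) all(e %in% nodes))
    if (any(bad))
      stop_adbn("adbn_constraint_error", "required arc over unknown node")
  }
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fam <- function(v, parents) {
    key <- paste(v, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_evals <<- n_evals + 1L
    cache[[key]] <- family_score(v, parents, data, score, ess)
  }

  run_once <- function(edges) {
    fam_scores <- vapply(nodes, function(v) fam(v, parents_of(edges, v)),
                         numeric(1))
    trajectory <- sum(fam_scores)
    n_moves <- 0L
    tol <- 1e-9
    repeat {
      if (n_moves >= max_iter) break
      best <- NULL; best_gain <- tol
      # additions
      for (u in nodes) for (v in nodes) {
        if (u == v || has_edge(edges, u, v) || has_edge(edges, v, u)) next
        if (!edge_legal(constraints, u, v)) next
        if (reaches(edges, v, u)) next
        g <- fam(v, c(parents_of(edges, v), u)) - fam_scores[v]
        if (g > best_gain) { best_gain <- g; best <- list(op = "add", u = u, v = v) }
      }
      # deletions
      if (nrow(edges)) for (e in seq_len(nrow(edges))) {
        u <- edges[e, "from"]; v <- edges[e, "to"]
        if (nrow(req) && has_edge(req, u, v)) next
        g <- fam(v, setdiff(parents_of(edges, v), u)) - fam_scores[v]
        if (g > best_gain) { best_gain <- g; best <- list(op = "del", u = u, v = v) }
      }
      # reversals
      if (nrow(edges)) for (e in seq_len(nrow(edges))) {
        u <- edges[e, "from"]; v <- edges[e, "to"]
        if (nrow(req) && has_edge(req, u, v)) next
        if (!edge_legal(constraints, v, u)) next
        without <- edges[-e, , drop = FALSE]
        if (reaches(without, u, v)) next
        g <- (fam(u, c(parents_of(edges, u), v)) - fam_scores[u]) +
          (fam(v, setdiff(parents_of(edges, v), u)) - fam_scores[v])
        if (g > best_gain) { best_gain <- g; best <- list(op = "rev", u = u, v = v) }
      }
      if (is.null(best)) break
      edges <- switch(best$op,
        add = rbind(edges, c(best$u, best$v)),
        del = edges[!(edges[, "from"] == best$u & edges[, "to"] == best$v), ,
                    drop = FALSE],
        rev = rbind(edges[!(edges[, "from"] == best$u & edges[, "to"] == best$v), ,
                          drop = FALSE],
                    c(best$v, best$u)))
      colnames(edges) <- c("from", "to")
      for (w in unique(c(best$u, best$v)))
        fam_scores[w] <- fam(w, parents_of(edges, w))
      n_moves <- n_moves + 1L
      trajectory <- c(trajectory, sum(fam_scores))
    }
    list(edges = edges, score = sum(fam_scores), trajectory = trajectory,
         n_moves = n_moves)
  }

  best_run <- run_once(req)
  if (restarts > 0L) {
    set.seed(substream_seed(seed, "hill_climb_restarts"))
    legal <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    legal <- legal[legal$from != legal$to, ]
    legal <- legal[mapply(function(u, v) edge_legal(constraints, u, v),
                          legal$from, legal$to), ]
    for (i in seq_len(restarts)) {
      start <- req
      cand <- legal[sample.int(nrow(legal), min(length(nodes), nrow(legal))), ]
      for (j in seq_len(nrow(cand))) {
        u <- cand$from[j]; v <- cand$to[j]
        if (!has_edge(start, u, v) && !has_edge(start, v, u) &&
            !reaches(start, v, u)) {
          start <- rbind(start, c(u, v)); colnames(start) <- c("from", "to")
        }
      }
      run <- run_once(start)
      if (run$score > best_run$score) best_run <- run
    }
  }

  model <- structure(list(
    nodes = lapply(data, levels),
    edges = best_run$edges,
    cpts = NULL,
    score_used = score,
    score_value = best_run$score,
    ess = ess,
    trajectory = best_run$trajectory),
    class = "bn_model")
  attr(model, "n_family_evals") <- n_evals
  attr(model, "n_moves") <- best_run$n_moves
  model
}

#' Structural diff between two networks
#'
#' @param model_a,model_b `bn_model` objects (or bare edge matrices plus a
#'   node set).
#' @return list with `added`, `removed`, `reversed` edge matrices (an edge
#'   reversed between the models is reported once, as reversed) and
#'   `node_diff`, the symmetric difference of the node sets.
#' @export
compare_networks <- function(model_a, model_b) {
  ea <- as_edge_matrix(model_a$edges); eb <- as_edge_matrix(model_b$edges)
  key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2], sep = "\r") else character()
  ka <- key(ea); kb <- key(eb)
  rev_b <- key(eb[, c(2, 1), drop = FALSE])
  reversed_idx <- which(!(ka %in% kb) & ka %in% rev_b)
  reversed <- ea[reversed_idx, , drop = FALSE]
  removed <- ea[!(ka %in% kb) & !(ka %in% rev_b), , drop = FALSE]
  rev_a <- key(ea[, c(2, 1), drop = FALSE])
  added <- eb[!(kb %in% ka) & !(kb %in% rev_a), , drop = FALSE]
  list(added = added, removed = removed, reversed = reversed,
       node_diff = c(setdiff(names(model_a$nodes), names(model_b$nodes)),
                     setdiff(names(model_b$nodes), names(model_a$nodes))))
}
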