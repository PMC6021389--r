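# ---- discrete factor algebra for exact inference ---------------------------
# A "factor" here is a potential over a set of discrete variables:
# list(vars = character, levels = named list, values = numeric array laid out
# with vars[1] varying fastest).

mk_factor <- function(vars, levels, values) {
  dims <- vapply(levels, length, integer(1))
  list(vars = vars, levels = levels,
       values = array(values, dim = if (length(dims)) dims else 1L))
}

cpt_factor <- function(model, node) {
  cpt <- model$cpts[[node]]
  vars <- names(dimnames(cpt))
  mk_factor(vars, stats::setNames(dimnames(cpt), vars), as.vector(cpt))
}

# expand a factor's value vector onto a configuration grid over `vars`
expand_values <- function(f, vars, dims) {
  if (!length(f$vars)) return(rep(as.vector(f$values), prod(dims)))
  total <- prod(dims)
  ai <- arrayInd(seq_len(total), .dim = dims)
  cols <- match(f$vars, vars)
  fdims <- vapply(f$levels, length, integer(1))
  lin <- ai[, cols[1]]
  if (length(cols) > 1) {
    mult <- fdims[1]
    for (j in 2:length(cols)) {
      lin <- lin + (ai[, cols[j]] - 1L) * mult
      mult <- mult * fdims[j]
    }
  }
  as.vector(f$values)[lin]
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  levels <- c(f1$levels, f2$levels)[vars]
  dims <- vapply(levels, length, integer(1))
  mk_factor(vars, levels,
            expand_values(f1, vars, dims) * expand_values(f2, vars, dims))
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) {
    return(mk_factor(character(), list(), sum(f$values)))
  }
  pos <- match(var, f$vars)
  perm <- c(setdiff(seq_along(f$vars), pos), pos)
  v <- aperm(f$values, perm)
  dims <- dim(v)
  v <- rowSums(matrix(v, ncol = dims[length(dims)]))
  mk_factor(f$vars[perm[-length(perm)]], f$levels[f$vars[perm[-length(perm)]]], v)
}

factor_restrict <- function(f, var, value) {
  if (!var %in% f$vars) return(f)
  pos <- match(var, f$vars)
  idx <- match(value, f$levels[[var]])
  args <- rep(list(quote(expr = )), length(f$vars))
  args[[pos]] <- idx
  v <- do.call(`[`, c(list(f$values), args, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  newdims <- dim(f$values)[keep]
  mk_factor(f$vars[keep], f$levels[keep],
            array(v, dim = if (length(newdims)) newdims else 1L))
}

#' Exact posterior of a target node by variable elimination
#'
#' Reduces the network's CPTs by the evidence, eliminates every other
#' unobserved variable by sum-product (cheapest-factor-first order,
#' deterministic), and normalizes.  Variables absent from the evidence are
#' marginalized out, so partial evidence is allowed.
#'
#' @param model a fitted `bn_model`.
#' @param evidence named character vector / list of observed states (must
#'   not include the target; unknown names or states are errors).
#' @param target the node whose posterior is required.
#' @return named numeric posterior over the target's states (sums to 1).
#' @export
predict_class <- function(model, evidence, target) {
  if (is.null(model$cpts))
    stop_adbn("adbn_input_error", "model has no fitted CPTs")
  nodes <- names(model$nodes)
  if (!target %in% nodes)
    stop_adbn("adbn_lookup_error", "unknown target '%s'", target)
  evidence <- evidence[!is.na(unlist(evidence))]
  ev_vars <- names(evidence)
  if (target %in% ev_vars)
    stop_adbn("adbn_input_error", "evidence must not include the target")
  bad <- setdiff(ev_vars, nodes)
  if (length(bad))
    stop_adbn("adbn_lookup_error", "unknown evidence node(s): %s",
              paste(bad, collapse = ", "))
  for (v in ev_vars) {
    if (!as.character(evidence[[v]]) %in% model$nodes[[v]])
      stop_adbn("adbn_input_error", "evidence state '%s' not a state of '%s'",
                as.character(evidence[[v]]), v)
  }
  factors <- lapply(nodes, function(v) cpt_factor(model, v))
  for (v in ev_vars) {
    factors <- lapply(factors, factor_restrict, var = v,
                      value = as.character(evidence[[v]]))
  }
  hidden <- setdiff(nodes, c(ev_vars, target))
  for (h in hidden) {
    involved <- vapply(factors, function(f) h %in% f$vars, TRUE)
    if (!any(involved)) next
    merged <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(merged, h)))
  }
  res <- Reduce(factor_product, factors)
  for (v in setdiff(res$vars, target)) res <- factor_marginalize(res, v)
  post <- as.vector(res$values)
  if (length(res$vars)) {
    names(post) <- res$levels[[target]]
  } else {
    # degenerate: target eliminated by evidence restriction cannot happen,
    # but keep a defensive uniform
    post <- rep(1 / length(model$nodes[[target]]), length(model$nodes[[target]]))
    names(post) <- model$nodes[[target]]
  }
  post <- post[model$nodes[[target]]]
  s <- sum(post)
  if (!is.finite(s) || s <= 0)
    stop_adbn("adbn_input_error", "evidence has zero probability under the model")
  post / s
}

#' Posterior of a target for every row of a data table
#'
#' Vectorized wrapper around [predict_class()]: rows sharing the same
#' evidence configuration (including missingness pattern) are solved once.
#'
#' @param model a fitted `bn_model`.
#' @param data data.frame whose columns matching model nodes (other than
#'   the target) serve as evidence; missing cells are marginalized.
#' @param target the node to predict.
#' @return matrix of posteriors, one row per record, columns the target's
#'   states.
#' @export
predict_table <- function(model, data, target) {
  ev_vars <- intersect(setdiff(names(model$nodes), target), names(data))
  states <- model$nodes[[target]]
  if (!length(ev_vars)) {
    post <- predict_class(model, stats::setNames(list(), character()), target)
    return(matrix(post, nrow(data), length(states), byrow = TRUE,
                  dimnames = list(NULL, states)))
  }
  key <- do.call(paste, c(lapply(data[ev_vars], as.character), sep = "\r"))
  uniq <- !duplicated(key)
  out <- matrix(NA_real_, nrow(data), length(states),
                dimnames = list(NULL, states))
  for (i in which(uniq)) {
    ev <- lapply(data[i, ev_vars, drop = FALSE], as.character)
    ev <- ev[!vapply(ev, is.na, TRUE)]
    post <- predict_class(model, ev, target)
    out[key == key[i], ] <- matrix(post, sum(key == key[i]), length(states),
                                   byrow = TRUE)
  }
  out
}

#' Forward (ancestral) sampling from a fitted network
#'
#' Draws n i.i.d. joint samples by sampling each node in topological order
#' from its CPT row given the already-sampled parents.
#'
#' @param model a fitted `bn_model` (valid DAG, normalized CPT rows).
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame of factors, one column per node.
#' @export
sample_from_network <- function(model, n, seed = 1L) {
  if (is.null(model$cpts))
    stop_adbn("adbn_input_error", "model has no fitted CPTs")
  nodes <- names(model$nodes)
  ord <- topological_order(nodes, model$edges)
  set.seed(substream_seed(seed, "sample_from_network"))
  out <- vector("list", length(nodes))
  names(out) <- nodes
  for (v in ord) {
    cpt <- model$cpts[[v]]
    r <- dim(cpt)[1]
    parents <- names(dimnames(cpt))[-1]
    if (!length(parents)) {
      p <- as.vector(cpt)
      draw <- sample.int(r, n, replace = TRUE, prob = p)
    } else {
      cfg <- rep(1L, n); mult <- 1L
      for (pp in parents) {
        cfg <- cfg + (out[[pp]] - 1L) * mult
        mult <- mult * length(model$nodes[[pp]])
      }
      pm <- matrix(as.vector(cpt), nrow = r)     # r x configs
      u <- stats::runif(n)
      cum <- apply(pm, 2L, cumsum)               # r x configs
      draw <- rep(1L, n)
      for (k in seq_len(r - 1L)) {
        draw <- draw + (u > cum[k, cfg])
      }
    }
    out[[v]] <- draw
  }
  as.data.frame(lapply(nodes, function(v) {
    factor(model$nodes[[v]][out[[v]]], levels = model$nodes[[v]])
  }), col.names = nodes)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a network model to JSON / DOT
#'
#' The JSON document carries nodes, state lists, edges, CPT arrays and score
#' metadata; the DOT export is a plain edge list for visualization.
#'
#' @param model a `bn_model`.
#' @param path output file.
#' @return `path`, invisibly (write) or a `bn_model` (read).
#' @export
write_bn_json <- function(model, path) {
  doc <- list(
    nodes = model$nodes,
    edges = as.data.frame(as_edge_matrix(model$edges)),
    cpts = lapply(model$cpts, function(a) {
      list(dim = dim(a), dimnames = dimnames(a), values = as.vector(a))
    }),
    score_used = model$score_used,
    score_value = model$score_value)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(doc$edges))
    as_edge_matrix(cbind(doc$edges$from, doc$edges$to))
  else as_edge_matrix(NULL)
  cpts <- lapply(doc$cpts, function(c0) {
    array(as.numeric(c0$values), dim = as.integer(c0$dim), dimnames = c0$dimnames)
  })
  structure(list(nodes = lapply(doc$nodes, as.character),
                 edges = edges,
                 cpts = if (length(cpts)) cpts else NULL,
                 score_used = doc$score_used, score_value = doc$score_value),
            class = "bn_model")
}

#' @rdname write_bn_json
#' @export
write_bn_dot <- function(model, path) {
  edges <- as_edge_matrix(model$edges)
  lines <- c("digraph bn {",
             sprintf("  \"%s\";", names(model$nodes)),
             if (nrow(edges)) sprintf("  \"%s\" -> \"%s\";",
                                      edges[, "from"], edges[, "to"]),
             "}")
  writeLines(lines, path)
  invisible(path)
}
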