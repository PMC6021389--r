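# shared fixtures and independent oracles, all built in code at test time

# a tiny, fully valid cohort data.frame with k rows
tiny_cohort_df <- function(k = 3L) {
  dict <- default_dictionary()
  df <- data.frame(subject_id = sprintf("S%02d", seq_len(k)),
                   visit = rep("BL", k),
                   diagnosis = rep(c("HC", "MCI", "AD"), length.out = k),
                   stringsAsFactors = FALSE)
  for (spec in dict) {
    df[[spec$name]] <- switch(spec$kind,
      continuous = round(seq(10, 20, length.out = k), 3),
      ordinal = rep(c(0, 0.5, 1), length.out = k),
      categorical = rep(spec$categories[1:2], length.out = k))
  }
  df$CDR <- rep(c(0, 0.5, 1), length.out = k)
  df
}

# independent brute-force binning: right-closed intervals with infinite bounds
oracle_bin <- function(values, boundaries) {
  vapply(values, function(v) {
    b <- 1L
    for (cut in boundaries) if (v > cut) b <- b + 1L
    b
  }, integer(1))
}

# exhaustive search for the best single CAIM boundary
oracle_best_single_cut <- function(values, classes) {
  distinct <- sort(unique(values))
  cands <- (distinct[-1] + distinct[-length(distinct)]) / 2
  scores <- vapply(cands, function(b) {
    caim_score(build_quanta_matrix(values, classes, b))
  }, numeric(1))
  list(cut = cands[which.max(scores)], score = max(scores))
}

# random discrete Bayesian network with dirichlet-ish CPTs
random_bn <- function(n_nodes, max_states = 3L, edge_prob = 0.35, seed = 1L) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  states <- lapply(nodes, function(v) {
    paste0(v, "_s", seq_len(sample(2:max_states, 1)))
  })
  names(states) <- nodes
  edges <- NULL
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i < j && stats::runif(1) < edge_prob) edges <- rbind(edges, c(nodes[i], nodes[j]))
  }
  edges <- adbn:::as_edge_matrix(edges)
  cpts <- lapply(nodes, function(v) {
    parents <- adbn:::parents_of(edges, v)
    r <- length(states[[v]])
    dims <- vapply(parents, function(p) length(states[[p]]), integer(1))
    q <- prod(c(1, dims))
    m <- matrix(stats::rgamma(r * q, shape = 1) + 0.05, nrow = r)
    m <- sweep(m, 2L, colSums(m), "/")
    dn <- c(stats::setNames(list(states[[v]]), v),
            stats::setNames(lapply(parents, function(p) states[[p]]), parents))
    array(m, dim = c(r, dims), dimnames = dn)
  })
  names(cpts) <- nodes
  structure(list(nodes = states, edges = edges, cpts = cpts,
                 score_used = "random", score_value = NA_real_),
            class = "bn_model")
}

# independent inference oracle: full-joint enumeration over all assignments
oracle_posterior <- function(model, evidence, target) {
  nodes <- names(model$nodes)
  grid <- expand.grid(model$nodes, stringsAsFactors = FALSE)
  names(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    cpt <- model$cpts[[v]]
    vars <- names(dimnames(cpt))
    idx <- match(grid[[vars[1]]], model$nodes[[vars[1]]])
    mult <- dim(cpt)[1]
    for (pp in vars[-1]) {
      idx <- idx + (match(grid[[pp]], model$nodes[[pp]]) - 1L) * mult
      mult <- mult * length(model$nodes[[pp]])
    }
    p <- p * as.vector(cpt)[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  post <- tapply(p[keep], factor(grid[[target]][keep],
                                 levels = model$nodes[[target]]), sum)
  post[is.na(post)] <- 0
  post <- as.vector(post) / sum(post)
  stats::setNames(post, model$nodes[[target]])
}

# a strongly dependent two-column discrete table (noisy copy of a)
sim_chain <- function(n, seed, p_flip = 0.1) {
  set.seed(seed)
  a <- sample(c("a1", "a2"), n, TRUE)
  b <- ifelse(stats::runif(n) < p_flip,
              sample(c("b1", "b2"), n, TRUE),
              ifelse(a == "a1", "b1", "b2"))
  data.frame(a = factor(a), b = factor(b))
}

# the eight severity-linked features of the generator
signal_features <- function() {
  c("age", "ApoE", "GM", "CSF", "PiB_PET", "MMSE", "LMIR", "LMDR")
}

# undirected skeleton keys of an edge matrix
skeleton_keys <- function(edges) {
  if (!nrow(edges)) return(character())
  unique(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}
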