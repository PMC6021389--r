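two_node_chain <- function(pa1 = 0.3, pb1_a1 = 0.9, pb1_a0 = 0.2) {
  nodes <- list(A = c("0", "1"), B = c("0", "1"))
  cpts <- list(
    A = array(c(1 - pa1, pa1), dim = 2,
              dimnames = stats::setNames(list(nodes$A), "A")),
    B = array(c(1 - pb1_a0, pb1_a0, 1 - pb1_a1, pb1_a1), dim = c(2, 2),
              dimnames = stats::setNames(list(nodes$B, nodes$A), c("B", "A"))))
  structure(list(nodes = nodes, edges = rbind(c("A", "B")), cpts = cpts,
                 score_used = "manual", score_value = NA_real_),
            class = "bn_model")
}

test_that("CPT fitting uses smoothed multinomial estimates", {
  d <- data.frame(x = factor(c("T", "T", "F"), levels = c("T", "F")))
  m0 <- fit_cpts(adbn:::as_edge_matrix(NULL), d, smoothing = 0)
  expect_equal(as.vector(m0$cpts$x), c(2 / 3, 1 / 3))
  m1 <- fit_cpts(adbn:::as_edge_matrix(NULL), d, smoothing = 1)
  expect_equal(as.vector(m1$cpts$x), c(3 / 5, 2 / 5))

  # unseen parent configuration falls back to the uniform row
  d2 <- data.frame(p = factor(c("p1", "p1", "p1"), levels = c("p1", "p2")),
                   y = factor(c("y1", "y2", "y1")))
  m2 <- fit_cpts(rbind(c("p", "y")), d2, smoothing = 0)
  expect_equal(as.vector(m2$cpts$y[, 2]), c(0.5, 0.5))
})

test_that("log-likelihood loss matches hand evaluation and is minimized at the MLE", {
  uni <- fit_cpts(adbn:::as_edge_matrix(NULL),
                  data.frame(x = factor(c("a", "b"))), smoothing = 0)
  expect_equal(loglik_loss(uni, data.frame(x = factor(c("a", "b", "a")))),
               log(2))

  # two-node chain on a worked 4-record table
  d <- data.frame(A = factor(c("0", "0", "1", "1")),
                  B = factor(c("0", "1", "1", "1")))
  m <- fit_cpts(rbind(c("A", "B")), d, smoothing = 0)
  # P(records): (.5*.5), (.5*.5), (.5*1), (.5*1)
  expect_equal(loglik_loss(m, d),
               -mean(log(c(0.25, 0.25, 0.5, 0.5))), tolerance = 1e-12)

  # perturbing the fitted CPTs can only increase the training loss
  base <- loglik_loss(m, d)
  for (eps in c(0.05, 0.15)) {
    pert <- m
    v <- as.vector(pert$cpts$B)
    v <- v + c(eps, -eps, -eps, eps)
    v <- pmin(pmax(v, 1e-6), 1 - 1e-6)
    pert$cpts$B <- array(sweep(matrix(v, 2), 2, colSums(matrix(v, 2)), "/"),
                         dim = dim(m$cpts$B), dimnames = dimnames(m$cpts$B))
    expect_gte(loglik_loss(pert, d), base - 1e-12)
  }

  # an impossible record under an unsmoothed model gives infinite loss
  m0 <- fit_cpts(adbn:::as_edge_matrix(NULL),
                 data.frame(x = factor("a", levels = c("a", "b"))),
                 smoothing = 0)
  expect_warning(
    loss <- loglik_loss(m0, data.frame(x = factor("b", levels = c("a", "b")))),
    "zero-probability")
  expect_identical(loss, Inf)
})

test_that("variable elimination matches joint enumeration", {
  m <- two_node_chain()
  post <- predict_class(m, c(B = "1"), "A")
  expect_equal(unname(post["1"]), 0.27 / 0.41, tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-9)

  # no evidence: the prior marginal
  prior <- predict_class(m, character(), "B")
  expect_equal(unname(prior["1"]), 0.3 * 0.9 + 0.7 * 0.2, tolerance = 1e-12)

  expect_error(predict_class(m, c(A = "1"), "A"), class = "adbn_input_error")
  expect_error(predict_class(m, c(Z = "1"), "A"), class = "adbn_lookup_error")
  expect_error(predict_class(m, c(B = "9"), "A"), class = "adbn_input_error")

  set.seed(55)
  for (i in 1:25) {
    bn <- random_bn(sample(4:8, 1), max_states = 3L, seed = 100 + i)
    nodes <- names(bn$nodes)
    target <- sample(nodes, 1)
    n_ev <- sample(0:(length(nodes) - 1), 1)
    ev_vars <- sample(setdiff(nodes, target), n_ev)
    ev <- vapply(ev_vars, function(v) sample(bn$nodes[[v]], 1), "")
    post <- predict_class(bn, ev, target)
    oracle <- oracle_posterior(bn, as.list(ev), target)
    expect_equal(post, oracle, tolerance = 1e-10)
  }
})

test_that("posterior prediction over a table marginalizes missing evidence", {
  m <- two_node_chain()
  d <- data.frame(B = factor(c("1", "0", NA), levels = c("0", "1")))
  post <- predict_table(m, d, "A")
  expect_equal(unname(post[1, "1"]), 0.27 / 0.41, tolerance = 1e-12)
  # missing evidence row falls back to the prior of A
  expect_equal(unname(post[3, "1"]), 0.3, tolerance = 1e-12)
})

test_that("forward sampling reproduces the generating distribution", {
  # single-node fair coin
  coin <- structure(list(
    nodes = list(X = c("h", "t")),
    edges = adbn:::as_edge_matrix(NULL),
    cpts = list(X = array(c(0.5, 0.5), dim = 2,
                          dimnames = list(X = c("h", "t"))))),
    class = "bn_model")
  s <- sample_from_network(coin, 4000, seed = 2)
  expect_lt(abs(mean(s$X == "h") - 0.5), 0.03)

  # one-hot CPTs force a unique assignment
  forced <- two_node_chain(pa1 = 1, pb1_a1 = 1, pb1_a0 = 0)
  sf <- sample_from_network(forced, 50, seed = 3)
  expect_true(all(sf$A == "1" & sf$B == "1"))

  # two-node chain conditional frequencies match the CPT within 0.03
  m <- two_node_chain()
  s2 <- sample_from_network(m, 10000, seed = 4)
  expect_lt(abs(mean(s2$B[s2$A == "1"] == "1") - 0.9), 0.03)
  expect_lt(abs(mean(s2$B[s2$A == "0"] == "1") - 0.2), 0.03)

  # determinism and seed sensitivity
  expect_identical(sample_from_network(m, 100, seed = 9),
                   sample_from_network(m, 100, seed = 9))
  expect_false(identical(sample_from_network(m, 100, seed = 9),
                         sample_from_network(m, 100, seed = 10)))

  cyclic <- m; cyclic$edges <- rbind(c("A", "B"), c("B", "A"))
  expect_error(sample_from_network(cyclic, 10), class = "adbn_graph_error")
})

test_that("score selection by CV loss picks the minimum and is reproducible", {
  net <- default_truth_network()
  d <- sample_from_network(net, 600, seed = 21)[c("CSF", "CDR", "MMSE")]
  sel <- select_scoring_function(d, folds = 5L, seed = 3L)
  expect_equal(sel$losses[[sel$chosen]], min(sel$losses))
  sel2 <- select_scoring_function(d, folds = 5L, seed = 3L)
  expect_identical(sel, sel2)

  # leave-one-out on a 10-record table stays finite with smoothing
  d10 <- d[1:10, ]
  loo <- select_scoring_function(d10, folds = 10L, seed = 1L, smoothing = 1)
  expect_true(all(is.finite(loo$losses)))
  expect_length(loo$losses, 4L)
})

test_that("arc strengths behave for dependent and independent pairs", {
  d <- sim_chain(2000, seed = 61)
  m <- hill_climb(d, score = "bic")
  m <- fit_cpts(m, d, smoothing = 1)
  ci <- arc_strength(m, d, method = "ci_test")
  expect_lt(ci$p_value[1], 1e-3)

  sd <- arc_strength(m, d, method = "score_delta")
  expect_gt(sd$strength[1], 0)
  # removing an arc with positive score delta lowers the network score
  reduced <- m$edges[0, , drop = FALSE]
  expect_lt(network_score(reduced, d, "bic"), network_score(m$edges, d, "bic"))

  # an independent pair forced as a required edge has low bootstrap support
  set.seed(62)
  ind <- data.frame(a = factor(sample(c("a1", "a2"), 300, TRUE)),
                    b = factor(sample(c("b1", "b2"), 300, TRUE)))
  cons <- structure_constraints(required = rbind(c("a", "b")))
  mi <- hill_climb(ind, cons, score = "bic")
  boot <- arc_strength(mi, ind, method = "bootstrap", replicates = 40L,
                       seed = 5L)
  expect_lt(boot$strength[1], 0.3)

  expect_error(arc_strength(m, d, method = "nope"),
               class = "adbn_input_error")
})

test_that("model serialization round-trips JSON and writes DOT", {
  net <- default_truth_network()
  d <- sample_from_network(net, 400, seed = 77)
  m <- fit_cpts(net, d, smoothing = 1)
  jp <- withr::local_tempfile(fileext = ".json")
  write_bn_json(m, jp)
  back <- read_bn_json(jp)
  expect_equal(back$nodes, m$nodes)
  expect_equal(adbn:::as_edge_matrix(back$edges), adbn:::as_edge_matrix(m$edges))
  ev <- c(MMSE = "0-9", GM = "gm3")
  expect_equal(predict_class(back, ev, "CDR"), predict_class(m, ev, "CDR"),
               tolerance = 1e-12)

  dp <- withr::local_tempfile(fileext = ".dot")
  write_bn_dot(m, dp)
  txt <- readLines(dp)
  expect_true(any(grepl("\"CDR\" -> \"MMSE\"", txt)))
})
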