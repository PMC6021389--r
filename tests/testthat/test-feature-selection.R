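test_that("entropy and the three filters reproduce closed-form values", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(shannon_entropy(1.0), 0.0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "adbn_input_error")

  cl <- c("A", "A", "B", "B")
  expect_equal(information_gain(cl, c("x", "x", "y", "y")), 1.0)
  expect_equal(information_gain(cl, c("x", "y", "x", "y")), 0.0)
  ig <- information_gain(c("A", "A", "A", "B"), c("x", "x", "y", "y"))
  expect_equal(ig, -0.75 * log2(0.75) - 0.25 * log2(0.25) + 1 - 1.5,
               tolerance = 1e-12)
  expect_equal(ig, 0.3112781, tolerance = 1e-6)

  expect_equal(gain_ratio(cl, c("x", "x", "y", "y")), 1.0)
  expect_equal(gain_ratio(c("A", "A", "A", "B"), c("x", "x", "y", "y")),
               0.3112781, tolerance = 1e-6)
  expect_error(gain_ratio(cl, rep("x", 4)), class = "adbn_undefined_ratio")

  expect_equal(symmetrical_uncertainty(cl, cl), 1.0)
  expect_equal(symmetrical_uncertainty(cl, c("x", "y", "x", "y")), 0.0)
  expect_equal(symmetrical_uncertainty(c("A", "A", "A", "B"),
                                       c("x", "x", "y", "y")),
               2 * 0.3112781 / (0.8112781 + 1), tolerance = 1e-6)
})

test_that("filter invariants hold on random contingency data", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    cl <- sample(letters[1:3], n, replace = TRUE)
    at <- sample(LETTERS[1:4], n, replace = TRUE)
    ig <- information_gain(cl, at)
    # symmetry and the mutual-information bound
    expect_equal(ig, information_gain(at, cl), tolerance = 1e-12)
    expect_lte(ig, min(adbn:::empirical_entropy(cl),
                       adbn:::empirical_entropy(at)) + 1e-12)
    expect_equal(symmetrical_uncertainty(cl, at),
                 symmetrical_uncertainty(at, cl), tolerance = 1e-12)
    # invariance under category relabeling
    relab <- stats::setNames(sample(LETTERS[1:4]), LETTERS[1:4])[at]
    expect_equal(information_gain(cl, relab), ig, tolerance = 1e-12)
  }
})

test_that("information gain of an independent attribute vanishes with n", {
  set.seed(23)
  igs <- replicate(30, {
    cl <- sample(c("a", "b", "c"), 1e4, replace = TRUE)
    at <- sample(c("x", "y", "z"), 1e4, replace = TRUE)
    information_gain(cl, at)
  })
  expect_lt(mean(igs), 0.01)
})

test_that("cross-validated selection recovers the dependent features", {
  # eight features driven by severity, 24 independent discrete noise columns
  net <- default_truth_network()
  d <- sample_from_network(net, 2000, seed = 31)
  set.seed(31)
  noise <- as.data.frame(lapply(1:24, function(i) {
    factor(sample(paste0("l", 1:sample(2:3, 1)), 2000, replace = TRUE))
  }), col.names = paste0("noise", 1:24))
  data <- cbind(d[signal_features()], noise)
  rep <- select_features(data, d$CDR, folds = 10L, keep = 8L, seed = 5L)
  expect_setequal(rep$final_set, signal_features())
  expect_true(all(rep$selection_frequency[signal_features()] == 100))

  # all-noise universe: within-sample rank stability exists (folds share
  # most rows), but it does not replicate across independent cohorts —
  # no noise feature is selected in both of two unrelated samples
  rep0 <- select_features(noise, d$CDR, folds = 10L, keep = 8L, seed = 5L)
  set.seed(77)
  noise_b <- as.data.frame(lapply(1:24, function(i) {
    factor(sample(paste0("l", 1:sample(2:3, 1)), 2000, replace = TRUE))
  }), col.names = paste0("noise", 1:24))
  cdr_b <- factor(sample(levels(d$CDR), 2000, TRUE, prob = c(0.6, 0.3, 0.1)))
  rep0b <- select_features(noise_b, cdr_b, folds = 10L, keep = 8L, seed = 5L)
  expect_length(intersect(rep0$final_set, rep0b$final_set), 0L)
  # and no noise feature ever enters the final set alongside real signal
  expect_length(setdiff(rep$final_set, signal_features()), 0L)

  # frequency arithmetic with two folds
  tiny <- data.frame(f1 = factor(c("a", "b", "a", "b")),
                     f2 = factor(c("a", "a", "b", "b")))
  rep2 <- select_features(tiny, factor(c("x", "x", "y", "y")),
                          folds = 2L, keep = 1L, seed = 1L)
  expect_true(all(rep2$selection_frequency %in% c(0, 50, 100)))

  expect_error(select_features(tiny, factor(c("x", "x", "y", "y")),
                               folds = 2L, keep = 5L),
               class = "adbn_input_error")

  # deterministic given the seed
  rep3 <- select_features(data, d$CDR, folds = 10L, keep = 8L, seed = 5L)
  expect_identical(rep3$selection_frequency, rep$selection_frequency)
})

test_that("correlation filtering reports Pearson and Spearman variants", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_filter(x, x)$pearson$r, 1.0)
  expect_equal(correlation_filter(x, rev(x))$pearson$r, -1.0)
  # rank differences (-1, 1, -1, 1, 0): rho = 1 - 6*4 / (5*24) = 0.8
  sp <- correlation_filter(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$spearman
  expect_equal(sp$rho, 0.8, tolerance = 1e-9)
})
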