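test_that("hold-out splits are exhaustive, stratified and reproducible", {
  d <- data.frame(id = 1:100, g = rep(c("a", "b"), c(90, 10)))
  sp <- holdout_split(d, 0.1, seed = 3L)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(sort(c(sp$test$id, sp$development$id)), 1:100)

  st <- holdout_split(d, 0.1, stratify_by = "g", seed = 3L)
  expect_equal(unname(table(st$test$g)), c(9L, 1L), ignore_attr = TRUE)

  expect_identical(holdout_split(d, 0.1, stratify_by = "g", seed = 3L)$test_rows,
                   st$test_rows)
  expect_error(holdout_split(d, 1.2, seed = 1L), class = "adbn_input_error")
  tiny <- data.frame(g = c("a", "a", "b"))
  expect_error(holdout_split(tiny, 0.3, stratify_by = "g", seed = 1L),
               "b", class = "adbn_stratification_error")
})

test_that("k-fold assignments partition the records evenly", {
  f10 <- kfold_indices(10, 10, seed = 1L)
  expect_equal(sort(unique(f10)), 1:10)
  expect_true(all(table(f10) == 1))
  f3 <- kfold_indices(10, 3, seed = 1L)
  expect_equal(sort(as.integer(table(f3)), decreasing = TRUE), c(4L, 3L, 3L))
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:60, 1); k <- sample(2:n, 1)
    f <- kfold_indices(n, k, seed = i)
    expect_length(f, n)
    expect_true(all(abs(diff(range(table(factor(f, levels = 1:k))))) <= 1))
  }
  expect_error(kfold_indices(3, 5), class = "adbn_input_error")
})

test_that("multi-class accuracy carries a Clopper-Pearson interval", {
  acc <- multiclass_accuracy(c(rep("a", 7), rep("b", 3)),
                             c(rep("a", 7), rep("a", 3)))
  expect_equal(acc$mca, 0.7)
  expect_equal(acc$ci, c(0.3475471, 0.9332605), tolerance = 1e-4)
  all20 <- multiclass_accuracy(rep("a", 20), rep("a", 20))
  expect_equal(all20$mca, 1.0)
  expect_equal(all20$ci[2], 1.0)
  expect_true(acc$ci[1] <= acc$mca && acc$mca <= acc$ci[2])
  expect_error(multiclass_accuracy(character(), character()),
               class = "adbn_input_error")
})

test_that("Clopper-Pearson coverage holds in simulation", {
  set.seed(99)
  x <- stats::rbinom(2000, 50, 0.7)
  cover <- vapply(x, function(k) {
    ci <- stats::binom.test(k, 50)$conf.int
    ci[1] <= 0.7 && 0.7 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.93)
})

test_that("multi-class AUC equals brute-force concordance counting", {
  truth <- c("a", "a", "b", "b", "c", "c")
  perfect <- rbind(c(.8, .1, .1), c(.7, .2, .1), c(.1, .8, .1),
                   c(.2, .7, .1), c(.1, .1, .8), c(.2, .1, .7))
  colnames(perfect) <- c("a", "b", "c")
  expect_equal(multiclass_auc(truth, perfect), 1.0)

  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(multiclass_auc(truth, flat), 0.5)

  set.seed(13)
  post <- matrix(stats::rgamma(18, 1), 6, 3)
  post <- sweep(post, 1, rowSums(post), "/")
  colnames(post) <- c("a", "b", "c")
  # oracle: mean over classes of pairwise concordance with midrank ties
  oracle <- mean(vapply(c("a", "b", "c"), function(cl) {
    pos <- which(truth == cl); neg <- which(truth != cl)
    conc <- 0
    for (i in pos) for (j in neg) {
      conc <- conc + (post[i, cl] > post[j, cl]) + 0.5 * (post[i, cl] == post[j, cl])
    }
    conc / (length(pos) * length(neg))
  }, numeric(1)))
  expect_equal(multiclass_auc(truth, post), oracle, tolerance = 1e-12)

  # binary case reduces to the Mann-Whitney statistic
  bt <- c("a", "a", "a", "b", "b")
  bp <- cbind(a = c(.9, .6, .4, .35, .2), b = c(.1, .4, .6, .65, .8))
  u <- mean(outer(bp[bt == "a", "a"], bp[bt == "b", "a"],
                  function(x, y) (x > y) + 0.5 * (x == y)))
  expect_equal(multiclass_auc(bt, bp), u, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    proc_auc <- as.numeric(pROC::auc(pROC::roc(bt, bp[, "a"], levels = c("b", "a"),
                                               direction = "<", quiet = TRUE)))
    expect_equal(multiclass_auc(bt, bp), proc_auc, tolerance = 1e-12)
  }

  expect_warning(multiclass_auc(c("a", "a", "b"), flat[1:3, ]), "absent")
  expect_error(multiclass_auc(c("z", "z"), flat[1:2, ]),
               class = "adbn_input_error")
  bad <- flat; bad[1, 1] <- 0.9
  expect_error(multiclass_auc(truth, bad), class = "adbn_input_error")
})

test_that("per-class sensitivity and specificity follow one-vs-rest counting", {
  diagonal <- confusion_matrix(rep(c("a", "b", "c"), 5), rep(c("a", "b", "c"), 5))
  ss <- sensitivity_specificity(diagonal)
  expect_true(all(ss$sensitivity == 1) && all(ss$specificity == 1))

  cm <- structure(rbind(c(8L, 2L), c(3L, 7L)), class = "confusion_matrix",
                  dimnames = list(c("pos", "neg"), c("pos", "neg")))
  ss2 <- sensitivity_specificity(cm)
  expect_equal(ss2$sensitivity[1], 0.8)
  expect_equal(ss2$specificity[1], 0.7)

  zero <- structure(rbind(c(5L, 0L), c(0L, 0L)), class = "confusion_matrix",
                    dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(sensitivity_specificity(zero)$sensitivity[2]))
})

test_that("Pearson correlation recovers a known latent correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_lt(pearson_correlation(c(1, 2, 3, 4), c(9, 7, 6, 2))$r, 0)
  expect_error(pearson_correlation(x, rep(1, 5)),
               class = "adbn_undefined_correlation")

  set.seed(4)
  z <- stats::rnorm(1473)
  y <- 0.8 * z + sqrt(1 - 0.64) * stats::rnorm(1473)
  est <- pearson_correlation(z, y)
  expect_gt(est$r, 0.76); expect_lt(est$r, 0.84)
  expect_true(est$ci[1] <= est$r && est$r <= est$ci[2])
})

test_that("feature-subset evaluation is comparable and deterministic", {
  net <- default_truth_network()
  d <- sample_from_network(net, 2500, seed = 91)
  subsets <- list(weak = "age",
                  strong = c("GM", "CSF", "PiB_PET", "age", "ApoE",
                             "MMSE", "LMDR"))
  reps <- evaluate_feature_subsets(d, subsets, target = "CDR", seed = 7L)
  expect_gte(reps$strong$auc, reps$weak$auc)
  reps2 <- evaluate_feature_subsets(d, subsets, target = "CDR", seed = 7L)
  expect_equal(reps$strong$auc, reps2$strong$auc)
  expect_equal(reps$weak$confusion, reps2$weak$confusion)
  expect_error(evaluate_feature_subsets(d, list(bad = character())),
               class = "adbn_input_error")
  expect_error(evaluate_feature_subsets(d, list(bad = "no_such")),
               class = "adbn_lookup_error")
})
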