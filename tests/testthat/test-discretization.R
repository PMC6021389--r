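test_that("quanta matrix counts match brute-force binning", {
  q <- build_quanta_matrix(1:6, rep(c("A", "B"), each = 3), 3.5)
  expect_equal(unname(q$counts), rbind(c(3, 0), c(0, 3)))
  expect_equal(q$column_totals, c(`1` = 3, `2` = 3), ignore_attr = TRUE)

  q0 <- build_quanta_matrix(1:6, rep(c("A", "B"), each = 3))
  expect_equal(dim(q0$counts), c(2L, 1L))
  expect_equal(unname(q0$counts[, 1]), c(3, 3))

  set.seed(11)
  values <- stats::runif(30, 0, 10)
  classes <- sample(c("a", "b", "c"), 30, replace = TRUE)
  bounds <- c(3.2, 7.1)
  q2 <- build_quanta_matrix(values, classes, bounds)
  bins <- oracle_bin(values, bounds)
  for (ci in seq_along(q2$class_labels)) for (r in 1:3) {
    expect_equal(q2$counts[ci, r],
                 sum(classes == q2$class_labels[ci] & bins == r),
                 ignore_attr = TRUE)
  }

  expect_error(build_quanta_matrix(1:3, c("A", "B")), class = "adbn_input_error")
  expect_error(build_quanta_matrix(1:3, c("A", "B", "A"), c(2, 2)),
               class = "adbn_input_error")
})

test_that("the CAIM criterion evaluates to its closed forms", {
  expect_equal(caim_score(build_quanta_matrix(1:6, rep(c("A", "B"), each = 3), 3.5)), 3.0)
  expect_equal(caim_score(build_quanta_matrix(1:4, c("A", "B", "A", "B"))), 1.0)
  # middle cut of the alternating pattern: two half-pure intervals
  expect_equal(caim_score(build_quanta_matrix(1:4, c("A", "B", "A", "B"), 2.5)), 0.5)
  # one pure interval of n samples scores n
  expect_equal(caim_score(build_quanta_matrix(1:7, rep("A", 7))), 7)
  # an empty interval is degenerate
  expect_error(caim_score(build_quanta_matrix(1:4, rep("A", 4), 9)),
               class = "adbn_degenerate_error")
})

test_that("CAIM score is invariant to class and interval permutations", {
  set.seed(5)
  for (i in 1:20) {
    values <- sample(1:12, 25, replace = TRUE)
    classes <- sample(c("x", "y", "z"), 25, replace = TRUE)
    bounds <- sort(sample(seq(1.5, 11.5, 1), 2))
    q <- build_quanta_matrix(values, classes, bounds)
    if (any(q$column_totals == 0)) next   # degenerate draw
    s <- caim_score(q)
    relabel <- c(x = "z", y = "x", z = "y")[classes]
    expect_equal(caim_score(build_quanta_matrix(values, relabel, bounds)), s)
    flipped <- caim_score(build_quanta_matrix(-values, classes, sort(-bounds)))
    expect_equal(flipped, s)
  }
})

test_that("greedy CAIM discretization matches the exhaustive single-cut oracle", {
  s <- caim_discretize(1:6, rep(c("A", "B"), each = 3))
  expect_equal(s$cut_points, 3.5)
  expect_equal(s$achieved_caim, 3.0)

  # greedy adds the best available cut (ties toward the smaller one)
  s2 <- caim_discretize(1:4, c("A", "B", "A", "B"))
  expect_length(s2$cut_points, 1L)
  expect_equal(s2$cut_points, 1.5)
  expect_equal(s2$achieved_caim, 7 / 6)

  # forced growth to the class count even when every cut lowers the score:
  # alternating classes over 6 values, no-cut score 1.5, best cut 1.4
  s3 <- caim_discretize(1:6, rep(c("A", "B"), 3))
  expect_length(s3$cut_points, 1L)
  expect_equal(s3$achieved_caim, 1.4)
  expect_lt(s3$achieved_caim, 1.5)

  # class-sorted values with 3 equal classes: three pure intervals
  s4 <- caim_discretize(1:9, rep(c("A", "B", "C"), each = 3))
  expect_length(s4$cut_points, 2L)
  expect_equal(s4$achieved_caim, 3)

  set.seed(99)
  for (i in 1:60) {
    values <- sample(1:12, sample(8:20, 1), replace = TRUE)
    if (length(unique(values)) < 2) next
    classes <- sample(letters[1:sample(2:3, 1)], length(values), replace = TRUE)
    if (length(unique(classes)) < 2) next
    first_cut <- caim_discretize(values, classes, max_intervals = 2L)
    oracle <- oracle_best_single_cut(values, classes)
    expect_equal(first_cut$cut_points, oracle$cut)
    expect_equal(first_cut$achieved_caim, oracle$score)
    # never fewer intervals than min(#classes, #distinct values)
    full <- caim_discretize(values, classes)
    expect_gte(length(full$cut_points) + 1L,
               min(length(unique(classes)), length(unique(values))))
  }

  expect_error(caim_discretize(rep(1, 5), c("A", "B", "A", "B", "A")),
               class = "adbn_degenerate_error")
  expect_error(caim_discretize(1:5, rep("A", 5)),
               class = "adbn_degenerate_error")
})

test_that("fixed clinical schemes encode the conventional categories", {
  cdr <- fixed_scheme("CDR")
  expect_equal(as.character(apply_scheme(0.5, cdr)), "very mild")
  expect_equal(as.character(apply_scheme(2, cdr)), "mild/moderate")
  expect_equal(as.character(apply_scheme(c(0, 1), cdr)),
               c("normal", "mild/moderate"))
  # the severe class is outside the supported range
  expect_error(apply_scheme(3, cdr), class = "adbn_support_error")

  apoe <- fixed_scheme("ApoE")
  expect_equal(match(as.character(apply_scheme("e4e4", apoe)),
                     apoe$interval_labels), 5L)
  expect_length(apoe$interval_labels, 5L)

  mmse <- fixed_scheme("MMSE")
  expect_equal(as.character(apply_scheme(c(30, 22, 15, 4), mmse)),
               c("24-30", "19-23", "10-18", "0-9"))

  expect_error(fixed_scheme("GM"), class = "adbn_lookup_error")
})

test_that("applying a scheme is total, keeps missing, and matches brute force", {
  sch <- caim_discretize(1:9, rep(c("A", "B", "C"), each = 3))
  # a value equal to a cut point falls in the lower interval
  on_cut <- apply_scheme(sch$cut_points[1], sch)
  expect_equal(as.integer(on_cut), 1L)
  expect_true(is.na(apply_scheme(NA_real_, sch)))

  set.seed(3)
  vals <- stats::runif(100, -5, 15)
  codes <- as.integer(apply_scheme(vals, sch))
  expect_equal(codes, oracle_bin(vals, sch$cut_points))

  expect_error(apply_scheme("e9e9", fixed_scheme("ApoE")),
               class = "adbn_support_error")
})

test_that("scheme serialization round-trips", {
  tab <- cohort_table(tiny_cohort_df(12L))
  # give CDR some spread so CAIM has two classes
  schemes <- list(CDR = fixed_scheme("CDR"), MMSE = fixed_scheme("MMSE"),
                  ApoE = fixed_scheme("ApoE"),
                  GM = caim_discretize(1:8, rep(c("A", "B"), 4),
                                       feature = "GM"))
  path <- withr::local_tempfile(fileext = ".json")
  write_schemes(schemes, path)
  back <- read_schemes(path)
  expect_equal(back$GM$cut_points, schemes$GM$cut_points)
  expect_equal(back$CDR$category_map, schemes$CDR$category_map)
  expect_equal(back$MMSE$interval_labels, schemes$MMSE$interval_labels)
  vals <- c(1.2, 4.4, 7.9)
  expect_equal(apply_scheme(vals, back$GM), apply_scheme(vals, schemes$GM))
})
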