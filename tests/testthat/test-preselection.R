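test_that("lasso preselection finds a planted predictive feature", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    X <- matrix(rnorm(n * 10), n, 10)
    y <- rbinom(n, 1, plogis(2 * X[, 4]))
    tab <- feature_table(X, paste0("s", 1:n),
                         paste0("original_firstorder_F", 1:10, "_T1_L1"))
    md <- cohort_metadata(paste0("s", 1:n), rep_len(c("e1", "e2"), n),
                          ifelse(y == 1, "wt", "mut"), "wt")
    sel <- preselect_lasso(tab, md, seed = s)
    hits <- hits + (length(sel$selected) > 0 && sel$selected[1] == 4L)
  }
  expect_gte(hits, 19L)  # planted feature ranked first in >= 95% of runs
})

test_that("lasso preselection handles degenerate inputs", {
  toy <- toy_cohort(n = 80, seed = 2)
  # max_features = 0 truncates to an empty, still-valid result
  sel0 <- preselect_lasso(toy$table, toy$metadata, max_features = 0, seed = 1)
  expect_s3_class(sel0, "selection_result")
  expect_length(sel0$selected, 0)
  # all-constant matrix gives an empty selection with a warning
  const <- feature_table(matrix(1, 40, 3), paste0("s", 1:40),
                         paste0("original_firstorder_C", 1:3, "_T1_L1"))
  mdc <- cohort_metadata(paste0("s", 1:40), rep_len(c("e1", "e2"), 40),
                         rep_len(c("wt", "mut"), 40), "wt")
  expect_warning(selc <- preselect_lasso(const, mdc, seed = 1), "constant")
  expect_length(selc$selected, 0)
})

test_that("lasso selection equals the nonzero support at the chosen penalty", {
  toy <- toy_cohort(n = 150, beta = c(1.5, -1, 0), seed = 3)
  sel <- preselect_lasso(toy$table, toy$metadata, seed = 5)
  expect_identical(sort(sel$selected),
                   sort(unname(which(sel$diagnostics != 0))))
})

test_that("stability frequencies match a direct refit over the same subsamples", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1]))
  tab <- feature_table(X, paste0("s", 1:n),
                       paste0("original_firstorder_F", 1:3, "_T1_L1"))
  md <- cohort_metadata(paste0("s", 1:n), rep_len(c("e1", "e2"), n),
                        ifelse(y == 1, "wt", "mut"), "wt")
  # subsamples drawn here, in the test, and handed to both routes
  subs <- lapply(1:6, function(b) {
    set.seed(100 + b)
    c(sample(which(y == 1), ceiling(sum(y == 1) / 2)),
      sample(which(y == 0), ceiling(sum(y == 0) / 2)))
  })
  grid <- exp(seq(log(0.5), log(0.0005), length.out = 40))
  sel <- preselect_stability(tab, md, penalty_grid = grid,
                             frequency_threshold = 0, subsamples = subs)
  oracle <- rowMeans(vapply(subs, function(ix) {
    fit <- glmnet::glmnet(X[ix, ], y[ix], family = "binomial",
                          lambda = grid, standardize = TRUE)
    apply(as.matrix(fit$beta) != 0, 1, any)
  }, logical(3)))
  expect_equal(unname(sel$diagnostics), unname(oracle))
})

test_that("stability selection respects threshold semantics and monotonicity", {
  set.seed(21)
  n <- 120
  X <- cbind(matrix(rnorm(n * 4), n, 4), 0)  # last feature identically zero
  y <- rbinom(n, 1, plogis(2 * X[, 1] - X[, 2]))
  tab <- feature_table(X, paste0("s", 1:n),
                       paste0("original_firstorder_F", 1:5, "_T1_L1"))
  md <- cohort_metadata(paste0("s", 1:n), rep_len(c("e1", "e2"), n),
                        ifelse(y == 1, "wt", "mut"), "wt")
  sel <- preselect_stability(tab, md, n_subsamples = 30, seed = 3,
                             frequency_threshold = 0)
  expect_true(all(sel$diagnostics >= 0 & sel$diagnostics <= 1))
  expect_equal(unname(sel$diagnostics[5]), 0)  # constant-zero feature never picked
  # raising the threshold never enlarges the selection
  prev <- sel$selected
  for (thr in c(0.3, 0.6, 0.9)) {
    s2 <- preselect_stability(tab, md, n_subsamples = 30, seed = 3,
                              frequency_threshold = thr)
    expect_true(all(s2$selected %in% prev))
    prev <- s2$selected
  }
})

test_that("seeded preselection is deterministic", {
  toy <- toy_cohort(n = 100, seed = 8)
  a <- preselect_lasso(toy$table, toy$metadata, seed = 17)
  b <- preselect_lasso(toy$table, toy$metadata, seed = 17)
  expect_identical(a, b)
  c <- preselect_stability(toy$table, toy$metadata, n_subsamples = 20, seed = 17)
  d <- preselect_stability(toy$table, toy$metadata, n_subsamples = 20, seed = 17)
  expect_identical(c, d)
})
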