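test_that("tuning reaches CV MCC 1 on linearly separable blobs", {
  sep <- separable_cohort(n = 60, seed = 2)
  m <- tune_lambda(sep$table, sep$metadata, seed = 1)
  expect_equal(max(m$cv_trace$mean_mcc), 1)
  expect_true(m$lambda_star %in% m$cv_trace$lambda)
})

test_that("tuned CV MCC stays near zero when labels carry no signal", {
  best <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    X <- matrix(rnorm(n * 8), n, 8)
    y <- sample(rep(0:1, each = n / 2))  # labels independent of features
    tab <- feature_table(X, paste0("s", 1:n),
                         paste0("original_firstorder_F", 1:8, "_T1_L1"))
    md <- cohort_metadata(paste0("s", 1:n), rep_len(c("e1", "e2"), n),
                          ifelse(y == 1, "wt", "mut"), "wt")
    m <- tune_lambda(tab, md, repeats = 3, seed = s)
    best[s] <- max(m$cv_trace$mean_mcc)
  }
  expect_true(all(best > -0.2 & best < 0.2))
})

test_that("ties in CV MCC break toward the larger penalty and the grid is searched", {
  sep <- separable_cohort(n = 60, seed = 5)
  m <- tune_lambda(sep$table, sep$metadata, seed = 2)
  top <- m$cv_trace$lambda[m$cv_trace$mean_mcc >= max(m$cv_trace$mean_mcc) - 1e-12]
  expect_equal(m$lambda_star, max(top))
})

test_that("sparsity weakly decreases along the penalty path", {
  toy <- toy_cohort(n = 150, beta = c(1.5, -1, 0.5, 0, 0), seed = 7)
  y <- outcome01(toy$metadata)
  Xs <- scale(unclass(toy$table))
  grid <- radicp:::log_lambda_grid(radicp:::lambda_max_logistic(Xs, y))
  fit <- radicp:::glmnet_fixed_grid(Xs, y, grid)
  nz <- colSums(as.matrix(fit$beta) != 0)
  # grid is descending in lambda, so nonzero counts are non-decreasing
  expect_true(all(diff(nz) >= 0))
})

test_that("near-zero penalty agrees with the unpenalized ML fit", {
  toy <- toy_cohort(n = 400, beta = c(1, -0.7), seed = 9)
  y <- outcome01(toy$metadata)
  Xs <- scale(unclass(toy$table))
  fit <- radicp:::glmnet_fixed_grid(Xs, y, c(0.1, 1e-6))
  co <- radicp:::coef_at(fit, c(0.1, 1e-6), 1e-6)
  ml <- glm(y ~ Xs, family = binomial())
  expect_equal(unname(co$beta), unname(coef(ml)[-1]), tolerance = 1e-2)
  expect_equal(co$a0, unname(coef(ml)[1]), tolerance = 1e-2)
})

test_that("prediction is a calibrated monotone logistic map", {
  sep <- separable_cohort(n = 60, seed = 3)
  m <- tune_lambda(sep$table, sep$metadata, seed = 1)
  pred <- predict(m, sep$table)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # probability monotone when sweeping a positive-coefficient feature
  expect_gt(m$coefficients[1], 0)
  grid_tab <- feature_table(cbind(seq(-3, 3, length.out = 11), 0),
                            paste0("g", 1:11), colnames(sep$table))
  pg <- predict(m, grid_tab)
  expect_true(all(diff(pg$probability) >= 0))
  # all-zero model predicts 0.5 everywhere
  m0 <- m
  m0$coefficients[] <- 0
  m0$intercept <- 0
  expect_equal(predict(m0, sep$table)$probability, rep(0.5, 60))
  # missing feature is a clear error
  half <- feature_table(unclass(sep$table)[, 1, drop = FALSE],
                        rownames(sep$table), colnames(sep$table)[1])
  expect_error(predict(m, half), "lacks")
})

test_that("tuning MCC agrees with the evaluation MCC on shared inputs", {
  set.seed(13)
  y <- rbinom(50, 1, 0.4)
  pred <- rbinom(50, 1, 0.5)
  cm <- confusion(ifelse(y == 1, "wt", "mut"), ifelse(pred == 1, "wt", "mut"),
                  positive = "wt")
  expect_identical(radicp:::mcc_from_labels(y, pred), mcc(cm))
})

test_that("recipe B keeps more features than the invariance recipes", {
  wins <- 0L
  for (s in 1:8) {
    sim <- simulate_multicenter(
      synthetic_config(n_per_env = rep(50, 4), k_noise = 30,
                       batch_shift_scale = 1, seed = 40 + s))
    a1 <- suppressWarnings(
      fit_recipe(sim$table, sim$metadata, "A1", seed = s, max_features = 6,
                 repeats = 3))
    b <- fit_recipe(sim$table, sim$metadata, "B", seed = s, repeats = 3)
    wins <- wins + (n_nonzero(b) > n_nonzero(a1))
  }
  expect_gte(wins, 6L)
})

test_that("class smaller than the fold count is refused", {
  toy <- toy_cohort(n = 30, seed = 1)
  md <- toy$metadata
  md$outcome[md$outcome == "wildtype"][-(1:2)] <- "mutant"
  md$outcome <- droplevels(md$outcome)
  expect_error(tune_lambda(toy$table, md, folds = 3), "folds")
})
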