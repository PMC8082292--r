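test_that("every published confusion matrix reproduces its published metrics", {
  for (nm in names(published_confusions)) {
    entry <- published_confusions[[nm]]
    cm <- wt_confusion(entry$cm)
    ssa <- sens_spec_acc(cm)
    expect_equal(round(unname(ssa["sensitivity"]), 2), entry$sens, info = nm)
    expect_equal(round(unname(ssa["specificity"]), 2), entry$spec, info = nm)
    expect_equal(round(unname(ssa["accuracy"]), 2), entry$acc, info = nm)
    expect_equal(round(mcc(cm), 2), entry$mcc, info = nm)
  }
})

test_that("confusion matrix construction and orientation", {
  truth <- c("mut", "wt", "wt", "mut", "wt")
  pred <- c("mut", "wt", "mut", "mut", "wt")
  cm <- confusion(truth, pred, positive = "wt")
  expect_identical(unclass(cm)[1, 1], 2L)  # pred wt / ref wt
  expect_identical(unclass(cm)[2, 1], 1L)  # pred mut / ref wt
  expect_identical(sum(cm), 5L)
  # swapping the positive class permutes roles but not counts
  cm2 <- confusion(truth, pred, positive = "mut")
  expect_identical(sort(as.vector(cm)), sort(as.vector(cm2)))
  # all-correct toy has empty off-diagonal
  cm3 <- confusion(truth, truth, positive = "wt")
  expect_identical(unclass(cm3)[1, 2] + unclass(cm3)[2, 1], 0L)
  expect_error(confusion(character(0), character(0), "wt"), "empty")
})

test_that("degenerate confusion matrices flag undefined metrics, MCC -> 0", {
  cm <- confusion_from_counts(0, 1, 0, 5)  # no positives in reference
  expect_true(is.na(sens_spec_acc(cm)["sensitivity"]))
  expect_identical(mcc(confusion_from_counts(0, 0, 0, 5)), 0)
  expect_identical(mcc(confusion_from_counts(5, 0, 0, 5)), 1)
})

test_that("Wilson intervals reproduce published bounds under 2-dp truncation", {
  expect_equal(truncate_decimals(wilson_interval(13, 15)),
               c(lower = 0.62, upper = 0.96))
  expect_equal(truncate_decimals(wilson_interval(9, 11)),
               c(lower = 0.52, upper = 0.94))
  expect_equal(truncate_decimals(wilson_interval(2, 3)),
               c(lower = 0.20, upper = 0.93))
  # boundary behavior
  ci <- wilson_interval(1, 1)
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[2] == 1)
  # interval contains the point estimate and shrinks with n
  for (n in c(10, 40, 160)) {
    ci <- wilson_interval(round(0.3 * n), n)
    expect_true(ci[1] <= 0.3 + 1e-9 && ci[2] >= 0.3 - 1e-9)
  }
  w <- vapply(c(10, 40, 160), function(n)
    diff(wilson_interval(round(0.3 * n), n)), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("rank AUC equals the exhaustive pairwise oracle, including ties", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    pairwise <- 0
    for (i in which(y == 1)) for (j in which(y == 0))
      pairwise <- pairwise + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    expect_equal(auc(scores, y), pairwise / (sum(y == 1) * sum(y == 0)))
  }
  expect_equal(auc(1:10, rep(0:1, each = 5)), 1)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("bootstrap AUC interval brackets the point and is seed-stable", {
  set.seed(2)
  y <- rep(0:1, each = 40)
  scores <- y + rnorm(80)
  ci <- bootstrap_auc_ci(scores, y, n_boot = 400, seed = 5)
  ci2 <- bootstrap_auc_ci(scores, y, n_boot = 400, seed = 5)
  expect_identical(ci, ci2)
  a <- auc(scores, y)
  expect_true(ci[1] <= a && a <= ci[2])
})

test_that("paired AUC comparison is symmetric with a floored p-value", {
  set.seed(3)
  y <- rep(0:1, each = 30)
  s1 <- y + rnorm(60)
  s2 <- rnorm(60)
  p12 <- compare_auc(s1, s2, y, n_boot = 300, seed = 7)
  p21 <- compare_auc(s2, s1, y, n_boot = 300, seed = 7)
  expect_equal(p12$p_value, p21$p_value)
  expect_equal(p12$delta_auc, -p21$delta_auc)
  same <- compare_auc(s1, s1, y, n_boot = 300, seed = 7)
  expect_equal(same$p_value, 1)
  expect_gte(p12$p_value, 1 / 300)
  expect_error(compare_auc(s1[-1], s2, y), "length")
})

test_that("Holm adjustment matches the hand-computed step-down result", {
  # sorted: 0.01*3 = 0.03; 0.03*2 = 0.06; 0.04*1 -> max(0.06, 0.04) = 0.06
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  p <- runif(10)
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("NIR test reproduces published p-values and the brute-force tail", {
  # mixed-split scenario: n = 22, 19 correct, NIR = 15/22
  mix <- nir_test(wt_confusion(c(13, 1, 2, 6)))
  expect_equal(mix$nir, 15 / 22)
  expect_equal(round(mix$p_value, 3), 0.048)
  # center-1 scenario: n = 7, 5 correct, NIR = 4/7
  c1 <- nir_test(wt_confusion(c(3, 1, 1, 2)))
  expect_equal(round(c1$p_value, 3), 0.359)
  # exact tail equals direct pmf summation for a spread of cases
  for (n in c(5, 22, 57, 100)) {
    cm <- confusion_from_counts(round(n * 0.3), round(n * 0.1),
                                round(n * 0.2), n - round(n * 0.3) -
                                  round(n * 0.1) - round(n * 0.2))
    got <- nir_test(cm)
    correct <- round(n * 0.3) + (n - round(n * 0.3) - round(n * 0.1) -
                                   round(n * 0.2))
    brute <- sum(dbinom(correct:n, n, got$nir))
    expect_equal(got$p_value, brute)
  }
  # all correct: tail is a single term NIR^n
  cm <- confusion_from_counts(3, 0, 0, 7)
  expect_equal(nir_test(cm)$p_value, (7 / 10)^10)
})

test_that("LOCO test sets partition the cohort and produce a report per recipe", {
  sim <- simulate_multicenter(
    synthetic_config(n_per_env = c(20, 20, 25, 25), k_noise = 10, seed = 31))
  lo <- suppressWarnings(
    run_loco(sim$table, sim$metadata, recipes = c("A1", "B"), seed = 2,
             n_boot = 100, max_features = 5, repeats = 2))
  expect_named(lo, levels(sim$metadata$environment))
  test_ids <- unlist(lapply(names(lo), function(e)
    sim$metadata$sample_id[sim$metadata$environment == e]))
  expect_setequal(test_ids, sim$metadata$sample_id)       # union = cohort
  expect_identical(anyDuplicated(test_ids), 0L)           # pairwise disjoint
  expect_identical(length(lo) * 2L,
                   sum(lengths(lapply(lo, `[[`, "reports"))))
  r <- lo$center1$reports$A1
  expect_s3_class(r, "evaluation_report")
  expect_identical(r$n_test, 20L)
  expect_true(all(lo$center1$auc_comparisons$p_holm >=
                    lo$center1$auc_comparisons$p_raw))
})

test_that("stratified split obeys the rounding rule and preserves class balance", {
  sim <- simulate_multicenter(synthetic_config(seed = 17))  # n = 77
  y <- sim$metadata$outcome
  sp <- suppressWarnings(
    run_split(sim$table, sim$metadata, recipes = "B", seed = 5, n_boot = 100,
              repeats = 2))
  n_tr <- length(sp$train_index)
  # per-class round(0.7 * n_class) to the training side
  expected_tr <- sum(vapply(levels(y), function(cl)
    round(0.7 * sum(y == cl)), numeric(1)))
  expect_identical(n_tr, as.integer(expected_tr))
  expect_identical(sort(c(sp$train_index, sp$test_index)), seq_len(77L))
  f_tr <- mean(y[sp$train_index] == positive_class(sim$metadata))
  f_te <- mean(y[sp$test_index] == positive_class(sim$metadata))
  expect_lt(abs(f_tr - f_te), 1 / min(table(y)))
  # fixed seed reproduces the identical split
  sp2 <- suppressWarnings(
    run_split(sim$table, sim$metadata, recipes = "B", seed = 5, n_boot = 100,
              repeats = 2))
  expect_identical(sp$train_index, sp2$train_index)
})

test_that("selection frequency table matches a brute-force recount", {
  runs <- list(
    r1 = list(selected_names = c("fA", "fB")),
    r2 = list(selected_names = c("fB", "fC")),
    r3 = list(selected_names = character(0)),
    r4 = list(selected_names = c("fB")))
  tab <- selection_frequency_table(runs)
  expect_identical(tab$feature[1], "fB")
  expect_identical(tab$total[1], 3L)
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$total[i],
                     sum(vapply(runs, function(r)
                       tab$feature[i] %in% r$selected_names, logical(1))))
  empty <- selection_frequency_table(list())
  expect_identical(nrow(empty), 0L)
})
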