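#' Confusion matrix with prediction rows and reference columns
#'
#' Cross-tabulates predicted against reference labels for a binary
#' problem. The orientation is rows = prediction, columns = reference.
#'
#' @param labels_true Reference labels.
#' @param labels_pred Predicted labels.
#' @param positive Label treated as the positive class.
#' @return A `confusion_matrix`: 2x2 integer matrix ordered
#'   (positive, negative) on both margins, with the positive class stored
#'   as an attribute.
#' @export
confusion <- function(labels_true, labels_pred, positive) {
  if (length(labels_true) == 0) stop("empty input")
  if (length(labels_true) != length(labels_pred))
    stop("labels_true and labels_pred differ in length")
  labels_true <- as.character(labels_true)
  labels_pred <- as.character(labels_pred)
  lev <- unique(c(labels_true, labels_pred))
  if (length(lev) > 2) stop("labels are not binary: ", paste(lev, collapse = ", "))
  if (!positive %in% lev && length(lev) == 2)
    stop("positive class '", positive, "' not among labels")
  neg <- setdiff(lev, positive)
  neg <- if (length(neg)) neg[1] else "negative"
  cm <- matrix(0L, 2, 2,
               dimnames = list(prediction = c(positive, neg),
                               reference = c(positive, neg)))
  for (i in seq_along(labels_true))
    cm[labels_pred[i], labels_true[i]] <- cm[labels_pred[i], labels_true[i]] + 1L
  confusion_from_counts(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2],
                        positive = positive, negative = neg)
}

#' Build a confusion matrix directly from the four counts
#'
#' Convenience constructor matching the printed-table convention:
#' rows = prediction, columns = reference, positive class first.
#'
#' @param tp,fp,fn,tn Counts: true/false positives, false/true negatives,
#'   where "positive" refers to the `positive` label.
#' @param positive,negative Class labels.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive = "positive",
                                  negative = "negative") {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  cm <- matrix(as.integer(counts), 2, 2, byrow = TRUE,
               dimnames = list(prediction = c(positive, negative),
                               reference = c(positive, negative)))
  structure(cm, positive = positive, class = c("confusion_matrix", "matrix"))
}

cm_counts <- function(cm) {
  list(tp = cm[1, 1], fp = cm[1, 2], fn = cm[2, 1], tn = cm[2, 2])
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the value
#' defined as 0 when any marginal is empty (zero denominator). Identical
#' to the statistic maximized by [tune_lambda()].
#'
#' @param cm A `confusion_matrix`.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  k <- cm_counts(cm)
  mcc_counts(k$tp, k$fp, k$fn, k$tn)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`. A metric whose denominator is empty (e.g. sensitivity when
#' the reference contains no positives) is returned as `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_acc <- function(cm) {
  k <- cm_counts(cm)
  n <- k$tp + k$fp + k$fn + k$tn
  c(sensitivity = if (k$tp + k$fn > 0) k$tp / (k$tp + k$fn) else NA_real_,
    specificity = if (k$tn + k$fp > 0) k$tn / (k$tn + k$fp) else NA_real_,
    accuracy = if (n > 0) (k$tp + k$tn) / n else NA_real_)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n Observed successes out of `n` trials.
#' @param confidence Coverage level (default 0.95, i.e. z = 1.96).
#' @return Numeric `c(lower, upper)`, clipped to `[0, 1]`.
#' @examples
#' wilson_interval(13, 15)   # c(0.6212..., 0.9627...)
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n with n >= 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  pmin(pmax(c(lower = center - half, upper = center + half), 0), 1)
}

#' Truncate toward zero at k decimals (reporting convention)
#'
#' Interval endpoints are reported truncated — not rounded — to two
#' decimals; full-precision values are always retained alongside.
#'
#' @param x Numeric.
#' @param k Decimals kept.
#' @return Truncated numeric.
#' @export
truncate_decimals <- function(x, k = 2) trunc(x * 10^k) / 10^k

#' Rank-based AUC (probability of correct pairwise ordering)
#'
#' Area under the ROC curve computed from midranks, equivalent to the
#' proportion of (positive, negative) pairs ordered correctly with ties
#' counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @param positive Positive-class label; by default labels are taken as
#'   0/1 with 1 positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  y <- if (is.null(positive)) as.integer(labels == 1) else
    as.integer(as.character(labels) == positive)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Class-stratified bootstrap index draws: resample within each class.
stratified_boot_index <- function(y) {
  ix1 <- which(y == 1); ix0 <- which(y == 0)
  c(ix1[sample.int(length(ix1), replace = TRUE)],
    ix0[sample.int(length(ix0), replace = TRUE)])
}

#' Stratified-bootstrap percentile confidence interval for the AUC
#'
#' Resamples within each outcome class (so every replicate contains both
#' classes), recomputes the rank AUC, and returns the percentile interval.
#'
#' @inheritParams auc
#' @param n_boot Number of bootstrap replications (default 2000).
#' @param confidence Coverage level.
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L,
                             confidence = 0.95, seed = 1L, positive = NULL) {
  y <- if (is.null(positive)) as.integer(labels == 1) else
    as.integer(as.character(labels) == positive)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be present")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    ix <- stratified_boot_index(y)
    auc(scores[ix], y[ix])
  }, numeric(1))
  a <- (1 - confidence) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Compare two models' AUCs by paired stratified bootstrap
#'
#' Both score vectors are resampled on the same class-stratified bootstrap
#' indices; the two-sided p-value is `2 * min(P(dAUC <= 0), P(dAUC >= 0))`
#' over replicates, floored at `1/n_boot` and capped at 1.
#'
#' @param scores_a,scores_b Scores from two models on the same samples.
#' @inheritParams bootstrap_auc_ci
#' @return List with `p_value`, `delta_auc` (observed AUC difference
#'   a - b), and `n_boot`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, n_boot = 2000L,
                        seed = 1L, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  y <- if (is.null(positive)) as.integer(labels == 1) else
    as.integer(as.character(labels) == positive)
  set.seed(seed)
  d <- vapply(seq_len(n_boot), function(b) {
    ix <- stratified_boot_index(y)
    auc(scores_a[ix], y[ix]) - auc(scores_b[ix], y[ix])
  }, numeric(1))
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  list(p_value = min(1, max(p, 1 / n_boot)),
       delta_auc = auc(scores_a, y) - auc(scores_b, y),
       n_boot = n_boot)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' No-information-rate test of a confusion matrix
#'
#' The no-information rate (NIR) is the majority-class fraction of the
#' reference labels — the accuracy of a constant classifier. The one-sided
#' exact binomial test asks whether the observed number of correct
#' predictions exceeds what guessing the majority class would give:
#' `p = P(X >= correct)` for `X ~ Binomial(n, NIR)`.
#'
#' @param cm A `confusion_matrix`.
#' @return List with `nir`, `accuracy`, and the one-sided `p_value`.
#' @export
nir_test <- function(cm) {
  k <- cm_counts(cm)
  n <- k$tp + k$fp + k$fn + k$tn
  if (n == 0) stop("empty confusion matrix")
  nir <- max(k$tp + k$fn, k$tn + k$fp) / n
  correct <- k$tp + k$tn
  p <- stats::pbinom(correct - 1, n, nir, lower.tail = FALSE)
  list(nir = nir, accuracy = correct / n, p_value = p)
}

#' Full evaluation report for one model on one test set
#'
#' Assembles the battery reported per scenario: confusion matrix; AUC with
#' stratified-bootstrap CI; accuracy, sensitivity and specificity with
#' Wilson intervals; MCC with a stratified-bootstrap percentile CI (MCC is
#' not a proportion, so a Wilson interval does not apply); and the exact
#' binomial NIR test. Interval endpoints are reported both at full
#' precision and truncated to two decimals.
#'
#' @param metadata_test [cohort_metadata()] of the test samples.
#' @param probabilities Positive-class probabilities on the test samples.
#' @param labels_pred Predicted outcome labels on the test samples.
#' @param n_boot Bootstrap replications for the AUC and MCC intervals.
#' @param seed Integer seed for the bootstrap.
#' @param scenario Free-text descriptor stored on the report.
#' @return An `evaluation_report` list.
#' @export
evaluate_predictions <- function(metadata_test, probabilities, labels_pred,
                                 n_boot = 2000L, seed = 1L,
                                 scenario = "") {
  if (nrow(metadata_test) == 0) stop("empty test set")
  pos <- positive_class(metadata_test)
  y <- outcome01(metadata_test)
  cm <- confusion(as.character(metadata_test$outcome), labels_pred, pos)
  k <- cm_counts(cm)
  n <- sum(unlist(k))
  ssa <- sens_spec_acc(cm)
  both <- length(unique(y)) == 2

  metric_ci <- function(succ, den) {
    if (den == 0) return(list(point = NA_real_, ci = c(NA_real_, NA_real_)))
    list(point = succ / den, ci = wilson_interval(succ, den))
  }
  sens <- metric_ci(k$tp, k$tp + k$fn)
  spec <- metric_ci(k$tn, k$tn + k$fp)
  acc <- metric_ci(k$tp + k$tn, n)

  auc_point <- if (both) auc(probabilities, y) else NA_real_
  auc_ci <- if (both)
    bootstrap_auc_ci(probabilities, y, n_boot = n_boot, seed = seed)
  else c(NA_real_, NA_real_)

  mcc_point <- mcc(cm)
  mcc_ci <- if (both) {
    set.seed(seed + 1L)
    pred01 <- as.integer(labels_pred == pos)
    reps <- vapply(seq_len(n_boot), function(b) {
      ix <- stratified_boot_index(y)
      mcc_from_labels(y[ix], pred01[ix])
    }, numeric(1))
    unname(stats::quantile(reps, c(0.025, 0.975)))
  } else c(NA_real_, NA_real_)

  fmt <- function(m) list(
    point = m$point, ci_lower = unname(m$ci[1]), ci_upper = unname(m$ci[2]),
    ci_lower_2dp = truncate_decimals(unname(m$ci[1])),
    ci_upper_2dp = truncate_decimals(unname(m$ci[2])))

  structure(list(
    scenario = scenario,
    n_test = n,
    positive_class = pos,
    confusion = cm,
    metrics = list(
      auc = fmt(list(point = auc_point, ci = auc_ci)),
      accuracy = fmt(acc),
      sensitivity = fmt(sens),
      specificity = fmt(spec),
      mcc = fmt(list(point = mcc_point, ci = mcc_ci))),
    nir = nir_test(cm),
    class_absent = !both,
    n_boot = n_boot, seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$scenario, "- n =", x$n_test,
      "(positive:", paste0(x$positive_class, ")"), "\n")
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-12s %.2f [%.2f; %.2f]\n", m, v$point,
                v$ci_lower_2dp, v$ci_upper_2dp))
  }
  cat(sprintf("  NIR %.3f, p[acc > NIR] = %.3f\n", x$nir$nir, x$nir$p_value))
  invisible(x)
}

## Evaluate one fitted model on held-out data and attach its CV summary.
evaluate_model <- function(model, table_test, metadata_test, n_boot, seed,
                           scenario) {
  pred <- predict(model, table_test)
  rep <- evaluate_predictions(metadata_test, pred$probability, pred$label,
                              n_boot = n_boot, seed = seed,
                              scenario = scenario)
  best <- which(model$cv_trace$lambda == model$lambda_star)
  rep$cv <- list(mean_mcc = model$cv_trace$mean_mcc[best],
                 mcc_ci = unname(stats::quantile(
                   model$cv_mcc_values[, best], c(0.025, 0.975))))
  rep$recipe <- model$recipe
  rep$lambda_star <- model$lambda_star
  rep$n_features <- n_nonzero(model)
  rep$fallback_used <- isTRUE(model$fallback_used)
  rep
}

subset_rows <- function(table, metadata, keep) {
  list(table = feature_table(unclass(table)[keep, , drop = FALSE],
                             rownames(table)[keep], colnames(table)),
       metadata = cohort_metadata(metadata$sample_id[keep],
                                  metadata$environment[keep],
                                  metadata$outcome[keep],
                                  positive_class(metadata)))
}

## Pairwise AUC comparisons across recipes on a shared test set, Holm-adjusted.
compare_recipes <- function(reports, probs, y, n_boot, seed) {
  rec <- names(probs)
  if (length(rec) < 2 || length(unique(y)) < 2) return(NULL)
  pairs <- utils::combn(rec, 2)
  praw <- vapply(seq_len(ncol(pairs)), function(j)
    compare_auc(probs[[pairs[1, j]]], probs[[pairs[2, j]]], y,
                n_boot = n_boot, seed = seed)$p_value, numeric(1))
  data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
             p_raw = praw, p_holm = holm_adjust(praw),
             stringsAsFactors = FALSE)
}

#' Leave-one-center-out evaluation of the model recipes
#'
#' For each environment in turn: the full pipeline (preselection,
#' invariance selection, MCC-tuned classifier) is run on the remaining
#' environments only — the invariance stage sees those environments as its
#' environment labels — and the resulting model is evaluated on the
#' held-out center. Pairwise AUC comparisons between recipes on each
#' held-out center are Holm-adjusted.
#'
#' @param table,metadata The full multicenter cohort.
#' @param recipes Character vector of recipes to fit (see [fit_recipe()]).
#' @param seed Integer seed for every stochastic stage.
#' @param n_boot Bootstrap replications in the evaluation.
#' @param ... Further tuning/selection parameters passed to [fit_recipe()].
#' @return A `loco_result`: list with one element per environment, each
#'   holding `reports` (one `evaluation_report` per recipe), the fitted
#'   `models`, and the `auc_comparisons` table.
#' @export
run_loco <- function(table, metadata, recipes = c("A1", "A2", "B"),
                     seed = 1L, n_boot = 2000L, ...) {
  envs <- levels(metadata$environment)
  if (length(envs) < 2) stop("leave-one-center-out needs >= 2 environments")
  out <- vector("list", length(envs))
  names(out) <- envs
  for (e in envs) {
    test <- metadata$environment == e
    tr <- subset_rows(table, metadata, !test)
    te <- subset_rows_test(table, metadata, test)
    models <- lapply(recipes, function(r)
      fit_recipe(tr$table, tr$metadata, recipe = r, seed = seed, ...))
    names(models) <- recipes
    reports <- lapply(recipes, function(r)
      evaluate_model(models[[r]], te$table, te$metadata, n_boot, seed,
                     scenario = paste0("loco:", e, ":", r)))
    names(reports) <- recipes
    probs <- lapply(models, function(m) predict(m, te$table)$probability)
    cmpr <- compare_recipes(reports, probs, outcome01(te$metadata),
                            n_boot, seed)
    out[[e]] <- list(held_out = e, reports = reports, models = models,
                     auc_comparisons = cmpr)
  }
  structure(out, class = "loco_result")
}

## Test-set rows keep their environment labels but may contain a single
## environment, which cohort_metadata() rejects; carry the full factor.
subset_rows_test <- function(table, metadata, keep) {
  md <- metadata[keep, , drop = FALSE]
  md$environment <- factor(md$environment)  # keep level, no 2-env check
  attr(md, "positive_class") <- positive_class(metadata)
  class(md) <- class(metadata)
  list(table = feature_table(unclass(table)[keep, , drop = FALSE],
                             rownames(table)[keep], colnames(table)),
       metadata = md)
}

#' Stratified 70/30 split evaluation of the model recipes
#'
#' Splits the pooled cohort by outcome-stratified sampling —
#' `round(train_fraction * n_class)` of each class to the training side —
#' runs the full pipeline on the training part (environments retained for
#' the invariance stage), and evaluates on the held-out part.
#'
#' @inheritParams run_loco
#' @param train_fraction Fraction of each class assigned to training.
#' @return A `split_result`: `reports` and `models` per recipe, the
#'   `auc_comparisons` table, and the train/test index split.
#' @export
run_split <- function(table, metadata, recipes = c("A1", "A2", "B"),
                      train_fraction = 0.7, seed = 1L, n_boot = 2000L, ...) {
  y <- outcome01(metadata)
  set.seed(seed)
  tr_ix <- unlist(lapply(unique(y), function(cl) {
    ix <- which(y == cl)
    m <- round(train_fraction * length(ix))
    if (m < 2 || length(ix) - m < 1)
      stop("stratified split infeasible: class of size ", length(ix))
    ix[sample.int(length(ix), m)]
  }), use.names = FALSE)
  keep_tr <- seq_len(nrow(table)) %in% tr_ix
  tr <- subset_rows(table, metadata, keep_tr)
  te <- subset_rows_test(table, metadata, !keep_tr)
  models <- lapply(recipes, function(r)
    fit_recipe(tr$table, tr$metadata, recipe = r, seed = seed, ...))
  names(models) <- recipes
  reports <- lapply(recipes, function(r)
    evaluate_model(models[[r]], te$table, te$metadata, n_boot, seed,
                   scenario = paste0("split:", r)))
  names(reports) <- recipes
  probs <- lapply(models, function(m) predict(m, te$table)$probability)
  cmpr <- compare_recipes(reports, probs, outcome01(te$metadata), n_boot, seed)
  structure(list(reports = reports, models = models, auc_comparisons = cmpr,
                 train_index = sort(tr_ix),
                 test_index = which(!keep_tr)),
            class = "split_result")
}

#' Selection-frequency table across runs
#'
#' Tabulates which features each selection run retained: a 0/1 incidence
#' matrix (feature x run) plus row totals, sorted by total descending —
#' the summary used to ask which features recur across scenarios and
#' recipes.
#'
#' @param results Named list of `selection_result` objects (or anything
#'   with a `selected_names` field, e.g. invariance results via their
#'   `invariant_names`), sharing a feature namespace.
#' @return A data frame with one row per selected feature, one 0/1 column
#'   per run, and a `total` column; zero rows if `results` is empty.
#' @export
selection_frequency_table <- function(results) {
  if (length(results) == 0)
    return(data.frame(feature = character(0), total = integer(0)))
  if (is.null(names(results)))
    names(results) <- paste0("run", seq_along(results))
  name_of <- function(r) {
    if (!is.null(r$selected_names)) r$selected_names
    else if (!is.null(r$invariant_names)) r$invariant_names
    else as.character(r)
  }
  sel <- lapply(results, name_of)
  feats <- unique(unlist(sel))
  inc <- vapply(sel, function(s) as.integer(feats %in% s),
                integer(length(feats)))
  inc <- matrix(inc, nrow = length(feats),
                dimnames = list(NULL, names(results)))
  out <- data.frame(feature = feats, inc, total = as.integer(rowSums(inc)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
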