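#' Invariance p-value of a candidate feature subset
#'
#' Tests whether the relationship between a feature subset and the binary
#' outcome is invariant across acquisition environments, in the style of
#' invariant causal prediction: a subset is plausible if the
#' outcome-given-subset model needs no environment-specific terms.
#'
#' Two test constructions are available:
#' \describe{
#'   \item{`"environment"` (default)}{A likelihood-ratio test of the pooled
#'     logistic model of outcome on the subset against the same model
#'     augmented with environment main effects (`df = E - 1`). Because all
#'     parameters are estimated jointly by maximum likelihood, the test
#'     remains calibrated under covariate shift — environments may move the
#'     feature distributions freely without inducing false rejections — and
#'     it behaves well even when some centers contribute only a handful of
#'     samples.}
#'   \item{`"residual"`}{A two-sample construction: for each environment
#'     `e`, a logistic model is fitted on all samples outside `e`, and
#'     deviance residuals are compared between `e` and the fitting
#'     complement by a Welch test on means and a robust Brown-Forsythe
#'     style test on scale (Welch test on median-centered absolute
#'     deviations), Bonferroni-combined per environment
#'     (`p_e = 2 min(p_mean, p_scale)`) and across environments
#'     (`p = min(1, E min_e p_e)`). This mirrors the regression variant of
#'     the invariance framework, but the distribution of logistic deviance
#'     residuals depends on the local event probability, so strong
#'     covariate shift between environments inflates its rejection rate
#'     even when the outcome mechanism is invariant; it is provided for
#'     comparison, not as the default.}
#' }
#'
#' A subset whose model cannot be fitted at all is rejected with `p = 0`
#' rather than skipped.
#'
#' @param subset Integer vector of feature column indices (possibly empty;
#'   the empty subset tests whether outcome prevalence alone is invariant).
#' @param table A [feature_table()].
#' @param metadata A [cohort_metadata()] aligned with `table` (at least 2
#'   environments).
#' @param method Test construction, `"environment"` or `"residual"`.
#' @return A single p-value in `[0, 1]`.
#' @seealso [select_invariant()]
#' @export
invariance_pvalue <- function(subset, table, metadata,
                              method = c("environment", "residual")) {
  method <- match.arg(method)
  y <- outcome01(metadata)
  env <- droplevels(metadata$environment)
  if (nlevels(env) < 2) stop("need at least 2 environments")
  X <- unclass(table)[, as.integer(subset), drop = FALSE]
  if (method == "environment") invariance_lrt(X, y, env)
  else invariance_residual(X, y, env)
}

## -2 log-likelihood of a (stabilized) logistic fit of y on X.
binomial_deviance <- function(X, y) {
  fit <- fit_logistic_stable(X, y)
  p <- pmin(pmax(predict_logistic(fit, X), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

invariance_lrt <- function(X, y, env) {
  E <- nlevels(env)
  d_null <- tryCatch(binomial_deviance(X, y), error = function(e) NULL)
  dummies <- stats::model.matrix(~env)[, -1, drop = FALSE]
  d_alt <- tryCatch(binomial_deviance(cbind(X, dummies), y),
                    error = function(e) NULL)
  if (is.null(d_null) || is.null(d_alt)) return(0)
  stats::pchisq(max(d_null - d_alt, 0), df = E - 1, lower.tail = FALSE)
}

invariance_residual <- function(X, y, env) {
  envs <- levels(env)
  p_env <- rep(NA_real_, length(envs))
  for (i in seq_along(envs)) {
    inn <- env == envs[i]
    fit <- tryCatch(fit_logistic_stable(X[!inn, , drop = FALSE], y[!inn]),
                    error = function(e) NULL)
    if (is.null(fit)) return(0)
    if (isTRUE(fit$ridged))
      message("ridge-stabilized fit used for complement of environment ",
              envs[i])
    r_in <- deviance_residuals(y[inn],
                               predict_logistic(fit, X[inn, , drop = FALSE]))
    r_out <- deviance_residuals(y[!inn],
                                predict_logistic(fit, X[!inn, , drop = FALSE]))
    p_mean <- two_sample_p(r_in, r_out)
    p_scale <- two_sample_p(abs(r_in - stats::median(r_in)),
                            abs(r_out - stats::median(r_out)))
    p_env[i] <- min(1, 2 * min(p_mean, p_scale))
  }
  min(1, length(envs) * min(p_env))
}

## Welch two-sample p-value, degenerate inputs -> 1 (no evidence).
two_sample_p <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(1)
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) return(1)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Select invariant features by subset enumeration
#'
#' Enumerates all subsets of a preselected candidate pool up to
#' `max_subset_size` (including the empty set), computes the
#' [invariance_pvalue()] of each, accepts those with `p > alpha`, and
#' returns the intersection of all accepted subsets — the features that
#' every plausible invariant model agrees on. This intersection carries the
#' method's family-wise guarantee: whenever the truly invariant (causal)
#' subset is accepted, which happens with probability at least `1 - alpha`,
#' the output is contained in it.
#'
#' If no subset is accepted the result is empty with
#' `fallback_used = TRUE`, signalling that a downstream model should fall
#' back to the preselection pool (with a warning) rather than fit on
#' nothing.
#'
#' @param pool A `selection_result` from a preselection stage, or an
#'   integer vector of feature indices.
#' @param table A [feature_table()].
#' @param metadata A [cohort_metadata()].
#' @param alpha Significance level of the invariance test (default 0.05).
#' @param max_subset_size Largest subset cardinality enumerated.
#' @param max_subsets Guard on the total number of enumerated subsets.
#' @param method Test construction, passed to [invariance_pvalue()].
#' @return An `invariance_result` with the candidate pool, the full ledger
#'   of tested subsets (`tested_sets`: subset, size, p-value, accepted
#'   flag), the `invariant_features` intersection, `alpha`, and
#'   `fallback_used`.
#' @export
select_invariant <- function(pool, table, metadata, alpha = 0.05,
                             max_subset_size = 4L, max_subsets = 50000L,
                             method = c("environment", "residual")) {
  method <- match.arg(method)
  idx <- if (inherits(pool, "selection_result")) pool$selected
         else as.integer(pool)
  if (anyDuplicated(idx)) stop("candidate pool contains duplicate indices")
  m <- length(idx)
  sizes <- 0:min(max_subset_size, m)
  n_sub <- sum(choose(m, sizes))
  if (n_sub > max_subsets)
    stop("enumeration of ", n_sub, " subsets exceeds the cap of ",
         max_subsets, "; shrink the preselection pool or max_subset_size")
  subsets <- list(integer(0))
  for (s in sizes[sizes > 0]) {
    cmb <- utils::combn(idx, s)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  pvals <- vapply(subsets, invariance_pvalue, numeric(1),
                  table = table, metadata = metadata, method = method)
  accepted <- pvals > alpha
  inv <- if (any(accepted)) Reduce(intersect, subsets[accepted]) else integer(0)
  tested <- data.frame(
    subset = vapply(subsets, function(s) paste(s, collapse = ","),
                    character(1)),
    size = lengths(subsets), p_value = pvals, accepted = accepted,
    stringsAsFactors = FALSE)
  structure(list(candidate_pool = idx,
                 tested_sets = tested,
                 invariant_features = sort(as.integer(inv)),
                 invariant_names = colnames(table)[sort(as.integer(inv))],
                 alpha = alpha, method = method,
                 fallback_used = !any(accepted)),
            class = "invariance_result")
}

#' @export
print.invariance_result <- function(x, ...) {
  cat("<invariance_result>", nrow(x$tested_sets), "subsets tested at alpha =",
      x$alpha, paste0("(", x$method, " test)"),
      "\n  accepted:", sum(x$tested_sets$accepted),
      "\n  invariant features:",
      if (length(x$invariant_features))
        paste(x$invariant_names, collapse = ", ") else "(none)", "\n")
  if (x$fallback_used)
    cat("  no subset accepted; downstream fallback to the preselection pool\n")
  invisible(x)
}
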