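#' @importFrom glmnet glmnet cv.glmnet
NULL

new_selection_result <- function(method, selected, diagnostics, parameters,
                                 feature_names) {
  structure(list(method = method,
                 selected = as.integer(selected),
                 selected_names = feature_names[selected],
                 diagnostics = diagnostics,
                 parameters = parameters),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method:", x$method, "-", length(x$selected),
      "feature(s) selected\n")
  if (length(x$selected))
    cat(paste0("  ", utils::head(x$selected_names, 10)), sep = "\n")
  invisible(x)
}

#' Lasso-based feature preselection
#'
#' Fits an L1-penalized logistic path with internal standardization and
#' returns the features with nonzero coefficients at the cross-validated
#' penalty, ranked by descending absolute coefficient and truncated to
#' `max_features`. This is the embedded preselection stage that constrains
#' the invariance subset search to a tractable pool.
#'
#' @param table A [feature_table()].
#' @param metadata A [cohort_metadata()] aligned with `table`.
#' @param max_features Maximum pool size returned; kept small because the
#'   invariance stage enumerates subsets of the pool.
#' @param folds Number of cross-validation folds for the penalty choice.
#' @param seed Integer seed controlling fold assignment.
#' @return A `selection_result` with `method = "lasso"`, selected feature
#'   indices, and the absolute coefficients as diagnostics.
#' @export
preselect_lasso <- function(table, metadata, max_features = 20L,
                            folds = 10L, seed = 1L) {
  y <- outcome01(metadata)
  if (min(table(y)) < 2) stop("need at least 2 samples in each class")
  X <- unclass(table)
  sds <- apply(X, 2, stats::sd)
  if (all(sds < .Machine$double.eps)) {
    warning("all features are constant; returning an empty selection")
    return(new_selection_result("lasso", integer(0), numeric(0),
                                list(max_features = max_features, seed = seed),
                                colnames(table)))
  }
  set.seed(seed)
  foldid <- stratified_folds(y, min(folds, min(table(y))))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = TRUE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  nz <- which(co != 0)
  ord <- nz[order(abs(co[nz]), decreasing = TRUE)]
  sel <- utils::head(ord, max_features)
  diag <- abs(co)
  names(diag) <- colnames(table)
  new_selection_result("lasso", sel, diag,
                       list(max_features = max_features, folds = folds,
                            lambda = cv$lambda.min, seed = seed),
                       colnames(table))
}

#' Stability-based feature preselection
#'
#' Stability selection with class-stratified subsampling: the L1 path is
#' refit on `n_subsamples` half-cohorts over a fixed penalty grid, and a
#' feature's selection frequency is the fraction of subsamples in which its
#' coefficient is ever nonzero anywhere on the grid. Features with
#' frequency at or above `frequency_threshold` are retained, ranked by
#' descending frequency and truncated to `max_features`.
#'
#' @inheritParams preselect_lasso
#' @param n_subsamples Number of subsample refits.
#' @param subsample_fraction Fraction of each class drawn per subsample,
#'   strictly in (0,1).
#' @param penalty_grid Optional numeric penalty grid (descending); by
#'   default 50 log-spaced values spanning three decades below the
#'   smallest all-zeroing penalty of the full data.
#' @param frequency_threshold Minimum selection frequency to retain a
#'   feature, in `[0,1]`.
#' @param subsamples Optional list of row-index vectors to use instead of
#'   drawing subsamples internally (each must contain both classes); used
#'   mainly for verification against an external enumeration.
#' @return A `selection_result` with `method = "stability"` and the
#'   per-feature selection frequencies as diagnostics.
#' @export
preselect_stability <- function(table, metadata, n_subsamples = 100L,
                                subsample_fraction = 0.5,
                                penalty_grid = NULL,
                                frequency_threshold = 0.6,
                                max_features = 20L, seed = 1L,
                                subsamples = NULL) {
  if (is.null(subsamples) && n_subsamples < 2)
    stop("n_subsamples must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("subsample_fraction must lie strictly in (0,1)")
  y <- outcome01(metadata)
  X <- unclass(table)
  std <- standardize_fit(X)
  if (is.null(penalty_grid)) {
    lmax <- lambda_max_logistic(standardize_apply(X, std), y)
    penalty_grid <- log_lambda_grid(lmax, grid_size = 50)
  }
  set.seed(seed)
  if (is.null(subsamples)) {
    subsamples <- vector("list", n_subsamples)
    for (b in seq_len(n_subsamples)) {
      for (try in 1:10) {
        ix <- stratified_subsample(y, subsample_fraction)
        if (length(unique(y[ix])) == 2) break
        if (try == 10) stop("could not draw a subsample containing both classes")
      }
      subsamples[[b]] <- ix
    }
  }
  hits <- numeric(ncol(X))
  for (ix in subsamples) {
    fit <- glmnet::glmnet(X[ix, , drop = FALSE], y[ix], family = "binomial",
                          alpha = 1, lambda = penalty_grid,
                          standardize = TRUE)
    ever <- apply(fit$beta != 0, 1, any)
    hits <- hits + as.numeric(ever)
  }
  freq <- hits / length(subsamples)
  names(freq) <- colnames(table)
  keep <- which(freq >= frequency_threshold & freq > 0)
  if (frequency_threshold == 0) keep <- which(freq > 0)
  ord <- keep[order(freq[keep], decreasing = TRUE)]
  sel <- utils::head(ord, max_features)
  new_selection_result("stability", sel, freq,
                       list(n_subsamples = length(subsamples),
                            subsample_fraction = subsample_fraction,
                            frequency_threshold = frequency_threshold,
                            max_features = max_features, seed = seed),
                       colnames(table))
}
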