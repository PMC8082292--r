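## MCC from the four confusion counts; degenerate (zero) denominator -> 0.
## Single source of truth shared by the tuner and the evaluation metrics so
## the two agree bit-for-bit.
mcc_counts <- function(tp, fp, fn, tn) {
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
}

mcc_from_labels <- function(y_true01, y_pred01) {
  mcc_counts(sum(y_pred01 == 1 & y_true01 == 1),
             sum(y_pred01 == 1 & y_true01 == 0),
             sum(y_pred01 == 0 & y_true01 == 1),
             sum(y_pred01 == 0 & y_true01 == 0))
}

#' Tune an L1-penalized logistic model by repeated CV maximizing MCC
#'
#' Fits a lasso-logistic model on a feature subset, choosing the penalty
#' strength by repeated stratified cross-validation (default 10 repeats of
#' 3 folds) that maximizes the mean Matthews correlation coefficient of
#' hard 0.5-threshold predictions. The penalty grid is log-spaced over
#' three decades below the smallest all-zeroing penalty; ties in mean MCC
#' break toward the larger (sparser) penalty. Features are standardized to
#' zero mean and unit variance using training-data statistics before
#' penalized fitting, and the final model is refit on all training data at
#' the chosen penalty.
#'
#' @param table A [feature_table()] (training data).
#' @param metadata A [cohort_metadata()] aligned with `table`.
#' @param subset Integer indices of the features to use; `NULL` for all
#'   (the all-features recipe).
#' @param grid_size Number of penalty values on the grid.
#' @param repeats,folds Repeated cross-validation layout; every fold is
#'   class-stratified, which requires each class to have at least `folds`
#'   members.
#' @param seed Integer seed controlling fold assignment.
#' @param recipe Optional tag (`"A1"`, `"A2"`, `"B"`, ...) recorded on the
#'   model for bookkeeping.
#' @return A `tuned_model` with the standardized-scale coefficients and
#'   intercept, the chosen `lambda_star`, the per-penalty CV trace
#'   (`lambda`, `mean_mcc`, `sd_mcc`), the standardization constants, the
#'   feature subset, and the recipe tag.
#' @export
tune_lambda <- function(table, metadata, subset = NULL, grid_size = 50L,
                        repeats = 10L, folds = 3L, seed = 1L,
                        recipe = NA_character_) {
  y <- outcome01(metadata)
  cls <- table(y)
  if (length(cls) < 2 || min(cls) < folds)
    stop("each class needs at least `folds` (= ", folds, ") samples for ",
         "stratified cross-validation; reduce `folds`")
  if (is.null(subset)) subset <- seq_len(ncol(table))
  subset <- as.integer(subset)
  if (length(subset) == 0)
    stop("cannot tune a model on an empty feature subset")
  X <- unclass(table)[, subset, drop = FALSE]
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  grid <- log_lambda_grid(lambda_max_logistic(Xs, y), grid_size = grid_size)

  set.seed(seed)
  cv_mcc <- matrix(NA_real_, nrow = repeats * folds, ncol = length(grid))
  row <- 0L
  for (r in seq_len(repeats)) {
    foldid <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- foldid != f
      fit <- glmnet_fixed_grid(Xs[tr, , drop = FALSE], y[tr], grid)
      prob <- predict_grid(fit, Xs[!tr, , drop = FALSE], grid)
      cv_mcc[row, ] <- apply(prob >= 0.5, 2, function(hard)
        mcc_from_labels(y[!tr], as.integer(hard)))
    }
  }
  mean_mcc <- colMeans(cv_mcc)
  best <- max(mean_mcc)
  lambda_star <- grid[which(mean_mcc >= best - 1e-12)[1]]  # grid is descending

  final <- glmnet_fixed_grid(Xs, y, grid)
  co <- coef_at(final, grid, lambda_star)
  structure(list(feature_subset = subset,
                 feature_names = colnames(table)[subset],
                 intercept = co$a0, coefficients = co$beta,
                 lambda_star = lambda_star,
                 cv_trace = data.frame(lambda = grid, mean_mcc = mean_mcc,
                                       sd_mcc = apply(cv_mcc, 2, stats::sd)),
                 cv_mcc_values = cv_mcc,
                 standardization = std,
                 positive_class = positive_class(metadata),
                 outcome_levels = levels(metadata$outcome),
                 recipe = recipe, seed = seed),
            class = "tuned_model")
}

## glmnet on an explicit descending lambda grid, no internal standardization
## (features are already standardized); single-column inputs are padded with
## a zero column because glmnet requires >= 2 predictors.
glmnet_fixed_grid <- function(Xs, y, grid) {
  pad <- ncol(Xs) == 1
  if (pad) Xs <- cbind(Xs, .pad = 0)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                        lambda = grid, standardize = FALSE)
  attr(fit, "padded") <- pad
  fit
}

predict_grid <- function(fit, Xs, grid) {
  if (isTRUE(attr(fit, "padded"))) Xs <- cbind(Xs, .pad = 0)
  stats::predict(fit, newx = Xs, s = grid, type = "response",
                 exact = FALSE)
}

coef_at <- function(fit, grid, lambda) {
  co <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  beta <- co[-1, 1]
  if (isTRUE(attr(fit, "padded"))) beta <- beta[-length(beta)]
  list(a0 = co[1, 1], beta = beta)
}

#' Number of nonzero coefficients of a tuned model
#' @param model A `tuned_model`.
#' @return Integer count (intercept excluded).
#' @export
n_nonzero <- function(model) sum(model$coefficients != 0)

#' @export
print.tuned_model <- function(x, ...) {
  cat("<tuned_model>", if (!is.na(x$recipe)) paste0("recipe ", x$recipe),
      "- lambda* =", signif(x$lambda_star, 4), "-", n_nonzero(x),
      "nonzero coefficient(s) of", length(x$coefficients), "\n")
  invisible(x)
}

#' Predict from a tuned model
#'
#' Applies the stored standardization and coefficients to new data and
#' returns positive-class probabilities and hard labels at the fixed 0.5
#' threshold.
#'
#' @param object A `tuned_model`.
#' @param table A [feature_table()] whose feature names cover the model's
#'   subset (matched by name).
#' @param ... Unused.
#' @return A data frame with columns `sample_id`, `probability`
#'   (positive class) and `label` (predicted outcome level).
#' @export
predict.tuned_model <- function(object, table, ...) {
  missing <- setdiff(object$feature_names, colnames(table))
  if (length(missing))
    stop("table lacks model feature(s): ", paste(missing, collapse = ", "))
  X <- unclass(table)[, object$feature_names, drop = FALSE]
  Xs <- standardize_apply(X, object$standardization)
  prob <- stats::plogis(object$intercept + drop(Xs %*% object$coefficients))
  neg <- setdiff(object$outcome_levels, object$positive_class)
  data.frame(sample_id = rownames(table),
             probability = prob,
             label = ifelse(prob >= 0.5, object$positive_class, neg),
             stringsAsFactors = FALSE)
}

#' Fit one of the three model recipes
#'
#' The three modelling recipes compared throughout the package:
#' \describe{
#'   \item{A1}{lasso preselection, then invariance-based selection, then
#'     the MCC-tuned lasso-logistic classifier;}
#'   \item{A2}{stability preselection, then invariance-based selection,
#'     then the classifier;}
#'   \item{B}{the classifier on all features (the conventional embedded
#'     approach).}
#' }
#' When the invariance stage accepts no subset, the classifier falls back
#' to the preselection pool with a warning (`fallback_used` is recorded on
#' the model).
#'
#' @param table,metadata Training data.
#' @param recipe One of `"A1"`, `"A2"`, `"B"`.
#' @param seed Integer seed used for every stochastic stage.
#' @param alpha Invariance-test significance level.
#' @param max_features Preselection pool cap.
#' @param max_subset_size Invariance enumeration cap per subset.
#' @param n_subsamples Stability-selection subsample count (recipe A2).
#' @param repeats,folds,grid_size Passed to [tune_lambda()].
#' @return A `tuned_model`, with the `selection` (a `selection_result`)
#'   and, for A1/A2, the `invariance` ledger attached.
#' @export
fit_recipe <- function(table, metadata, recipe = c("A1", "A2", "B"),
                       seed = 1L, alpha = 0.05, max_features = 20L,
                       max_subset_size = 4L, n_subsamples = 100L,
                       repeats = 10L, folds = 3L, grid_size = 50L) {
  recipe <- match.arg(recipe)
  sel <- NULL; inv <- NULL
  if (recipe == "B") {
    subset <- seq_len(ncol(table))
  } else {
    sel <- if (recipe == "A1") {
      preselect_lasso(table, metadata, max_features = max_features, seed = seed)
    } else {
      preselect_stability(table, metadata, n_subsamples = n_subsamples,
                          max_features = max_features, seed = seed)
    }
    inv <- select_invariant(sel, table, metadata, alpha = alpha,
                            max_subset_size = max_subset_size)
    subset <- inv$invariant_features
    fell_back <- length(subset) == 0
    if (fell_back) {
      warning("invariance selection returned no features for recipe ",
              recipe, "; falling back to the preselection pool")
      subset <- sel$selected
    }
    if (length(subset) == 0)
      stop("preselection pool is empty for recipe ", recipe,
           "; cannot fit a model")
  }
  model <- tune_lambda(table, metadata, subset = subset,
                       grid_size = grid_size, repeats = repeats,
                       folds = folds, seed = seed, recipe = recipe)
  model$selection <- sel
  model$invariance <- inv
  model$fallback_used <- recipe != "B" && fell_back
  model
}
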