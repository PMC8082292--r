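## Internal numerical helpers shared by preselection, invariance and the
## classifier. None of these are exported.

## Column standardization; constant columns get scale 1 so they stay
## harmless (zero after centering) instead of producing NaN.
standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

## Class-stratified fold assignment: within each class, shuffle and deal
## folds round-robin. Guarantees both classes in every fold whenever each
## class has >= folds members.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    id[ix[sample.int(length(ix))]] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

## Class-stratified subsample of round(fraction * n_class) per class
## (at least 1), so both classes are always represented.
stratified_subsample <- function(y, fraction) {
  unlist(lapply(unique(y), function(cl) {
    ix <- which(y == cl)
    m <- max(1L, round(fraction * length(ix)))
    ix[sample.int(length(ix), m)]
  }), use.names = FALSE)
}

## Smallest penalty that zeroes every lasso coefficient for a standardized
## logistic problem (KKT condition at the intercept-only fit).
lambda_max_logistic <- function(Xs, y) {
  p0 <- mean(y)
  max(abs(crossprod(Xs, y - p0))) / length(y)
}

log_lambda_grid <- function(lambda_max, grid_size = 50, decades = 3) {
  exp(seq(log(lambda_max), log(lambda_max) - decades * log(10),
          length.out = grid_size))
}

## Logistic fit of y on X (columns = predictors; X may have 0 columns for
## an intercept-only model). Falls back to a tiny ridge penalty when the
## plain ML fit does not converge or separates perfectly.
fit_logistic_stable <- function(X, y, ridge = 1e-4) {
  X <- as.matrix(X)
  if (ncol(X) == 0) {
    p <- mean(y)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    return(list(intercept = stats::qlogis(p), coef = numeric(0),
                ridged = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                    family = stats::binomial())),
    error = function(e) NULL)
  separated <- is.null(fit) || !fit$converged ||
    any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8)
  if (!separated)
    return(list(intercept = fit$coefficients[1],
                coef = fit$coefficients[-1], ridged = FALSE))
  # ridge-stabilized IRLS
  b <- rep(0, ncol(X) + 1)
  Z <- cbind(1, X)
  pen <- diag(c(0, rep(ridge, ncol(X))))
  for (it in seq_len(100)) {
    eta <- drop(Z %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    b_new <- tryCatch(
      solve(crossprod(Z, Z * w) + length(y) * pen, crossprod(Z, w * z)),
      error = function(e) NULL)
    if (is.null(b_new)) break
    if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  list(intercept = b[1], coef = b[-1], ridged = TRUE)
}

predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  eta <- fit$intercept + if (length(fit$coef)) drop(X %*% fit$coef) else 0
  stats::plogis(eta)
}

## Deviance residuals of binary y against fitted probabilities.
deviance_residuals <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  d <- -2 * (y * log(p) + (1 - y) * log(1 - p))
  sign(y - p) * sqrt(pmax(d, 0))
}
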