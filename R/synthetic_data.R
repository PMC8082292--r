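#' Configuration for the synthetic multicenter generator
#'
#' Describes a multicenter cohort with three blocks of features:
#' \describe{
#'   \item{causal}{Gaussian features whose environment-specific means shift
#'     (covariate shift), while the outcome is drawn from one logistic model
#'     on them with coefficients fixed across environments — so the
#'     outcome-given-causal-features mechanism is invariant even though the
#'     marginal outcome prevalence differs by center.}
#'   \item{spurious}{Features generated downstream of the outcome as
#'     `gamma_e * y + noise` with an environment-dependent strength
#'     `gamma_e`, i.e. predictive within any one center but with an
#'     unstable, non-invariant relationship across centers.}
#'   \item{noise}{Features independent of the outcome, carrying
#'     per-environment location/scale batch effects of magnitude
#'     `batch_shift_scale` — the scanner/protocol fingerprint.}
#' }
#'
#' Default cohort structure mirrors a four-hospital glioma cohort:
#' per-center sizes 7/12/36/22 and positive-class (IDH1/2 wild-type)
#' prevalences 3/7, 1/12, 7/36, 15/22. Prevalence differences are realized
#' through the causal mean shifts, never through per-environment intercepts,
#' which would break the invariance the selection method assumes: for each
#' environment the scalar shift applied to every causal feature mean is
#' solved numerically so that the expected positive fraction equals the
#' requested prevalence.
#'
#' @param n_per_env Integer vector of per-environment sample counts.
#' @param prevalence_per_env Target positive-class fraction per environment,
#'   each in (0,1); `NULL` recycles the four-hospital defaults to the
#'   number of environments.
#' @param k_causal,k_spurious,k_noise Feature counts per block.
#' @param beta Logistic coefficients of the causal features (recycled to
#'   length `k_causal`); fixed across environments.
#' @param intercept Global intercept of the outcome model.
#' @param gamma_per_env Outcome-to-spurious edge strength per environment.
#'   The defaults (recycled to the number of environments when `NULL`)
#'   differ strongly across environments so spurious features are clearly
#'   non-invariant; setting all equal (with `batch_shift_scale = 0`)
#'   collapses the shift and makes spurious features legitimately
#'   invariant.
#' @param batch_shift_scale Standard deviation of the per-(environment,
#'   noise-feature) location shifts; also controls the log-scale spread of
#'   the matching variance perturbation.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_env = c(7L, 12L, 36L, 22L),
                             prevalence_per_env = NULL,
                             k_causal = 3L, k_spurious = 5L, k_noise = 200L,
                             beta = c(1.5, -1.0, 0.8),
                             intercept = 0,
                             gamma_per_env = NULL,
                             batch_shift_scale = 0.5,
                             seed = 1L) {
  n_env <- length(n_per_env)
  if (n_env < 2) stop("need at least 2 environments")
  if (is.null(prevalence_per_env))
    prevalence_per_env <- rep_len(c(3 / 7, 1 / 12, 7 / 36, 15 / 22), n_env)
  if (is.null(gamma_per_env))
    gamma_per_env <- rep_len(c(2, 0, -2, 1), n_env)
  if (length(prevalence_per_env) != n_env || length(gamma_per_env) != n_env)
    stop("prevalence_per_env and gamma_per_env must match length(n_per_env)")
  if (any(n_per_env < 1)) stop("every environment needs at least 1 sample")
  if (any(prevalence_per_env <= 0 | prevalence_per_env >= 1))
    stop("prevalences must lie strictly in (0,1)")
  if (k_causal < 1) stop("k_causal must be >= 1")
  if (k_spurious < 0 || k_noise < 0) stop("feature counts must be >= 0")
  beta <- rep_len(as.numeric(beta), k_causal)
  cfg <- list(n_per_env = as.integer(n_per_env),
              prevalence_per_env = as.numeric(prevalence_per_env),
              k_causal = as.integer(k_causal),
              k_spurious = as.integer(k_spurious),
              k_noise = as.integer(k_noise),
              beta = beta, intercept = as.numeric(intercept),
              gamma_per_env = as.numeric(gamma_per_env),
              batch_shift_scale = as.numeric(batch_shift_scale),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

## Expected positive fraction when the linear predictor is
## N(intercept + sum(beta) * delta, sum(beta^2)); plain 1-D quadrature.
expected_prevalence <- function(delta, beta, intercept) {
  mu <- intercept + sum(beta) * delta
  sdv <- sqrt(sum(beta^2))
  f <- function(z) stats::plogis(mu + sdv * z) * stats::dnorm(z)
  stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
}

## Solve for the per-environment causal mean shift hitting a target
## prevalence under the shared outcome model.
solve_mean_shift <- function(target, beta, intercept) {
  s <- sum(beta)
  if (abs(s) < 1e-12)
    stop("sum(beta) is ~0: mean shifts cannot move the prevalence; ",
         "choose coefficients with a nonzero sum")
  stats::uniroot(function(d) expected_prevalence(d, beta, intercept) - target,
                 lower = -50 / abs(s), upper = 50 / abs(s),
                 tol = 1e-9)$root
}

## Synthetic feature names following the <filter>_<class>_<name>_<seq>_<region>
## grammar, so the parser is exercised end-to-end on generated data.
synthetic_feature_names <- function(k_causal, k_spurious, k_noise) {
  filters <- c("original", "wavelet.HL", "wavelet.LH", "wavelet.HH",
               "wavelet2.LL", "log.sigma.2.mm.3D", "log.sigma.3.mm.3D")
  classes <- c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  seqs <- c("T1", "cT1", "T2", "FLAIR")
  regions <- c("L1", "L2", "L3")
  k <- k_causal + k_spurious + k_noise
  role <- c(rep("Causal", k_causal), rep("Spurious", k_spurious),
            rep("Noise", k_noise))
  idx <- seq_len(k)
  paste(filters[(idx - 1L) %% length(filters) + 1L],
        classes[(idx - 1L) %% length(classes) + 1L],
        sprintf("Sim%s%04d", role, idx),
        seqs[(idx - 1L) %% length(seqs) + 1L],
        regions[(idx - 1L) %% length(regions) + 1L],
        sep = "_")
}

#' Simulate a multicenter cohort with known ground truth
#'
#' Draws a cohort according to a [synthetic_config()]: causal features as
#' per-environment mean-shifted Gaussians, the binary outcome from a
#' logistic model on the causal features with coefficients shared by all
#' environments, spurious features as `gamma_e * y + N(0,1)`, and noise
#' features as `N(loc_ej, scale_ej^2)` batch-shifted per environment.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements
#'   \describe{
#'     \item{table}{[feature_table()] of simulated values.}
#'     \item{metadata}{[cohort_metadata()]; outcome levels are `mutant` /
#'       `wildtype` with `wildtype` positive.}
#'     \item{truth}{list with `causal_indices`, `spurious_indices`,
#'       `noise_indices` (disjoint, covering all columns), the `beta` and
#'       `intercept` used, the solved `causal_mean_shift_per_env`, and the
#'       per-environment batch parameters.}
#'   }
#' @examples
#' sim <- simulate_multicenter(synthetic_config(seed = 7))
#' realized_prevalence(sim$metadata)
#' @export
simulate_multicenter <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_env <- length(config$n_per_env)
  n <- sum(config$n_per_env)
  kc <- config$k_causal; ks <- config$k_spurious; kn <- config$k_noise
  k <- kc + ks + kn
  env <- factor(rep(seq_len(n_env), times = config$n_per_env))
  shifts <- vapply(config$prevalence_per_env, solve_mean_shift,
                   numeric(1), beta = config$beta,
                   intercept = config$intercept)

  # causal block + outcome, invariant mechanism
  Xc <- matrix(stats::rnorm(n * kc), n, kc) + shifts[as.integer(env)]
  eta <- config$intercept + drop(Xc %*% config$beta)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))

  # spurious block: outcome-driven with environment-dependent strength
  Xs <- if (ks > 0) {
    gam <- config$gamma_per_env[as.integer(env)]
    matrix(stats::rnorm(n * ks), n, ks) + gam * y
  } else matrix(numeric(0), n, 0)

  # noise block: batch-shifted per environment
  if (kn > 0) {
    loc <- matrix(stats::rnorm(n_env * kn, sd = config$batch_shift_scale),
                  n_env, kn)
    scl <- matrix(exp(stats::rnorm(n_env * kn, sd = config$batch_shift_scale / 2)),
                  n_env, kn)
    Xn <- matrix(stats::rnorm(n * kn), n, kn)
    e <- as.integer(env)
    Xn <- Xn * scl[e, , drop = FALSE] + loc[e, , drop = FALSE]
  } else {
    loc <- scl <- NULL
    Xn <- matrix(numeric(0), n, 0)
  }

  X <- cbind(Xc, Xs, Xn)
  fnames <- synthetic_feature_names(kc, ks, kn)
  ids <- sprintf("sample%03d", seq_len(n))
  tab <- feature_table(X, sample_ids = ids, feature_names = fnames)
  md <- cohort_metadata(ids, environment = paste0("center", env),
                        outcome = ifelse(y == 1, "wildtype", "mutant"),
                        positive_class = "wildtype")
  truth <- list(causal_indices = seq_len(kc),
                spurious_indices = if (ks > 0) kc + seq_len(ks) else integer(0),
                noise_indices = if (kn > 0) kc + ks + seq_len(kn) else integer(0),
                beta = config$beta, intercept = config$intercept,
                causal_mean_shift_per_env = shifts,
                gamma_per_env = config$gamma_per_env,
                batch_loc = loc, batch_scale = scl)
  list(table = tab, metadata = md, truth = truth)
}

#' Per-environment realized outcome prevalence
#'
#' Exact positive-class fraction within each environment of a cohort.
#'
#' @param metadata A [cohort_metadata()].
#' @return Named numeric vector, one fraction per environment.
#' @export
realized_prevalence <- function(metadata) {
  y <- outcome01(metadata)
  r <- tapply(y, metadata$environment, mean)
  stats::setNames(as.numeric(r), names(r))
}
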