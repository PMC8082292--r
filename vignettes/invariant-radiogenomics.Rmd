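---
title: "Invariant feature selection for multicenter radiogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant feature selection for multicenter radiogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiogenomics models predict a genomic label — here the IDH1/2 mutation
status of gliomas, a key prognostic and treatment-selection biomarker —
from quantitative imaging features. Models built on cohorts pooled from
several hospitals routinely degrade when applied to a center they were not
trained on: MRI intensities are not quantitative, and scanner vendor,
field strength and sequence parameters leave center-specific fingerprints
in the feature values. A feature that predicts the outcome only through
such a fingerprint (a *spurious* feature) looks excellent in
cross-validation and fails on new sites.

`radicp` treats each contributing center as an *environment* and selects
features whose relationship with the outcome is **invariant across
environments**, in the spirit of invariant causal prediction (ICP): if
`P(Y | X_S)` is the same in every environment, then `S` is plausibly part
of the stable, transportable mechanism, and a model restricted to `S`
should generalize to unseen acquisition settings.

## The pipeline

1. **Preselection** constrains the combinatorial subset search to a small
   pool (default 20 features):
   * *lasso preselection* — nonzero support of an L1-penalized logistic
     fit at the cross-validation-optimal penalty, ranked by |coefficient|;
   * *stability preselection* — selection frequency across 100
     class-stratified half-subsamples, each refit over a 50-point penalty
     grid spanning three decades; features with frequency ≥ 0.6 are kept.
     The defaults follow common stability-selection practice; the
     subsampling is class-stratified because real multicenter cohorts can
     be extremely imbalanced (a center may contribute a single
     positive case).
2. **Invariance selection** enumerates all subsets of the pool up to size
   4 (including the empty set), computes an invariance p-value for each,
   accepts subsets with `p > α` (α = 0.05), and returns the
   **intersection of accepted subsets**. Whenever the truly invariant
   subset is accepted — probability ≥ 1 − α for a calibrated test — the
   intersection is contained in it; this is the method's family-wise
   guarantee, and the one property the test suite checks empirically.
3. **Classification** fits an L1-penalized logistic model on the selected
   features; the penalty is tuned by 10×3-fold stratified repeated
   cross-validation maximizing the Matthews correlation coefficient (MCC)
   of hard 0.5-threshold predictions. Three recipes are compared: A1
   (lasso → invariance → classifier), A2 (stability → invariance →
   classifier) and B (classifier on all features, the conventional
   embedded approach).
4. **Evaluation** under two scenarios: leave-one-center-out (train on the
   remaining centers, the invariance stage using exactly those centers as
   environments) and a stratified 70/30 split. Reports carry the
   confusion matrix (rows = prediction, columns = reference), AUC with a
   class-stratified percentile-bootstrap 95% CI (2000 replications),
   accuracy/sensitivity/specificity with Wilson score intervals, MCC with
   a stratified-bootstrap CI, pairwise AUC comparisons by paired
   stratified bootstrap with Holm correction, and an exact one-sided
   binomial test of accuracy against the no-information rate (NIR).

## The invariance test

The test is the one genuinely open design choice. For a binary outcome we
use a likelihood-ratio test of the pooled logistic model of outcome on
the subset against the same model augmented with environment main
effects (`df = E − 1`): under invariance the environment terms add
nothing. Because all parameters are estimated jointly by maximum
likelihood, the test stays calibrated under *covariate shift* — centers
may move the feature distributions (different scanners shift feature
means) without triggering false rejections — and it remains usable when a
center contributes only a handful of samples.

A residual-based alternative is exposed as `method = "residual"`: fit on
all environments but one, then compare deviance residuals between the
held-out environment and the fitting complement (Welch test on means and
a Brown–Forsythe-style robust test on scale — the classical
variance-ratio F is not calibrated for the markedly non-normal deviance
residuals of a logistic fit), Bonferroni-combined within and across
environments. This mirrors the regression form of the ICP framework, but
for a binary outcome the residual distribution depends on the local event
probability, which itself moves under covariate shift: in simulations
with strong center-specific mean shifts this construction rejects the
true causal subset essentially always at n = 200 per environment. It is
therefore not the default.

Known limitation of the default test: its alternative is an
environment-specific *calibration* shift. A pure slope reversal between
two environments with identical implied prevalence can escape it; with
three or more environments of varying prevalence (the intended use) this
blind spot is immaterial in our simulations, where spurious subsets are
rejected essentially always.

Degenerate cases: a subset whose model cannot be fitted at all is
rejected with `p = 0` (logged in the tested-set ledger, never silently
skipped); perfect separation is handled by a tiny ridge-stabilized refit.
If *no* subset is accepted, the result is empty with
`fallback_used = TRUE` and downstream recipes fall back to the
preselection pool with a warning — a deliberate choice so that a full
pipeline run always yields a model, while the flag records that the
invariance evidence was insufficient.

## The synthetic generator

Real radiomics cohorts require images and a feature extractor, so the
package verifies its statistics on synthetic multicenter cohorts with
known ground truth (`simulate_multicenter()`):

* **Causal features**: per-environment mean-shifted Gaussians; the binary
  outcome follows one logistic model on them with coefficients *fixed
  across environments* (default β = (1.5, −1.0, 0.8)). Center-specific
  outcome prevalence is realized purely through these mean shifts
  (covariate shift), never through environment-specific intercepts, which
  would destroy the invariance the method assumes. The scalar shift per
  environment is solved numerically so the expected positive fraction
  matches the requested prevalence.
* **Spurious features**: `gamma_e · y + N(0,1)` with the strength
  `gamma_e` differing across environments (default 2, 0, −2, 1) —
  predictive within any one center, unstable across centers. Setting all
  `gamma_e` equal (and `batch_shift_scale = 0`) collapses the shift, and
  the selection may then legitimately retain spurious features: they are
  genuinely invariant in that configuration.
* **Noise features**: independent of the outcome, with per-environment
  location/scale batch effects — the scanner fingerprint.

The default cohort structure mirrors a four-hospital glioma cohort
(center sizes 7/12/36/22; wild-type prevalences 3/7, 1/12, 7/36, 15/22);
dimensionality defaults to 3 causal + 5 spurious + 200 noise features —
the *structure* of the high-dimensional regime, not its full scale, so
that simulation-heavy tests stay fast. Feature names follow the
pyradiomics-style `<filter>_<class>_<name>_<sequence>_<region>` grammar
so the name parser is exercised end to end. What the generator does *not*
emulate: correlated feature blocks, heavy-tailed texture distributions,
nonlinear feature–outcome links, or label noise. Passing tests on this
generator demonstrate the statistical machinery under its stated
assumptions, not performance on real images.

## Numerical and reporting conventions

* Features are standardized to zero mean and unit variance with
  *training* statistics before any penalized fit (constant features get
  scale 1) — the convention that makes one penalty comparable across
  features.
* The penalty grid has 50 log-spaced values over three decades below the
  smallest all-zeroing penalty; ties in mean CV MCC break toward the
  larger penalty (the sparser model).
* MCC of a degenerate confusion matrix (any empty margin) is defined
  as 0, so cross-validation folds with a tiny class never divide by zero;
  the tuner and the evaluation module share one MCC implementation.
* The prediction threshold is fixed at 0.5; no threshold tuning.
* Interval endpoints are *reported* truncated (not rounded) to two
  decimals — the convention that matches published radiogenomics tables —
  with full-precision values always retained.
* Metrics whose denominator is empty (e.g. sensitivity when the held-out
  center has no positive case) are flagged `NA`, never imputed.
* The stratified 70/30 split assigns `round(0.7 · n_class)` of each class
  to training; for a 77-patient cohort with classes 51/26 this gives
  54 train / 23 test.
* CV-performance intervals are percentile intervals over the
  repeats × folds metric values — a convention, flagged as such in
  reports, since published tables rarely state their CV-CI construction.
* All randomness (fold assignment, subsampling, bootstrap, generator) is
  controlled by explicit integer seeds; every seeded stage is
  bit-reproducible, which the test suite asserts.

## Problem sizes used in the verification suite

The statistical properties are checked at sizes chosen to make
Monte-Carlo error small while keeping the suite quick on a laptop:
null calibration of the invariance test on 500 two-environment datasets
(n = 100 each); empirical containment of the invariant set in the causal
set on 100 four-center cohorts at n = 200 per center; bootstrap-CI
coverage on 500 binormal datasets (500 replications each); and the
generalization-gap comparison (recipe B's CV-to-held-out MCC drop versus
A1/A2's) on 50 shift-heavy cohorts at n = 60 per center with reduced
tuning (3 repeats, 30-point grid, 30 stability subsamples) — the full
defaults are used for real analyses.

## Worked example

```{r, eval = FALSE}
library(radicp)

sim <- simulate_multicenter(synthetic_config(n_per_env = rep(50, 4),
                                             k_noise = 50, seed = 1))
res <- run_split(sim$table, sim$metadata, recipes = c("A2", "B"),
                 seed = 1, n_boot = 2000)
res$reports$A2
res$auc_comparisons
selection_frequency_table(list(A2 = res$models$A2$selection))
```

## Limitations

* Environments must be discrete and known; finer acquisition strata
  (scanner model, field strength) can be used instead of centers if
  available, at the cost of smaller per-environment samples.
* The subset enumeration is exponential in the pool size; the default
  caps (pool ≤ 20, subsets ≤ size 4, ≤ 50,000 total) exist because the
  invariance stage is the budget, not the model fit.
* Hidden confounding, nonlinear mechanisms, and instrumental settings are
  out of scope; the guarantee is conditional on the linear-logistic
  invariance model.
* With fewer than three environments, or environments with near-identical
  prevalence, the default test has reduced power against slope-only
  instability (see above).
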