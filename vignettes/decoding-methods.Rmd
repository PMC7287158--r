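---
title: "Decoding methods: models, cross-validation, and permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding methods: models, cross-validation, and permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdecode)
```

This vignette documents the statistical machinery of `mvdecode`: the
models and their assumptions, the cross-validation and preprocessing
semantics, the permutation tests, the numerical and design choices made
where several defensible options existed, and what the synthetic-data
generators do and do not emulate.

## The decoding problem

A dataset is a numeric array with one *sample* dimension (trials,
stimuli), one or more *feature* dimensions (channels, voxels), and
optionally *search* dimensions that the analysis sweeps (time points,
frequencies) or one *generalization* dimension (train at one index,
test at all). For each `[samples x features]` slice the engine
estimates how well a model predicts the class label or response from
the feature pattern, using cross-validation so that the estimate refers
to unseen data. The result is a metric laid out over the search grid —
a time course of accuracies, a train-time × test-time matrix, a
searchlight map.

## Classifiers

**Binary LDA.** Assumes each class is multivariate Gaussian with a
class-specific mean and a *common* covariance. Under that model the
Bayes-optimal boundary is linear: `w = Sigma^-1 (m1 - m2)`. Two
departures from the textbook estimator matter in the p ≈ n regimes
typical of neuroimaging:

* *Shrinkage.* The pooled covariance (within-class centered samples,
  denominator n − 2) is blended with a scaled identity,
  `Sigma_reg = (1 - lambda) Sigma_emp + lambda * nu * I`,
  `nu = trace(Sigma_emp)/p`. The scaling by `nu` preserves total
  variance, so `lambda = 1` yields a correctly scaled spherical
  covariance rather than a unit one. By default `lambda` is estimated
  by the Ledoit–Wolf closed form from the class-centered samples and
  clipped to [0, 1]; zero dispersion of the empirical covariance around
  the target (e.g. zero scatter) yields 1.
* *Bias placement.* `b = -w.(m1 + m2)/2 + log(P1/P2)`. With equal
  priors the boundary passes through the geometric midpoint of the
  class means; with empirical priors (the default) it shifts toward the
  rarer class, which is the MAP rule for the Gaussian model. A
  `prior = "equal"` flag forces equal priors. The class-1 posterior is
  then exactly `plogis(dval)`.

**Multiclass LDA.** Between-class scatter against shrinkage-regularized
within-class scatter, solved as a symmetric whitened eigenproblem; the
data are projected on the leading K − 1 discriminants scaled so the
within-class covariance in the subspace is the identity. The decision
rule is open in the formulation we follow (MAP vs. nearest centroid);
we chose MAP with equal identity covariances in the subspace —
`argmax_k [-||z - c_k||^2/2 + log P(k)]` — which reduces to nearest
centroid under equal priors but respects class frequencies otherwise.

**Gaussian naive Bayes.** Per-class, per-feature univariate Gaussians
(unbiased variances), i.e. a class-specific *diagonal* covariance —
the complementary relaxation to LDA's shared dense covariance.
Posteriors are evaluated in the log domain; zero variances are floored
at `1e-10` times the mean feature variance (with a warning) so constant
features degrade gracefully instead of producing infinities.

**Logistic regression.** Minimizes the logistic loss with classes coded
±1. The default penalty is log-F(1,1) on each weight
(`log(1 + exp(w_j)) - w_j/2`, maximal prior density at 0): it has no
tuning parameter and keeps the optimum finite on separable data, where
the unpenalized MLE diverges. The alternative is an L2 penalty
`lambda ||w||^2` with user-chosen or grid-tuned `lambda`. The bias is
never penalized: penalizing it would make the solution depend on an
arbitrary labeling convention. Solver: Newton steps with Armijo
backtracking, convergence at gradient norm ≤ 1e-6 (configurable),
at most 200 iterations; a model that fails to converge is returned with
`converged = FALSE` and a warning rather than an error.

**SVM.** The two-class L1 soft-margin problem is solved entirely in its
dual. The bias is absorbed by augmenting the kernel with a constant
feature (`k + 1`), which keeps the dual box-constrained only — there is
no equality constraint — so each coordinate has a closed-form clipped
update and convergence is monitored by the largest projected-gradient
violation per sweep (default tolerance 1e-3, the customary loose
setting for decoding workloads where the decision sign matters more
than the last digits of alpha; tighten `tol` for KKT-grade solutions).
The augmentation means the constant is regularized like a weight — the
standard trade-off of coordinate-descent SVM solvers; the hand-solvable
two-point problem and the QP-oracle tests in the suite quantify that
this does not move decisions. Platt calibration (fitted on the training
decision values when `prob = TRUE`) uses the smoothed targets
`(N1+1)/(N1+2)` and `1/(N2+2)`, so probabilities never saturate at 0/1.

**Kernel FDA.** The Fisher criterion in the kernel-induced feature
space: `alpha = (N + lambda I)^-1 (M1 - M2)` with class kernel means
`M_i` and within-class kernel scatter `N`. Ridge regularization is
applied to `N` directly (default `lambda = 0.01`); the bias centers the
projected class means symmetrically about zero. With a linear kernel
and matched (vanishing) regularization, predictions coincide with
binary LDA — one of the suite's equivalence oracles. Multiclass KFDA is
out of scope.

**Ensembles.** Seeded random sample/feature subsets per learner;
`vote` (plurality, ties toward the smallest class index — deterministic
and documented, rather than a hidden RNG draw) or `dval` (sign of the
mean decision value). Subsets that lose a class are redrawn
deterministically.

## Regression

Ridge regression keeps the formalism where the intercept is a constant
column of `X`, penalized like any coefficient; a `centerIntercept`
flag switches to the common practice of centering X and y and leaving
the intercept unpenalized. The primal and dual closed forms are
algebraically identical; `form = "auto"` picks the cheaper one
(primal when n ≥ p) and never changes predictions. Solves use
symmetric positive-definite factorizations via `solve()` on the
Gram/kernel systems; `lambda = 0` is allowed and reduces to OLS, with a
clear error if the system is singular. Kernel ridge is the dual form
written in kernel evaluations; with a linear kernel it equals dual
linear ridge without intercept (tested).

## Kernels

Linear, polynomial `(gamma x.x' + coef0)^degree`, RBF
`exp(-gamma ||x - x'||^2)`, and precomputed. The default RBF/polynomial
`gamma` is `1/p`, the scale-free convention that makes the kernel
insensitive to feature count. Precomputed kernel matrices are accepted
everywhere raw data are, *except* under a generalization dimension:
there the train-time and test-time feature spaces differ per cell, so a
single precomputed matrix is ill-defined and the drivers refuse it.
Self-kernels are symmetrized exactly after computation to suppress
floating-point asymmetry.

## Cross-validation, preprocessing, tuning

Fold plans are seeded and reproducible. Stratification (default for
classification) assigns each class's shuffled samples cyclically across
folds with a rotating offset, so per-class fold counts differ by at
most one and total sizes stay balanced. `cv = "none"` trains and tests
on all data and is reported as what it is — an optimistically biased
training-set metric (the suite checks the bias direction).
Repetitions re-randomize folds via per-repeat seed streams; metrics are
averaged with weights proportional to test-fold sizes within a
repetition, then averaged across repetitions.

Preprocessing is strictly fit-on-train / apply-to-test. Sampling steps
(under-/oversampling) alter only the training fold — resampling the
test fold would bias the metric's class balance. Sample averaging
applies to both folds, each side with fresh seeded within-class groups
(averaging the test fold too raises its signal-to-noise symmetrically);
remainder samples form a smaller final group. The leakage guarantee is
tested by perturbation probes: arbitrarily corrupting test-fold rows
changes neither fitted preprocessing state, nor tuning choices, nor
trained parameters.

Hyperparameter entries given as vectors of length > 1 are candidate
lists; the Cartesian product is scored by inner cross-validation
(default 5-fold) on the training fold only, ties broken by grid order
(deterministic). The winner is retrained on the full training fold.
mse/mae are minimized, all other metrics maximized.

## High-level drivers

One fold plan is generated per run and shared across all grid points,
which is why the time×time diagonal equals the across-time result
*exactly*, not just statistically. Searchlight neighbourhoods are
binary membership matrices per search dimension (unit diagonal
enforced); boundaries are truncated, not wrapped — spatial and temporal
axes are not periodic. Helpers build 1-D radius and 3-D cube
neighbourhoods. Only binary membership is supported; weighted
neighbourhoods would need a weighting convention for concatenated
features that the formulation we follow does not define.

## Statistics

*Binomial test*: exact tail `P(X >= k)`, `k = round(accuracy * n)` —
appropriate only for accuracy, and only as an approximation when folds
are not independent.

*Level-1 permutation test*: the full label vector is shuffled and the
*entire* cross-validated analysis is rerun per permutation (shuffling
within folds would preserve the train/test split structure under the
null only partially). p-values use the add-one rule
`(1 + #{null >= obs})/(1 + nPerm)`, so `min p = 1/(1 + nPerm)` and the
test is valid at finite permutation counts.

*Cluster permutation test*: elements above an absolute critical value
form connected clusters — orthogonal grid connectivity by default
(2-neighbour in 1-D, 4 in 2-D, 6 in 3-D), or an explicit adjacency
matrix — and the cluster *mass* (sum of member values; size available
by flag) is compared against the permutation distribution of the
maximal cluster statistic. Mass was chosen as the default because it is
sensitive to both extent and strength. Note the corrected inference is
about clusters, not elements: a significant cluster may contain
elements whose uncorrected p would not pass.

*Level-2 tests*: within-subject (vs. a null value, or paired), null by
per-subject sign flips of the whole difference map — flipping whole
maps preserves the spatial correlation structure under the null;
between-subjects, null by group reassignment. Statistics: mean, t,
Wilcoxon signed-rank (within) / rank-sum (between), two-sided by
default via absolute values.

## Synthetic data: what it emulates, what it does not

The generators produce: Gaussian class clouds with controllable mean
separation and isotropic/diagonal/random-SPD covariance; ERP-like
trials (white noise per channel/time, optionally smoothed with a
variance-preserving moving average, plus a class-dependent spatial
pattern inside one or more effect windows — two windows sharing one
pattern create the off-diagonal generalization blocks the time×time
driver should find); linear regression data `y = Xw + noise`; and
multi-subject metric maps (null value + regional effect +
between-subject Gaussian noise). Defaults are unit-variance Gaussian
noise and balanced classes.

What passing tests on these data show: the estimators, the engine, and
the tests behave correctly under their stated assumptions — chance
level is recovered, planted effects are localized, type-I error is
controlled. What they do not show: robustness to the realistic features
the generators omit — 1/f spectra and strong spatio-temporal
correlation, artifacts and outliers, unbalanced designs with
trial-order confounds, hemodynamic smearing. Conclusions about real
recordings still require the usual experimental controls.

## Numerical choices and degenerate inputs

* Seeds: every random operation derives a child seed from the run seed
  and a stream label, inside a scope that restores the caller's RNG
  state — library calls never disturb user-level randomness.
* Ties: decision value exactly 0 predicts class 1; ensemble vote ties
  and tuning ties go to the smallest index / first candidate.
* Degenerate inputs fail loudly and specifically: a single observed
  class, mismatched lengths, non-finite values, singular systems at
  zero regularization (with the remediation hint to increase lambda),
  `group_size` larger than a class, PCA components above rank (clipped
  with a warning), degenerate all-equal decision values in Platt
  calibration.
* AUC uses mid-ranks, counting ties as 1/2, and is invariant under
  strictly monotone transforms of the decision values (tested).

## Test problem sizes

The suite's statistical checks run at deliberately small scales chosen
for tight Monte-Carlo error at interactive runtimes: chance-level
recovery uses 20 simulation seeds of n = 300 (3 classes) and n = 400
(8 classes) with 10-fold × 5-repeat cross-validation; AUC calibration
uses 1000 seeds of 100 + 100 decision values; type-I calibration uses
500 null datasets × 39 permutations for the level-1 and level-2 tests
(39 and 99 permutation counts make alpha = 0.05 exactly attainable
under the add-one rule) and 400 datasets × 99 permutations for the
50-element cluster/elementwise comparison.

## Known limitations

Two-class only: logreg, SVM, kernel FDA, AUC/dval/tval metrics. One
generalization dimension. No missing-value handling, no categorical
features, no CSP/Riemannian features, no support vector regression, no
lasso/elastic net, binary (unweighted) searchlight neighbourhoods, and
no parametric (random-field) multiple-comparison corrections.
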