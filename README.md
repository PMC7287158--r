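# mvdecode

Multivariate pattern decoding for multi-dimensional neuroimaging-style
data in R.

In EEG/MEG/fMRI experiments, the question is rarely whether a single
channel responds to a condition, but whether the *pattern* of activity
across many channels or voxels carries information about it. `mvdecode`
answers that question with supervised learning: a classifier (or
regression model) is trained to predict the experimental condition from
the feature pattern, its cross-validated performance is swept over the
remaining data dimensions (time points, frequencies, voxel
neighbourhoods), and the resulting metric maps are tested for
significance with permutation statistics. The package is aimed at
cognitive-neuroscience analysts who want a complete, scriptable decoding
pipeline on plain R arrays, and at methodologists who need natively
implemented, testable model code rather than wrappers.

## What is inside

**Models** (all trained natively, exposed as `train*/predict*` pairs and
through a registry for `crossValidate()` and the drivers):

- `lda` — binary linear discriminant analysis under the equal-covariance
  Gaussian model. The pooled covariance Σ is shrinkage-regularized,
  Σ\_reg = (1−λ)Σ\_emp + λν*I* with ν = tr(Σ\_emp)/p, λ estimated by the
  Ledoit–Wolf formula when not fixed; w = Σ\_reg⁻¹(m₁−m₂),
  b = −wᵀ(m₁+m₂)/2 + log(P₁/P₂).
- `multiclass_lda` — generalized eigendecomposition of between- vs
  regularized within-class scatter; MAP prediction in the whitened
  (K−1)-dimensional discriminant subspace.
- `naive_bayes` — per-class, per-feature univariate Gaussians combined
  under conditional independence; log-domain posteriors.
- `logreg` — logistic regression minimizing
  Σᵢ log(1+exp(−yᵢ(wᵀxᵢ+b))) with log-F(1,1) (default,
  hyperparameter-free, finite on separable data) or L2 penalty; Newton
  solver with backtracking.
- `svm` — two-class L1 soft-margin SVM solved in the dual
  (max Σαᵢ − ½αᵀQα, 0 ≤ αᵢ ≤ c) by coordinate descent, bias via
  constant-feature kernel augmentation; linear, polynomial, RBF, or
  precomputed kernels; optional Platt probability calibration.
- `kernel_fda` — kernel Fisher discriminant (dual weights
  α = (N+λI)⁻¹(M₁−M₂) from the within-class kernel scatter N and class
  kernel means Mᵢ).
- `ridge` / `kernel_ridge` — ‖y−Xw‖² + λ‖w‖² with automatic
  primal/dual switching (w = (XᵀX+λIₚ)⁻¹Xᵀy or Xᵀ(XXᵀ+λIₙ)⁻¹y), and the
  kernelized dual α = (K+λIₙ)⁻¹y, f(x) = Σᵢ αᵢ k(xᵢ,x).
- `prototype` — nearest-centroid classifier, the worked example of the
  `registerModel()` extension point.

**Engine**: stratified/repeated k-fold, leave-one-out, holdout,
predefined and training-set fold plans; nested preprocessing
(z-scoring, demeaning, PCA, under-/oversampling, sample and kernel
averaging) fitted on training folds only; nested grid-search
hyperparameter tuning; metrics per Table-of-metrics conventions
(accuracy, rank-based AUC, confusion, per-class decision values, f1,
Cohen's kappa, precision, recall, pooled-variance t on decision values,
mae/mse/R²) with test-size-weighted fold averaging.

**Drivers**: `mvClassify()` / `mvRegress()` sweep any search dimensions
of an N-dimensional array, handle one generalization dimension
(train-at-t, test-at-t′, e.g. time×time decoding) and searchlight
neighbourhoods; `mvClassifyAcrossTime()` and `mvClassifyTimextime()`
cover the common 3-D [samples × features × time] cases.

**Statistics**: exact binomial test for accuracy; level-1 permutation
test (label shuffling, full re-analysis per permutation, add-one
p-values); cluster-based permutation correction (suprathreshold
clusters, mass statistic, max-cluster null); level-2 within-subject
(vs. a null value or paired, sign-flip null; mean/t/signed-rank) and
between-subjects (group reassignment; mean/t/rank-sum) permutation
tests, with optional cluster correction.

**Synthetic data**: seeded generators for Gaussian class clouds,
ERP-like epoched trials with planted spatiotemporal effects,
linear-model regression data, and multi-subject metric maps — every
analysis in the package is testable without external recordings.

## Worked example

Decode a planted ERP-like effect (two classes, 16 channels, 20 time
points, effect confined to time points 8–12):

```r
library(mvdecode)

g <- genErpLike(60, nChannels = 16, nTime = 20, K = 2, amplitude = 1.2,
                windows = list(8:12), seed = 7)
cfg <- list(model = "lda", metric = c("accuracy", "auc"),
            k = 5, `repeat` = 2, seed = 1)
r <- mvClassifyAcrossTime(cfg, g$X, g$clabel)
round(as.numeric(metricValues(r, "accuracy")), 3)
#>  [1] 0.504 0.525 0.621 0.588 0.513 0.462 0.450 0.817 0.883 0.900 0.875
#> [12] 0.867 0.492 0.500 0.496 0.475 0.429 0.525 0.508 0.458
```

Accuracy sits at chance (≈0.5) outside the effect window and rises to
0.90 inside it. Is the peak significant? The binomial test on the peak
accuracy (60 test trials, chance 0.5):

```r
pValues(binomialTest(0.9, 60, chance = 0.5))
#> [1] 4.86e-11
```

A non-parametric check at one time point — shuffle the labels 99 times
and redo the full cross-validated analysis:

```r
l1 <- permutationTestLevel1(list(model = "lda", metric = "accuracy",
                                 k = 5, seed = 1),
                            g$X[, , 10], g$clabel,
                            nPermutations = 99, seed = 2)
pValues(l1)
#> [1] 0.01
```

p = 0.01 is the smallest value 99 permutations can produce under the
add-one rule — no shuffled run matched the observed accuracy. Temporal
generalization (train at every time point, test at every other) with
the same configuration returns a 20×20 matrix whose diagonal equals the
across-time result above:

```r
tt <- mvClassifyTimextime(cfg, g$X, g$clabel)
dim(metricValues(tt))
#> [1] 20 20
mean(diag(metricValues(tt))[8:12])
#> [1] 0.868
```

A command-line face for file-based workflows (CSV/NPY data, JSON
configs) ships as `inst/scripts/mvdecode.R` with subcommands
`classify`, `regress`, `stats`, and `simulate`.

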