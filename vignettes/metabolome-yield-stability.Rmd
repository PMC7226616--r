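---
title: "Metabolome-based yield prediction with LASSO stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolome-based yield prediction with LASSO stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metayield)
```

## The problem

Field metabolomics studies of cereals profile tens to hundreds of metabolites
in source organs (the flag leaf and the spike bracts — glumes and lemmas) over
a factorial design of genotypes, trials, growing conditions (water-stressed
vs high-yielding) and developmental stages, and ask which metabolites predict
grain yield. The statistical difficulty is the shape of the data: per
organ-stage combination there are typically only a few dozen plots but many
collinear metabolite intensities, so ordinary regression is ill-posed and any
single model fit is fragile. `metayield` implements the inference chain that
has become standard for this setting:

1. **Missingness filter** — metabolites with more than 10% missing cells over
   all samples are removed (strictly greater than; a column at exactly 10% is
   kept).
2. **KNN imputation** — remaining gaps are filled from the `k = 10` nearest
   samples, with distances computed on unit-variance columns over mutually
   observed metabolites and rescaled by the number of shared observations,
   and values combined by inverse-distance weighting.
3. **Optional log2 transform** — models are fit on raw and/or log2
   intensities; `compare_scales()` reports both and recommends the scale with
   the higher validation performance.
4. **Penalised regression** — grain yield is regressed on all metabolites with
   an L1 penalty (the lasso), which performs variable selection and handles
   p close to or above n.
5. **Stability resampling** — the lasso is not fit once but on 100 random
   75/25 train/validation splits. Per split we record training R², adjusted
   R², RMSE, and the *predictive ability*: the squared Pearson correlation
   between predicted and observed yield on the held-out 25%. Per metabolite
   we record the *detection rate* (DR): the fraction of splits in which it
   received a nonzero coefficient.
6. **Refit and variance partitioning** — metabolites with DR ≥ 70%
   (inclusive) enter an ordinary multiple regression on the whole data and on
   the water-stressed and high-yielding subsets separately, with each
   feature's share of yield variance reported.

## The model and its estimator

The core estimator minimises, for penalty $\lambda \ge 0$,

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 + \lambda\lVert\beta\rVert_1$$

by cyclic coordinate descent on standardised features (columns centred and
scaled by the $n-1$ standard deviation). The intercept is never penalised.
Each coordinate update is the soft-thresholding operator
`soft_threshold(z, gamma) = sign(z) * max(|z| - gamma, 0)`. Fits report
coefficients on both the standardised and the original scale, and every
converged fit can be certified with `kkt_violation()`: active coordinates must
satisfy $X_j^\top r/n = \lambda\,\mathrm{sign}(\beta_j)$ and inactive ones
$|X_j^\top r/n| \le \lambda$, within $10\times$ the convergence tolerance.

The penalty is chosen by inner 5-fold cross-validation over a log-spaced grid
of 100 values from $\lambda_{\max}$ (the smallest penalty with an all-zero
solution) down to $10^{-3}\lambda_{\max}$, minimising mean validation MSE
(`rule = "min"`; a one-standard-error rule is available). Standardisation and
penalty selection happen strictly inside training rows — validation rows are
transformed with training parameters, so no information leaks.

### Numerical choices

* Coordinate order is cyclic (not random) for bit-reproducibility; paths are
  warm-started from the previous penalty.
* Single fits converge when the largest coefficient update in a full sweep is
  below `tol = 1e-8`. Inner-fold *selection* paths use a selection-grade
  tolerance of `1e-5` and stop early once the training deviance ratio exceeds
  0.999 (a saturated fit cannot win the validation comparison); penalties
  beyond the shortest fitted fold path are excluded from the grid. We
  verified that the selected penalty is unchanged relative to running the
  fold paths at `1e-6` without truncation.
* Ties on the CV grid go to the largest (sparsest) penalty.
* A zero-variance column inside a training set simply receives a zero
  coefficient for that run (counted as not selected), with a warning.
* If the predicted validation values are constant (an empty model), the
  predictive ability is defined as 0 rather than left undefined.
* Adjusted R² uses $1-(1-R^2)(n-1)/(n-p-1)$ with $p$ = number of *selected*
  features; with $p$ = all candidates it would be undefined whenever
  $p \ge n$, which is the usual situation here. It is flagged `NA` when
  $n \le p+1$.

## The resampling design

The resampling scheme is 100 independent random subsets of 75% of the plots
(the remaining 25% validating each), the operationally precise description of
repeated-subsampling validation; a literal 20-repeats-of-5-fold mode
(training on 4/5 of the data) is available via `make_splits(mode = "kfold")`
for comparison. Stratified splitting by a design column (e.g. growing
condition) uses largest-remainder allocation so that the total training size
is exact and level proportions are preserved.

Detection counts a metabolite when its coefficient is nonzero at the selected
penalty — no effect-size threshold. Mean effects are reported both
zero-inclusive (shrinkage-honest: zeros from unselected runs pull the average
towards zero) and zero-exclusive (the average over selected runs only), since
published effect tables rarely state which convention they use. Run metrics
are averaged as plain means across runs.

## The refit stage

`select_by_dr()` applies the DR ≥ 0.70 threshold inclusively and orders
features by descending DR, then descending absolute mean effect. The refit is
ordinary least squares; the per-condition fits re-estimate coefficients on
the subset rows but reuse the globally selected feature set (selection
happens once, on the pooled data). Variance shares come in two flavours:

* `sequential_dr` (default): Type-I incremental R² with features entered in
  selection order. Shares telescope to the model R² exactly and are
  nonnegative by construction.
* `lmg`: incremental R² averaged over predictor orderings — exact over all
  $2^p$ subsets with combinatorial weights for $p \le 10$, estimated from
  1000 sampled orderings for $11 \le p \le 20$, and refused above 20 features
  unless a sampling count is given.

No post-selection inference correction is applied to the refit p-values;
they are conditional on the selection and should be read as descriptive, not
as calibrated tests. This is a known caveat of the procedure.

## The synthetic-data generator

No raw data accompany studies of this kind, so validation rests on a
generator that emulates the study conditions with known ground truth:

* **Design**: full factorial, by default 5 genotypes × 4 trials × 3
  replicates per organ-stage cell (60 plots per cell; 3 organs × 2 stages =
  360 organ samples). The first half of the trials is grouped as
  water-stressed (WS), the rest as high-yielding (HY).
* **Intensities**: log2-scale multivariate normal with block-exchangeable
  correlation (`block_rho`, default 0.5 within 8 blocks — emulating pathway
  co-regulation), per-metabolite baselines N(10, 1), within-cell residual SD
  1 (exposed as a parameter; field studies do not report it), plus additive
  organ / stage / condition / genotype shifts drawn with SDs 0.5 / 0.3 / 0.4
  / 0.2 on the log2 scale. Raw intensities are $2^{\text{log2 values}}$,
  hence strictly positive; effects additive on log2 are multiplicative on
  raw, as relative intensities behave.
* **Yield**: generated from the *log2* intensities as
  $GY = \beta_0 + \log_2(X)\,\beta + s\,\mathbf{1}[\text{WS}] + \varepsilon$,
  with intercept 6 (a t/ha-like scale), WS penalty $s = -2$ (roughly the
  one-third yield loss typical of severe Mediterranean water stress),
  $\varepsilon \sim N(0, 1)$, and a sparse $\beta$: 10 nonzero entries of
  equal magnitude and random sign, scaled so the metabolite signal explains
  `target_r2 = 0.7` of the metabolite-plus-noise yield variance. Because
  yield is built from log2 intensities even when the pipeline runs on raw
  ones, the raw-vs-log2 model comparison is meaningful. The realised signal
  fraction is attached to the trait table as `attr(, "r2_true")`.
* **Missingness**: MCAR per column by default, with most columns at low
  rates and roughly one in ten above the 10% filter threshold so the filter
  is exercised; an abundance-dependent left-censoring mode
  (`mechanism = "censored"`) is available because GC-MS missingness is often
  intensity-related. True values under the mask are retained internally so
  imputation accuracy can be scored; all observed-data code paths read
  through the mask.
* **Reproducibility**: one root seed; every stochastic stage derives its own
  sub-stream via `derive_seed(seed, tag)`, so any stage can be re-run in
  isolation bit-identically.

### What the generator does not emulate

Real GC-MS data have heavy-tailed intensity distributions, batch and
injection-order drift, correlated (not exchangeable) pathway structure,
detection limits that censor jointly across co-eluting compounds, and
genotype-by-environment interactions in the yield model. Passing the
simulation batteries therefore demonstrates that the *procedure* is
implemented correctly and calibrated under its own assumptions — not that it
will achieve any particular accuracy on field data.

## Validation batteries and what they show

The test suite validates each stage at the study's own scale (one
organ-stage cell: n = 60 plots, 80 metabolite candidates, 100 resampling
runs; larger Monte-Carlo settings are scaled to a few seeds so the default
suite runs in minutes):

* **Solver correctness** — KKT certificates on random instances, exact
  agreement with the normal equations at $\lambda = 0$, closed-form
  soft-thresholding on orthonormal designs, objective dominance over a fine
  grid search at small p, and coefficient agreement with an independent
  lasso implementation on identical standardised data.
* **Null calibration** — with all true effects zero, the mean predictive
  ability stays below 0.10. Note that even under the null, the *maximum*
  spurious detection rate is occasionally high: at n = 60 and p = 80 some
  noise column has sampling correlation ≈ 0.35 with yield, and min-MSE
  penalty selection will pick it persistently in some data realisations.
  High DR alone, without validation performance, is therefore not evidence
  of signal.
* **Recovery limits** — with 10 equal-magnitude effects jointly explaining
  70% of yield variance, each feature's standardised effect is ≈ 0.48
  (marginal correlation ≈ 0.26 at n = 60), and neither this implementation
  nor an independent cross-validated lasso recovers *all* ten features at
  DR ≥ 0.70, nor reaches mean validation predictive ability 0.5 — the
  selected feature set is unstable at these sizes. The oracle OLS fit on the
  true features does reach R² 0.6–0.8, and the DR-thresholded refit is
  overwhelmingly F-significant in every replicate: the pipeline finds a
  *predictive subset*, not the complete causal set. This is the realistic
  operating regime of the method and is documented rather than hidden.
* **Preprocessing contracts** — exact filter boundary behaviour, bit-exact
  preservation of observed cells, and KNN beating column-mean imputation on
  block-correlated data, with error decreasing in the block correlation.
* **Determinism** — two pipeline runs from one configuration produce
  byte-identical output files.

`scripts/acceptance.R` recomputes these quantities from scratch against the
installed package.

## A worked example

```{r example, eval = FALSE}
design <- build_design()                       # 360 organ samples
sim <- simulate_metabolome(design, seed = 1)   # 80 metabolites + ground truth
traits <- simulate_traits(sim$matrix, sim$truth, seed = 1)
obs <- inject_missing(sim$matrix, sim$truth$missing_rates, seed = 1)

# one model per organ-stage cell, here: flag leaf at anthesis
cell <- obs$design$organ == "flag_leaf" & obs$design$stage == "anthesis"
m <- subset_samples(obs, which(cell)) |>
  filter_by_missingness() |>
  knn_impute() |>
  log2_transform()
y <- traits$GY[match(m$design$sample_id, traits$sample_id)]

st <- run_stability(m, y, make_splits(nrow(m$values), seed = 1))
glance(st)                     # mean R2 / Adj-R2 / RMSE / predictive ability
tidy(st)                       # detection rate and mean effect per metabolite

feats <- select_by_dr(st, 0.70)
refit <- fit_refit(m, y, feats)
tidy(refit)                    # coefficients and variance shares
autoplot(st); autoplot(refit)
```

## Known limitations

* Detection rates are descriptive stability statistics, not error-controlled
  selection (no complementary-pairs or per-family error bound).
* The refit inherits selection bias; its R² and p-values are optimistic.
* KNN imputation assumes missingness ignorable given the neighbours; under
  strong left-censoring a dedicated censored-likelihood imputer would be
  more appropriate.
* The per-metabolite ANOVA fits univariate fixed-effects models with two-way
  interactions and Type-II sums of squares; trial/block random effects are
  out of scope.
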