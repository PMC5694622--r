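---
title: "Verification-bias-corrected ROC surface and VUS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verification-bias-corrected ROC surface and VUS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A continuous diagnostic test $T$ is evaluated against a three-class
ordinal disease status $D \in \{1, 2, 3\}$ (e.g. benign, early stage,
late stage).  The three-class analogue of the ROC curve is the ROC
surface, whose coordinates at a cut-point pair $c_1 \le c_2$ are the
three true class fractions

$$\mathrm{TCF}_1 = P(T \le c_1 \mid D = 1), \quad
  \mathrm{TCF}_2 = P(c_1 < T \le c_2 \mid D = 2), \quad
  \mathrm{TCF}_3 = P(T > c_2 \mid D = 3),$$

and the volume under the surface (VUS) equals the ordering probability
$P(T_1 < T_2 < T_3)$ for independent test values drawn from the three
classes.  A useless test has VUS $= 1/6$ (its surface is the plane of
the triangle with vertices $(1,0,0)$, $(0,1,0)$, $(0,0,1)$); a perfect
test has VUS $= 1$.

The gold-standard disease verification is often given only to a subset
of subjects, typically chosen in a way that depends on the test and on
auxiliary covariates $A$.  Estimating the surface or the VUS from
verified subjects alone ("naive" analysis) is then biased.  When
verification is missing at random (MAR) — $V \perp D \mid (T, A)$ —
the bias can be corrected, and this package implements five corrected
estimators together with their inference.

## Bias-corrected estimators

All estimators share one currency: an $n \times 3$ matrix $\hat D$ of
disease values that replaces the unobserved indicator matrix.  With
$\hat\rho_k(T, A) = P(D = k \mid T, A)$ estimated by multinomial
logistic regression (or K nearest neighbors) on the verified subjects,
and $\hat\pi = P(V = 1 \mid T, A)$ estimated by binary regression on
all subjects:

| method | $\hat D_{ki}$ | needs |
|--------|---------------|-------|
| `full` | $D_{ki}$ | complete verification |
| `fi`   | $\hat\rho_{ki}$ | disease model |
| `msi`  | $V_i D_{ki} + (1 - V_i)\hat\rho_{ki}$ | disease model |
| `ipw`  | $V_i D_{ki} / \hat\pi_i$ | verification model |
| `spe`  | $V_i D_{ki}/\hat\pi_i - (V_i - \hat\pi_i)\hat\rho_{ki}/\hat\pi_i$ | both |
| `knn`  | as `msi`, $\hat\rho$ from KNN | disease model (KNN) |

FI and MSI are imputation estimators, consistent when the disease model
is correct; IPW reweights verified subjects, consistent when the
verification model is correct; SPE combines both and is doubly robust —
consistent if either model is correct.  SPE entries may fall outside
$[0, 1]$ and are deliberately not clipped: clipping would reintroduce
bias.  The KNN variant replaces the parametric disease model with
nonparametric neighbor averaging.

The VUS estimate is the tie-weighted trivariate Mann–Whitney statistic

$$\widehat{\mathrm{VUS}} =
  \frac{\sum_{i,j,l} w(T_i, T_j, T_l)\, \hat D_{1i} \hat D_{2j} \hat D_{3l}}
       {\bigl(\sum_i \hat D_{1i}\bigr)\bigl(\sum_j \hat D_{2j}\bigr)
        \bigl(\sum_l \hat D_{3l}\bigr)},$$

with $w = 1$ for a strictly increasing triple, $1/2$ for one adjacent
tie, $1/6$ for a triple tie and $0$ otherwise.  The triple-tie weight
$1/6$ is forced by the useless-test anchor: if every test value is
identical the statistic must equal $1/6$ exactly.  The ratio
normalisation makes the IPW variant a Hájek-style (ratio) estimator,
so it is invariant to the scale of the weights; the Horvitz–Thompson
alternative (fixed-$n$ denominators) was considered and rejected
because bounded, scale-free behavior is worth more here than exact
unbiasedness of the raw sums.  The statistic depends on test values
only through ranks and ties, hence is invariant under strictly
increasing transformations of the test.

The triple sum is evaluated by a sorted cumulative-sum kernel in C++
(one pass over subjects ordered by test value, $O(n \log n)$), which is
proven equal to the defining $O(n^3)$ triple loop on randomized
instances in the test suite.

## Modeling choices

**Verification model.** `fit_verification()` fits a binomial GLM with
the logit (default) or probit link.  A third option named `threshold`
is accepted for interface compatibility and is implemented as the
complementary log-log link; the term "threshold regression" is
ambiguous in this context, and the alias is documented rather than
silently invented semantics.  Fitted probabilities are floored at
`pi_floor` ($10^{-6}$ by default, configurable, flooring counted in the
returned object) before they are used as inverse weights.  Perfect
separation is reported as an error naming the offending predictor;
because strong true effects legitimately push fitted probabilities to
the numerical 0/1 boundary, separation is flagged only when the
boundary warning coincides with a standardized coefficient magnitude
above 15.

**Disease model.** `fit_rho_mlogit()` fits a multinomial logit with
class 1 as baseline via `nnet::multinom` on verified subjects (valid
under MAR) and predicts $\hat\rho$ for everyone.  Hitting the
iteration cap is an error, not a silent return.  Under the default
synthetic design the class posteriors are exactly multinomial-logit in
$(T, A)$ (equal within-class Gaussian covariances), so FI/MSI/SPE have
a correctly specified disease model there.

**KNN disease model.** `fit_rho_knn()` averages the disease indicator
rows of the $K$ verified subjects nearest in standardized predictor
space (Euclidean distance after centring/scaling by verified-subject
mean and SD, so the fit is exactly invariant to predictor rescaling).
Ties at the $K$-th distance are broken by lowest subject index, making
the fit fully deterministic.  `choose_k()` selects $K$ by V-fold
cross-validation on verified subjects (default 10 folds, seeded fold
assignment), scoring mean squared error between held-out indicator
rows and predictions over a default grid of odd values
$1, 3, \dots, \lceil\sqrt{n_\mathrm{verified}}\,\rceil$; ties go to the
smaller $K$.  MSE was chosen as the loss because the predictions are
probabilities, not hard labels; misclassification loss would ignore
calibration.

## Variance, intervals, test

Two variance routes are provided.

*Jackknife* (`vus_variance_jackknife()`, the default): leave-one-out
over subjects, re-computing the VUS with the fitted disease and
verification probabilities of the remaining subjects held fixed, and
$\widehat{\mathrm{Var}} = \frac{n-1}{n}\sum_i (\widehat{\mathrm{VUS}}_{(-i)} -
\overline{\widehat{\mathrm{VUS}}})^2$.  Holding the fits fixed is a
deliberate choice: it prices the U-statistic variability, which is the
dominant term for SPE (whose estimating function is orthogonal to the
nuisance models when both are correct).  For FI and MSI the
coefficient noise of the disease model enters at first order, so the
fixed-fit jackknife *understates* their variance; use the bootstrap
when honest FI/MSI intervals matter.

*Bootstrap* (`vus_variance_bootstrap()`): nonparametric resampling of
subjects with refitting of all models inside each replicate.
Replicate $r$ uses seed `seed + r` and parallelism distributes whole
replicates, so results are identical for any worker count.  A
replicate that loses an entire verified class, leaves a class with no
estimated mass (possible for SPE under extreme inverse weights), or
degenerates the disease model fit, is redrawn, up to a global cap of
$100B$ attempts.

Confidence intervals are built on the natural scale
($\widehat{\mathrm{VUS}} \pm z\,\mathrm{se}$) and on the logit scale
(delta method, bounds mapped back, hence always inside $(0,1)$); when
an SPE estimate exits $(0,1)$ the logit interval is reported
unavailable with a warning rather than silently clipped.  The
useless-test hypothesis $H_0: \mathrm{VUS} = 1/6$ versus
$H_1: \mathrm{VUS} > 1/6$ uses
$t = (\widehat{\mathrm{VUS}} - 1/6)/\widehat{\mathrm{se}}$ against the
standard normal upper tail; formatted output prints p-values below
$10^{-4}$ as "< 0.0001" while JSON retains full precision.

## Surface geometry

`roc_surface()` evaluates the TCFs on all admissible pairs of a
cut-point grid (default: the unique observed test values with
$\pm\infty$ sentinels, so the simplex vertices are attained exactly).
The interval convention is half-open, right-closed ($\le c_1$,
$(c_1, c_2]$, $> c_2$); any consistent convention partitions the
full-data indicators, and this one matches the "higher test, worse
class" orientation.  `surface_volume()` integrates TCF$_2$ over the
(TCF$_1$, TCF$_3$) footprint as a Riemann sum; with the default grid
and distinct test values it reproduces the tie-free VUS exactly, which
the suite uses as a cross-module consistency check.

`tcf_ellipsoid()` summarises the sampling variability of the TCF
3-vector at a fixed cut-point pair by a bootstrap covariance matrix and
returns the ellipsoid $\{x : (x - \hat c)^\top \Sigma^{-1}(x - \hat c)
\le \chi^2_{3}(\mathrm{level})\}$.  Three degrees of freedom are used
because under bias correction the three estimated TCFs are not linearly
constrained.  A singular bootstrap covariance (e.g. a degenerate test)
is pseudo-inverted and flagged.  The surface is exported as long-format
CSV and as a triangulated OBJ mesh rather than rendered interactively.

## The synthetic-data generator

`simulate_roc3()` emulates a verification-biased study whose default
parameters are the package's reference design: trinomial disease with
$\theta = (0.40, 0.35, 0.25)$; given class $k$,
$(T, A) \sim N_2\!\bigl(k \binom{2}{1},
\bigl(\begin{smallmatrix}1.75 & 0.1\\ 0.1 & 2.5\end{smallmatrix}\bigr)\bigr)$;
and $\mathrm{logit}\,P(V = 1 \mid T, A) = 1 - 2.2\,T + 4\,A$.  The
generating class labels are kept in a `D_true` column so simulation
studies can measure bias, but the analysis contract uses only the
masked label: MAR masking is exactly the verification draw, with no
additional missingness.  `true_vus()` (Monte-Carlo over class-marginal
triples, with standard error) and `true_tcf()` (closed-form normal
CDFs) are the corresponding truth oracles; `true_vus()` is
cross-checked in the suite against one-dimensional numerical
integration of the trivariate ordering probability.

What the generator does *not* emulate: real markers are often skewed
and bounded (the rank-invariance of the VUS makes this mostly
harmless), verification decisions may be discrete policies rather than
smooth logistic functions, covariates may be categorical or missing,
and MAR itself is an untestable assumption.  Passing tests therefore
demonstrate correctness of the estimators under a known MAR mechanism,
not robustness to MNAR verification.

## Numerical behavior under the default design, and limitations

The default design is deliberately harsh for weighting methods: the
linear predictor of the verification model has standard deviation
$\approx 6.8$, so true verification probabilities span essentially
$(0, 1)$ and inverse weights are heavy-tailed (the weight of a
verified subject can exceed $10^3$).  Consequences observed in the
test suite, at the problem sizes it uses (up to $n = 1000$ and 100–200
replicates for the recovery and coverage experiments; up to
$n = 20000$ for single-fit parameter recovery):

* FI, MSI and SPE recover the true VUS with negligible median bias at
  $n = 1000$; the naive verified-only estimator is detectably biased.
* IPW is consistent but skewed at this sample size; its median sits
  one to three Monte-Carlo SEs from the truth depending on the
  replicate set.
* The KNN estimator carries visible negative bias ($\approx -0.07$ at
  $n = 1000$, decaying slowly with $n$): where verification is rare,
  the nearest verified neighbors are systematically displaced, an
  extrapolation bias intrinsic to nearest-neighbor imputation under
  sharp MAR designs.  Prefer the parametric disease model, or use KNN
  only when verified subjects cover the predictor space well.
* SPE is occasionally undefined (an extreme weight empties a class's
  estimated mass); the package raises a clear error, and resampling
  procedures redraw such replicates.
* Jackknife-based normal intervals for SPE at $n = 1000$ achieve
  coverage near but slightly below nominal (the suite's fixed-seed
  experiment gives 92–93%); heavy-tailed weights make coverage
  sensitive to the replicate set, and the bootstrap is the more
  conservative route.

Degenerate inputs are handled explicitly rather than repaired: missing
test or covariate values are rejected (dropping rows would change the
verification mechanism), a disease class absent among verified
subjects is an error, zero estimated class mass is an error, and the
monotone-ordering check — class-conditional means of $T$ strictly
increasing, the simplest operationalization consistent with the
stochastic-ordering assumption — reports rather than raises, with an
explicit override in the pipeline.
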