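---
title: "Stacked ensembles for knowledge-based DVH prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensembles for knowledge-based DVH prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction problem

Knowledge-based planning (KBP) predicts the best achievable organ-at-risk
(OAR) dose-volume histogram (DVH) for a new patient from anatomical features
of previously planned patients. A cumulative DVH gives, for every dose level
$d$ on a shared grid, the fraction of the organ volume receiving at least
$d$; it is monotone non-increasing, starts at 1 at 0 Gy, and lives in
$[0,1]$. `dvhstack` regresses DVHs on a feature vector $x \in \mathbb{R}^P$
(default $P = 9$) supplied by upstream contouring tools.

## DVH compression

Cohort DVHs are compressed by principal component analysis: the mean curve
plus the leading $n_{pc} = 3$ orthonormal components of the centered curve
matrix. Each curve is represented by three principal-component scores (PCS),
and each score is modeled separately. Three components capture essentially
all systematic variation in single-organ cohorts while keeping the
regression targets low-dimensional. Component signs are fixed (largest
absolute entry positive) so bases are reproducible.

Decoding scores back to a curve can leave the $[0,1]$/monotonicity envelope;
the decoder applies the minimal projection onto valid DVHs: clip to
$[0,1]$, enforce monotonicity by a running minimum from low to high dose,
and set the 0 Gy bin to 1. For curves inside the basis span the projection
is the identity, so encode–decode round trips are exact to numerical
precision.

## Base learners

Four linear families fit each score from standardized features
(z-scores with sample SD; constant columns are centered only and flagged):

* **forward stepwise**: at each step the candidate whose coefficient t-test
  (equivalent to the partial F-test) in the extended model has the smallest
  p-value enters if $p <$ `p_enter` (default 0.05); the selected set is
  refitted by ordinary least squares. We use the t-form of the entry
  statistic and 0.05 because the entry rule needs a conventional, scale-free
  threshold; both choices are stated in the documentation rather than
  hidden.
* **ridge / lasso / elastic net**: minimizers of
  $\lVert y - X\beta\rVert_2^2 + \lambda_1\lVert\beta\rVert_1 +
  \lambda_2\lVert\beta\rVert_2^2$ with an unpenalized intercept. The
  objective is kept on the literal residual-sum-of-squares scale (no $1/N$),
  so the all-zero lasso solution occurs exactly at
  $\lambda_1 \ge \max_j |2 x_j^\top y|$ and penalty grids are stated on one
  scale. The solver is cyclic coordinate descent (compiled), converged when
  the largest coefficient change falls below $10^{-8}$.
* Penalty magnitudes are tuned by seeded 5-fold internal cross-validation
  over 20 log-spaced points from $10^{-4}$ to the null-path bound, ties
  toward the larger penalty. Elastic-net bank members hold their
  $\lambda_2/\lambda_1$ ratio fixed while the magnitude is tuned; the six
  default ratios $\{0.1, 0.3, 1, 3, 10, 30\}$ are log-spaced so the bank
  spans lasso-like to ridge-like behavior.

The default bank is therefore nine learners: stepwise, ridge, lasso, and
six elastic nets.

## Stacking on leave-one-out metadata

For each training case $n$ and learner $k$, the learner is fitted on the
other $N-1$ cases (features re-standardized within the fold, penalties
re-selected with the fold seed) and predicts the held-out case, giving the
metadata $z_{kn}$. Stacking weights per score component solve

$$\alpha^* = \arg\min_{\alpha}\ \sum_n \Big(y_n - \sum_k \alpha_k z_{kn}\Big)^2
\quad \text{s.t. } \alpha_k \ge 0,$$

by an exact Lawson–Hanson active-set non-negative least squares
(KKT tolerance $10^{-8}$, lowest-index tie-break). Because every unit vector
is feasible, the stacked internal-CV error never exceeds any single
learner's — the package's central invariant, asserted exactly in the test
suite. The weights are deliberately not constrained to sum to one: stepwise
coefficients tend to be too large (its weight shrinks them), penalized fits
tend to under-fit (their weights expand them). On default synthetic cohorts
the component-1 weight sum sits near 1.0, within the expected 0.5–1.5
diagnostic band.

A `"fixed"` penalty mode that selects each learner's penalties once on the
full set and reuses them inside folds is provided for replicated studies;
it is approximate and labeled as such. Leave-one-out is the default fold
policy because it is the normative definition of the metadata; k-fold is a
configuration option.

## Model-based case filtering

Each case's leave-one-out score predictions are decoded to DVHs and scored
against the clinical curve with wRMSE; the per-case profile is the *median
over the learner bank*, and the worst `s_percent` (default 10%) of cases are
dropped (floor rule, ties to the lower index). After filtering, metadata and
weights are rebuilt from scratch on the retained cases so removed cases
cannot influence $\alpha$; the PCA basis is fitted once on the unfiltered
cohort and kept, because it is a representation rather than a fit to
protect, and keeping it makes filter scores comparable. The filter profile
uses the full 3-component decoded DVH rather than a per-component surrogate
so that the score is in clinically meaningful units.

## The weighted error

$$\mathrm{wRMSE} = \sqrt{\sum_i w''_i\,(\mathrm{DVH}_i - \widehat{\mathrm{DVH}}_i)^2},
\qquad w''_i = \frac{w_i}{\sum_j w_j}.$$

Raw weights: linear 50 at 0 Gy to 100 at the prescription dose (constant
beyond); Gaussian of SD 2 Gy centered at the median dose $D_{50}$ (the
linearly interpolated first downward crossing of volume fraction 0.5),
floored at $10^{-12}$ so weights stay positive; or constant. We use the
*sum-normalized* weights: with an extra factor of $N$ in the normalization
the constant scheme would equal $\sqrt{N}\cdot\mathrm{RMSE}$, which
contradicts the defining property that constant weighting reduces to the
standard RMSE; sum-normalization is the unique scaling with that property.

# The synthetic cohort generator

The generator emulates exactly the statistical structure the method
assumes, so that failures of the method are attributable to the method:

* **Features**: multivariate normal, unit variances, compound-symmetric
  correlation 0.5 — anatomical features (volumes, distance-to-target
  summaries) are strongly mutually correlated in real cohorts.
* **Curve family**: a sigmoid falloff mean (center near half the
  prescription dose, 78 Gy prescription by default) plus three orthonormal
  smooth modes built from the sigmoid's parametric derivatives (shift,
  width, curvature), windowed to the falloff region and tapered to zero at
  0 Gy. Mode 1 is oriented so a positive score means more dose — inferior
  sparing. Within the stated per-mode score budget, raw linear combinations
  are already valid DVHs, so the decoder's projection is inert and the
  feature-to-curve map is exactly linear.
* **Scores**: $\mathrm{PCS} = Bx + \varepsilon$ with Gaussian noise. The
  default $B$ has sparse rows (2–3 active features per mode), scaled so the
  signal SDs are (0.15, 0.08, 0.04); sparsity reflects that a handful of
  geometric quantities drive each DVH mode, and it reproduces the
  documented clinical regime in which shrinkage-heavy learners underfit and
  greedy selection destabilizes at small $N$ — without it all nine learners
  are statistically exchangeable and ensembling has nothing to exploit.
  The noise SD is set to $\sqrt{3/7}$ of the signal SD so a clean
  least-squares fit attains $R^2 \approx 0.7$ on the first score, the
  realistic "partially explainable" regime.
* **Contamination**: anatomical outliers (features shifted 4 SD along the
  equal-loading direction, with a quadratic response departure active only
  beyond 2 SD — locally linear, globally not); dosimetric outliers (mode-1
  score offset $+5\sigma_{\text{noise}}$, i.e. systematically inferior
  sparing); mislabeled cases (a column-reversed coefficient matrix, i.e. a
  different feature-to-dose mapping). Magnitude-zero specs return the
  cohort unchanged, and injected indices are recorded for recall
  evaluation.
* **Scenario presets** fix the four experiment designs: 20/146
  (small training), 40+10/111 (anatomical), 40+10/110 (dosimetric),
  80+10/148 (mislabeled); validation sets are always outlier-free.

What the generator does *not* emulate: real distance-to-target histogram
features, heteroscedastic or heavy-tailed planning noise, multi-organ
trade-offs, and grid-resampling artifacts. Passing tests therefore
demonstrate correctness of the machinery and the method's behavior in its
idealized regime, not clinical performance.

# Numerical and design choices

* Dose grid: 0 to 1.1 × prescription in 111 uniform bins (sub-Gy spacing at
  78 Gy); configurable.
* All randomness (cohorts, CV folds) flows from explicit integer seeds;
  fold $n$ of the metadata loop uses `seed + n`, component $c$ offsets the
  seed by $1000c$. Identical seeds give byte-identical serialized models.
* Coordinate descent and path fits are warm-started large-to-small across
  the penalty grid; the stepwise entry test reuses a Cholesky-based OLS
  with explicit rank checks (rank-deficient candidates simply cannot
  enter).
* Degenerate inputs: all-zero metadata yields zero weights with a warning;
  cohorts whose post-filter size falls below $K + 2$ are rejected before
  any expensive computation; constant feature columns are centered, not
  scaled.
* Training-time problem sizes in the replicated studies: the experiment
  runner defaults to the fixed (approximate) penalty mode with a 10-point
  grid, which preserves the learner bank while keeping a 4-scenario,
  20-replicate study in the minutes range; the normative per-fold mode is
  the `train_ensemble()` default for single fits.

## Known limitations

* With 20% contamination (the 40+10 presets), every leave-one-out fold
  still contains at least nine outliers, so the fold models partially
  absorb the offset and filter recall saturates around 8/10; an oracle
  that knew the normal cases would separate the outliers perfectly, but no
  in-training-set cross-validation can use that oracle.
* In the 20-case clean scenario, dropping 10% of a homoscedastic Gaussian
  cohort is a pure data loss of about 5% validation error, which is the
  same order as the margin separating the ensemble from the best
  individual model; on real cohorts, where the worst decile is genuinely
  less informative, the same filter is reported to help.
* The comparison benchmark "best individual model" is taken as the model
  with the best mean error across replicates (a benchmark a practitioner
  could actually select), not the per-replicate minimum over all nine
  learners, which is an oracle.
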