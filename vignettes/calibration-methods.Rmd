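---
title: "Calibrating variant effect predictors into ACMG/AMP evidence points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating variant effect predictors into ACMG/AMP evidence points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepcal)
```

# The model

A variant effect predictor assigns each missense variant a score $s \in
[0, 1]$, oriented so that higher means more likely damaging. Under the
Bayesian reading of the ACMG/AMP framework, the evidence carried by $s$ is
a likelihood ratio $LR(s)$, and with a prior probability of pathogenicity
$\alpha$ the posterior is

$$\mathrm{posterior}(s) = \frac{\alpha\,LR(s)}{\alpha\,LR(s) + (1-\alpha)}.$$

Evidence strengths map onto the LR scale exponentially. Writing $C$ for
the very-strong odds constant, the threshold for $x$ points is $LR_x =
C^{x/8}$, and $LR_1 = C^{1/8}$ is the supporting-level threshold.
`build_evidence_scale()` solves for $C$ numerically (bisection on $\log C$
over $[1, 10^{12}]$) from a single anchor: the posterior at the minimal
Pathogenic point total of $+10$ must equal $0.99$ at the given prior. This
makes every threshold a pure, monotone function of the prior — lower
priors demand larger LRs for the same strength — which is the package's
resolution of an underdetermined choice: the original points framework
solves several tier constraints simultaneously, but only the
Pathogenic-at-0.99 anchor is needed to reproduce the published point
system, and the anchor (both the point total and the target posterior) is
configurable.

Continuous evidence points are $EP(s) = \mathrm{clip}(\log LR(s) / \log
LR_1,\ -8,\ +8)$. We clip at $\pm 8$ rather than the clinical cap of
$\pm 4$ so that over-confident assignments remain visible to the error
metrics: if the truth at a score is $+5$ and the estimate $+7$, clipping
at $\pm 4$ would hide the two-point error that clipping at $\pm 8$
preserves. Integer points truncate toward zero — a variant must *reach*
$LR_x$ to earn $x$ points — and point totals map to the five tiers at the
published cut-points (Pathogenic $\ge 10$, Likely pathogenic $6..9$, VUS
$0..5$, Likely benign $-6..-1$, Benign $\le -7$).

# Calibration methods

Eleven methods estimate the score-to-posterior map from labeled control
variants. Discriminative methods regress labels on scores: Platt scaling
(logistic in $s$), weighted Platt (inverse class-frequency weights in the
log-likelihood, the package's reading of "class weights for imbalance"),
beta calibration (logistic in $\log s$ and $-\log(1-s)$, with a negative
slope coefficient removed by refitting, preserving monotonicity), isotonic
regression (pool-adjacent-violators), smoothed isotonic (a monotone
piecewise-cubic Hermite interpolant through the step midpoints), a
smoothing-spline calibrator (cubic spline on the logit of an isotonic
pre-fit, smoothing parameter chosen by 5-fold cross-validated log-loss),
and a monotone neural network. Mixture methods fit one density per class —
skew-normal, Beta, or truncated Normal, all renormalized to $[0, 1]$ — and
combine them through Bayes' rule at the training pathogenic fraction
$\alpha'$; this class-conditional reading of a "two-component" model is a
deliberate design choice (the unsupervised alternative, a two-component
mixture per class, is noted but not implemented). The local posterior
method expands a symmetric window around each evaluation score until it
holds at least a fraction `window_frac` of the labeled variants and
`gnomad_frac` of the unlabeled variants, then combines the window's class
rates with the target prior; the nine combinations of `window_frac`
$\in \{0.10, 0.20, 0.30\}$ and `gnomad_frac` $\in \{0, 0.03, 0.06\}$ enter
method selection as nine distinct candidates.

The monotone network is one input, two hidden tanh layers of width 16, and
a sigmoid output; all weights pass through a softplus re-parameterization
so the effective weights are non-negative, which with monotone activations
guarantees a non-decreasing map. It trains by full-batch Adam on the
binomial negative log-likelihood with a seeded 20% validation split and
early stopping (patience 30 evaluation points). This is a self-contained
equivalent of the external monotone-calibration network it stands in for;
equivalence is functional, not bit-level.

Methods that fail to fit are flagged and excluded from selection for that
unit rather than crashing the pipeline.

## Prior shift

Most methods implicitly assume the calibration-set class balance
$\alpha'$ equals the deployment prior $\alpha$. `prior_shift_correct()`
removes the training prior and applies the target one:
$LR = \frac{\rho}{1-\rho}\cdot\frac{1-\alpha'}{\alpha'}$, then
$\mathrm{posterior} = \alpha LR / (\alpha LR + 1 - \alpha)$. Posteriors
are clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-9}$,
before any odds conversion.

## Conservative bootstrap envelopes

`oob_bootstrap_envelope()` resamples the labeled scores with replacement
(1000 rounds at study scale), refits the method, and predicts on the
out-of-bag scores, so each score accumulates roughly $n_{boot}/e$
estimates. The 5th percentile is used where the full-data fit implies at
least $+1$ point, the 95th where it implies at most $-1$, and the
full-data fit itself in the indeterminate region — under-stating rather
than over-stating evidence on both sides. Spline smoothing parameters are
tuned once on the full data and reused across bootstrap refits.

# Simulation engine and miscalibration metrics

Class-conditional score distributions come from four families — Beta,
truncated Normal, truncated Skew-t, truncated Skew-Cauchy — fitted by
maximum likelihood (Nelder-Mead on transformed parameters; truncated
densities renormalized by Simpson quadrature on a 401-point grid during
optimization and a 2001-point grid afterwards). The skew-t and skew-Cauchy
use the standard location/scale/slant (+ degrees of freedom)
parameterization, with the skew-Cauchy fixed at one degree of freedom.
Sampling from truncated families inverts the CDF on the 2001-point grid.

A scenario fixes the pair, the calibration-set size $n \in \{25, 50, 100,
300, 500, 1000\}$, the observed pathogenic fraction $\alpha' \in \{0.05,
0.1, \ldots, 0.9, 0.95\}$ and the true prior $\alpha \in \{0.01, \ldots,
0.1, 0.2, 0.3, 0.4, 0.5\}$ — a grid of $6 \times 11 \times 14 = 924$
scenarios per pair. Calibration sets use deterministic class counts
$\mathrm{round}(n\alpha')$ (reproducibility over faithfulness to an
unstated sampling scheme), and test sets of 1000 draws come from the
$\alpha$-weighted mixture with the closed-form true posterior attached.

Calibration error is measured in evidence points: $\Delta EP(s) =
EP_{est}(s) - EP_{true}(s)$ with both sides clipped at $\pm 8$; MAPE is
the mean $|\Delta EP|$, PFraction the fraction of scores with $\Delta EP >
1$ among scores in the pathogenic region ($EP_{true} > 1$), BFraction the
mirror image. The source texts state the pathogenic region once as
"one or more" and once strictly; the strict reading is the default, with
`region_rule = "ge1"` available, and both are covered by tests. Region
membership uses a $10^{-9}$ guard so scores at exactly one point are
classified consistently under either rule despite floating-point noise in
the log-LR conversion.

# Data-adaptive selection

Genes qualify for gene-specific calibration through tiered rules on the
labeled-control count and pathogenic fraction: 50–99 labeled with
$0.4 \le pfrac \le 0.7$; 100–299 with $0.1 \le pfrac \le 0.9$; $\ge 300$
with $0.05 \le pfrac \le 0.99$ and at least 10 benign controls. The sum
ranges are disjoint, so conditions cannot overlap.

`select_and_calibrate()` fits the best family to each class of the unit,
generates replicate synthetic sets at the unit's own $n$ and $\alpha'$
(30 at study scale), runs every candidate method on each replicate with
the conservative OOB envelope (the conservative posterior, not the point
estimate, is what the safety filter judges — the filter exists to control
over-confidence, so it must see the posterior that will actually be
deployed), prior-corrects to the unit prior, and scores $\Delta EP$
against the closed-form truth. Selection is three-staged: (1) remove
methods whose replicates violate — 75th-percentile regional
over-confidence error above 2 points or maximum above 3, in either region
— more than 25% of the time; (2) keep the three best mean MAPE ranks;
(3) pick the lowest mean PFraction+BFraction rank. Rank ties break by
method name, making selection fully deterministic given the seed; every
stochastic step takes an explicit seed and derives per-replicate child
seeds. Replicate datasets are shared across methods, so comparisons are
paired. Units where every method fails or is filtered out are reported as
uncalibratable rather than given a fallback.

Synthetic replicates carry unlabeled scores (drawn from the
$\alpha$-mixture) only when the real unit has them; local-posterior
configurations that require a population-fraction constraint are excluded
otherwise, since they could not be applied to the unit either.

`hybrid_route()` encodes the deployment strategy: gene-specific
calibration where eligible and successful, otherwise the variant's
domain-cluster thresholds, otherwise the non-domain cluster, otherwise
uncalibrated.

# Positive-unlabeled prior estimation

The prior $\alpha$ is estimated from labeled pathogenic variants (P) and
unlabeled population variants (U) sharing a numeric feature space. An
ensemble (100 members) of L2-regularized logistic classifiers is trained
P-vs-U, each member on a *unique bootstrap*: P and U are resampled
separately, but a variant present in both sets keeps its two copies on the
same side of the train/out-of-bag divide, restoring the leakage guarantee
that plain per-set bootstrapping would break. Each member balances classes
by random under-sampling, z-scores and PCA-projects features to 95%
cumulative variance using its own training sample only, and every variant
is scored by the mean over members that held it out.

The distance-removal curve then repeatedly draws a labeled positive score
(with replacement) and removes the closest unlabeled score, recording the
distance, until U is exhausted. While unlabeled positives remain the
recorded distances stay small; once they are gone the distances jump. The
elbow index over $|U|$ estimates the prior. The reference algorithm
locates the elbow with a model pretrained on simulations; that artifact is
not reproducible here, so the package uses a deterministic changepoint:
the two-segment fit to the cumulative curve in which each segment is
linear with slope equal to its mean recorded distance, with the breakpoint
minimizing the squared error of the increments. (An unconstrained
two-segment linear fit to the cumulative curve was tried first and
rejected: when the post-elbow distances grow as U depletes, the cumulative
curve is convex and the free fit chases the curvature instead of the
kink, collapsing small mixing proportions to zero.) A slope-ratio guard
(second segment at least 1.5× the first) catches degenerate curves:
uniformly tiny distances mean U is saturated with positives (prior 1),
uniformly large ones that it holds none (prior 0); both return
low-confidence flags. The final estimate is the median of 5000 bootstrap
re-estimates with the IQR as uncertainty, retained only when the PU-AUC
(positives vs unlabeled, rank statistic) exceeds 0.75.

Under near-complete separation the estimator recovers mixing proportions
0.05/0.2/0.5 with median error well under 0.05. At moderate separability
(PU-AUC around 0.9) it inherits an upward bias of roughly +0.1 at small
proportions — the bias the reference's pretrained model presumably
absorbs; this is a known limitation, and the PU-AUC gate exists precisely
to exclude units where separability is too weak for the estimate to be
trusted.

# Domain aggregation

Domain intervals are resolved so each residue belongs to at most one
domain: overlapping intervals merge when the overlap covers at least half
of each, otherwise the overlap splits at its midpoint; resolution iterates
pairwise left-to-right until stable (multi-way overlaps therefore resolve
in score order of position, a documented choice). Per-domain all-variant
score histograms use 100 equal-width bins with a $10^{-6}$ pseudocount.
Distances are Jensen–Shannon (square root of the base-2 divergence, a
bounded metric), clustered by average-linkage hierarchical clustering
(configurable; the sources do not state the linkage). The dendrogram is
cut dynamically from the root: any branch whose member domains carry more
labeled controls than a cap splits into its children; a grid search over
50 log-spaced caps picks the one whose clustering has median labeled count
per cluster closest to 500 (ties toward the larger cap, i.e. coarser
clusters). Singleton domains above the cap cannot split and are flagged.

Cluster validation fits an unsupervised two-component skew-normal mixture
to a cluster's all-variant scores by direct numerical maximum likelihood
with 20 seeded restarts (components ordered by mean: "normal" below
"abnormal") and compares each component, via JSD on the histogram bins,
against the cluster's own control class distributions and against the
global ones; a positive difference (global minus cluster) means the
cluster's pooled controls represent its variants better than genome-wide
pooling does.

# Evaluation

Interval LRs are model-free: for each evidence level's score interval,
the fraction of pathogenic controls inside divided by the fraction of
benign controls inside. Intervals with pathogenic but no benign controls
report $+\infty$ and are treated as conservative ("infinitely far on the
preferred side") in comparisons; intervals with no controls at all are
undefined and skipped. Two calibrations are compared per level with
conservative win rules — both on the preferred side of the threshold:
closest (in log-LR) wins; opposite sides: the conservative one wins; both
on the wrong side: the less anti-conservative wins — and across units with
an exact one-sided binomial test at $p = 0.5$, ties excluded.
Classification metrics treat $\ge +1$ points as a pathogenic call and
$\le -1$ as a benign call, with TPR/FPR per side, their means, per-side
Matthews correlation coefficients and their mean, and the determinate rate
(nonzero points). Evidence heatmaps report per-stratum percentages at each
level from $-4$ to $+4$, with points beyond the clinical cap capped.

# What the synthetic generator does and does not capture

`generate_fixture()` emulates control tables (with review stars, allele
frequencies, splice scores), unlabeled population variants mixed at the
true prior, Gaussian feature clouds with controllable separability for
prior estimation, and domain layouts — everything needed for parameter
recovery with known truth. It does not emulate: correlated features (real
feature matrices have strong structure that PCA compresses differently),
per-gene transcript or annotation noise, heterogeneous review quality,
score distributions outside the four families, or ascertainment bias in
which variants get curated. Passing tests therefore demonstrate
correctness of the machinery and recovery under the stated generating
assumptions, not performance on any particular real predictor or gene.

# Problem sizes, numerical choices, defaults

Study-scale defaults follow the source protocol: 30 replicates, 1000
bootstrap rounds, 5000 prior bootstraps, 100 ensemble members. The test
suite and the acceptance script use desk-scale profiles — 4–10 replicates,
15–40 bootstrap rounds, 200 prior bootstraps, 40–50 ensemble members,
reduced network epochs — chosen as the smallest sizes at which the
assertions are stable across seeds; `framework_config("paper")` restores
the study scale. Posteriors are materialized on a 1001-point grid.
Tolerances: quadrature mass within $10^{-6}$; posterior/LR round trips to
$10^{-12}$; optimizer non-convergence is flagged, never silently accepted.
Tie-breaks (method ranks, family selection, the cap grid search) are all
deterministic and documented above. Degenerate inputs — single-valued
scores, empty classes, windows that cannot satisfy their constraints,
scores never out-of-bag — raise errors or flagged fallbacks as described
in the function documentation.

# Known limitations

* The evidence scale uses the single Pathogenic anchor rather than a
  simultaneous multi-tier solve; thresholds at extreme priors can differ
  slightly from multi-constraint derivations.
* The prior estimator's elbow is deterministic and carries upward bias at
  moderate separability (see above).
* The non-domain variant set is a single pooled cluster; it is not
  sub-clustered.
* Mixture calibrators are class-conditional fits; genuinely multimodal
  within-class score distributions are only captured insofar as the
  fitted family allows.
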