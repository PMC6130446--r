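---
title: "Connectotype models, kinship classification and heritability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectotype models, kinship classification and heritability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
connectotype model and its regularization, the preprocessing it expects, the
kinship analyses built on cross-prediction similarity, the synthetic cohort
generator that makes all of it testable, and the numerical and design choices
that were genuinely open.

## The connectotype model

A scan arrives as a frames × M matrix of parcellated ROI time courses. The
connectotype models every ROI as a weighted sum of all the others: for ROI
$i$, with (prewhitened) residual time courses $r_j$,

$$\hat r_i(t) = \sum_{j \neq i} b_{ij}\, r_j(t),$$

so the model is an M × M coefficient matrix $B$ with an exactly zero
diagonal. Row $i$ of $B$ solves the least-squares regression of column $i$ on
the remaining columns. Unlike a Pearson correlation matrix, $B$ is directed
and each coefficient is the *unique* (conditional) contribution of one ROI to
another: for data from a multivariate normal with precision matrix $\Theta$,
the population solution is $b_{ij} = -\theta_{ij}/\theta_{ii}$. That identity
is the package's strongest internal check — `fit_connectotype()` on long
synthetic scans must reproduce it entrywise (the test suite requires
agreement within ±0.05 at M = 30 and 5,000 frames).

Typical rs-fMRI scans have fewer usable frames than ROIs, so the per-ROI
regressions are underdetermined. Overfitting is controlled by truncated-SVD
regularization: the predictor matrix is inverted through its top $k$ singular
directions only (a spectral-cutoff pseudoinverse). One shared $k$ is used for
all M regressions — the model has a single regularization knob, not M of
them — and is chosen by cross-validation on held-out squared prediction
error, with folds formed from contiguous frame blocks (default 4) so that
temporal autocorrelation does not leak across the train/test boundary. Ties
in CV error break toward the smaller rank, i.e. toward more regularization.
The CV loss is squared error; correlation loss would ignore scale and was
the unchosen alternative.

Two exactness decisions: the per-ROI predictor matrix is the data with
column $i$ removed, and its SVD is recomputed exactly for every ROI (no
shared-SVD approximation). Tests hold the fitted coefficients to within
1e-8 of an independent brute-force oracle (explicit rank-$k$ reconstruction
followed by a Moore–Penrose pseudoinverse) across random instances at every
admissible rank.

## Preprocessing

Two preset profiles mirror the two acquisition styles the pipeline supports:

* **oregon** (child/longitudinal style): nuisance regression (intercept,
  linear trend, any supplied regressors such as whole-brain, ventricle,
  white-matter and movement signals), then a first-order Butterworth band
  pass (0.009–0.080 Hz), then AR prewhitening, then motion censoring.
* **hcp** (ICA-denoised adult style): nuisance regression only; no
  censoring, and prewhitening order 0, because ICA cleanup already removes
  the autocorrelation structure the AR step targets.

Censoring drops frames with frame displacement above 0.2 mm, then drops any
surviving run shorter than 5 contiguous frames, and flags the scan for
exclusion when less than 150 s survives. The run-length rule is tested by
property (1,000 random FD traces, no retained segment below the minimum).

Open orderings the source conventions do not pin down, resolved here and
switchable: regression is applied before filtering; the filter runs over the
full uncensored series with the mask applied afterwards (filtering across
already-cut gaps would smear artifact); the Butterworth filter is applied
forward–backward (zero phase), since phase distortion would corrupt
frame-wise predictions. The AR order for prewhitening defaults to 1 —
the minimal model that removes the dominant lag-1 autocorrelation without
discarding frames — estimated per ROI by Yule–Walker, with coefficients
clipped below |1| (with a warning) in the near-nonstationary case.

## Pair comparisons and fingerprinting

Every ordered pair of scans (model scan → target scan) is a comparison:
the model scan's connectotype multiplies the target scan's time courses,
and each ROI contributes one Pearson correlation between predicted and
observed signal. The per-ROI correlations average to one similarity per
comparison (Fisher z-transformed for group statistics). Same-scan self
comparisons split the scan into contiguous halves — first half fits,
second half (plus the odd frame) is predicted — so the model always
predicts fresh data. Comparisons are directional records; A→B and B→A both
exist and need not match.

Group contrasts (e.g. sibling vs unrelated similarity) use Welch's
unequal-variance t test on the z values, with Cohen's d; the plain "t test"
of the source convention does not specify equal variances, and Welch is the
safer default. The association between cross-scan self similarity and
inter-session interval is a Pearson correlation with its t-based p-value.

## Sibling classification

Feature vectors are the per-ROI prediction correlations of each ordered
non-self comparison; MZ, DZ and non-twin sibling comparisons form the
positive class, unrelated comparisons the negative class. Each run of an
experiment:

1. draws a family-aware holdout — either whole families (`family_holdout`,
   twin-containing families never enter training) or individual sibling
   scan-pairs (`scanpair_holdout`, longitudinal style);
2. ranks features by the two-sample Kolmogorov–Smirnov statistic on
   *training rows only* and keeps the top `top_p`;
3. undersamples unrelated training rows to match the positive count;
4. standardizes features with training-derived parameters and trains a
   linear SVM whose cost is tuned by leave-one-out cross-validation;
5. scores accuracy, sensitivity and specificity on the held-out rows.

The permutation null repeats the identical machinery with training labels
randomized. Because both directions of a pair share a family, holdout is by
family (or scan-pair), never by row, and an internal assertion verifies
train/test disjointness on every run.

Design choices: the SVM kernel is linear (high feature dimension, small n,
interpretable per-feature tallies). The cost grid is
$\{10^{-3}, 10^{-2}, 10^{-1}, 1\}$: for standardized features at these
sample sizes the linear-SVM solution saturates toward the hard-margin
classifier near cost 1, while the underlying quadratic program becomes
ill-conditioned and slow for larger costs, so the grid covers the entire
useful regularization range; ties break toward the smaller cost. Held-out
families are drawn among families with at least two members, since a
singleton holdout family carries no positive test rows. Test unrelated rows
are drawn from comparisons touching the held-out families (both-endpoint
rows preferred when available).

Anatomy-derived control features replace the prediction correlations with
signed per-ROI differences of cortical thickness or sulcal depth between
the two subjects, optionally adjusted for head size by normalization
(division) or regression (per-ROI least squares across subjects); the
synthetic anatomy generator plants its own familial structure plus a
head-size confounder so both adjustments are testable.

## Heritability and shared environment

The analysis unit is the subject pair; each pair's outcome vector is the
per-ROI prediction correlation averaged over the two comparison directions.
Factors follow the twin design: shared environment has two levels (related /
unrelated) and shared genetics three (MZ; DZ or sibling; unrelated). The
outcomes are rank-inverse-normal transformed per ROI, then decomposed by a
three-way repeated-measures ANOVA (ROI as the within-pair factor) in which
only the main effects are tested and interactions pool into the residual.
Heritability $h^2$ and shared environment $c^2$ are the ratios of the
genetics and environment sums of squares to the total.

The two factors are partially aliased by construction — relatedness is a
coarsening of the genetics levels — so the sums of squares are sequential
(Type I) with ROI first, environment second, genetics third. This is the
only ordering under which both main effects are estimable: the genetics
term captures exactly the MZ vs DZ/sibling contrast beyond relatedness.
With no MZ pairs the genetics term is structurally aliased and its SS is
reported as exactly 0 with a flag, never silently. Because unrelated pairs
vastly outnumber related ones, each ANOVA draws a fresh matched subset of
58 unrelated pairs; estimates are means over the resampled ANOVAs with
percentile 95% CIs. ROI-level significance is Bonferroni-corrected across
regions by default (Benjamini–Hochberg available).

The parameter-recovery generator (`simulate_pair_outcomes()`) plants exact
expected SS fractions: with equal group sizes, group-mean offsets
$a = \sqrt{3h^2/2}$ (MZ $+a$, DZ/sibling $-a$ around a relatedness offset
$b = 3\sqrt{c^2/2}$) against unit total variance make the sequential
genetics and environment fractions equal $h^2$ and $c^2$ in expectation.
Recovery is tested at planted 0.20 (estimate within [0.10, 0.30]), at
planted 0 (CI reaching below 0.05), and for monotonicity across planted
{0, 0.1, 0.2, 0.4}.

## The synthetic cohort generator

Kinship structure is planted in the *precision* (conditional-dependence)
domain, not the correlation domain, because the connectotype estimates
conditional regressions: this makes the ground-truth coefficients
analytically available as $b_{ij} = -\theta_{ij}/\theta_{ii}$. A sparse
symmetric edge support (density 0.15) and base weights
($\sigma = 0.35$) are drawn once per cohort; each subject's edge weights add
a deviation field composed of additive-genetic, shared-environment and
unique Gaussian components with variance fractions $g^2, c^2, e^2$ and
cross-subject genetic correlation equal to the kinship coefficient (MZ 1,
DZ/sibling 0.5, unrelated 0). Each precision matrix is made SPD by diagonal
loading to a minimum eigenvalue of 0.1; frames are multivariate normal
draws, optionally AR(1)-smoothed (coefficient 0.3, variance-preserving) so
prewhitening is genuinely exercised.

The deviation scale (0.35, equal to the base-weight scale) is the
generator's realism choice: individual connectomes share a common skeleton
but differ in edge weights by as much as the skeleton itself, which places
the self / sibling / unrelated similarity spectrum in the strongly
individuated regime that real fingerprinting studies report (self
similarity roughly double the unrelated level). With a much smaller
deviation scale all subjects collapse onto the group average and no
fingerprinting is possible; passing tests under the chosen scale therefore
demonstrate recovery of *strong* planted individuality, and say nothing
about regimes where individual variation is marginal. Other aspects of
real data the generator deliberately omits: hemodynamics, scanner noise
spectra, realistic motion spike trains, and spatial ROI geometry.

Family templates cover MZ pairs, DZ pairs, sibling pairs, sibling trios and
singletons; trio families contribute all three within-family pairs. The
adult-sample shape (198 subjects, 129 families; 10 MZ + 11 DZ + 58 sibling
pairs) is reproduced exactly by templates mz = 10, dz = 11, sib = 28,
trio = 10, singleton = 70 — the three-descendant families are what
reconcile the 198-subject total with the 79 printed pairs. The longitudinal
youth shape ships as `oregon_style_cohort()`: 131/27/1 subjects with 1/2/3
scans, and 16 sibling pairs whose scan multiplicities (12 pairs 1+1, 2
pairs 2+1, 1 pair 2+2, 1 pair 3+1 — an assumption, since the published
allocation table is not reproduced here) yield exactly 46 ordered sibling
comparisons and 60 same-subject cross-scan comparisons out of 188² ordered
pairs.

## Problem sizes

The study-scale experiments are scaled down from the source studies' sizes
to desk scale; all sizes below are the package's own choices, stated here
for reproducibility:

* *Oracle agreement*: 50 random instances, M ≤ 10, ≤ 60 frames, all ranks.
* *Identity recovery*: M = 30, 5,000 frames, one subject.
* *Fingerprinting*: 50 unrelated subjects, M = 30, 150 frames.
* *Classification*: 60 families (6 MZ, 6 DZ, 10 sibling-pair, 10 trio, 28
  singleton), M = 60, 400 frames, top 20 features, 200 runs + 200 null runs
  (scaled from the source's 1,000), 3 held-out families per run.
* *Zygosity ordering*: 10 independent cohorts of 40 families
  (10 MZ, 10 DZ, 10 sibling-pair, 10 singleton), M = 40, 400 frames,
  40 runs each.
* *Heritability*: 58 pairs per related group, 300-pair unrelated pool,
  58 matched per ANOVA, 200 ANOVAs (scaled from 1,000), M = 30 outcomes.

## Numerical notes and known limitations

* Zero-variance prediction or observation columns have undefined
  correlation; they are flagged invalid and excluded from similarity means,
  and imputed as 0 in classifier features (with rows dropped when more than
  20% of ROIs are invalid).
* Correlations within 1e-12 of ±1 are clamped before the Fisher transform.
* The rank grid is clipped to what the CV folds can support, with a
  warning, so the underdetermined regime never requests impossible ranks.
* `h^2 + c^2` is bounded by 1 by construction (they are disjoint SS
  fractions); degenerate all-constant outcomes return 0/0-free zeros.
* The significance margin for the classification experiment is assessed on
  the scale of the null *mean* (a 3-sigma z-test against the permutation
  null's mean over 200 runs). Per-run null accuracy has an irreducible
  standard deviation of ~0.12–0.17 because a 3-family holdout yields only
  ~10–20 test rows, so single-run accuracy, observed or null, is always
  coarse; distribution summaries (percentile bands, as produced by
  `run_experiment()`) are the meaningful outputs.
* Heritability here is an ANOVA SS fraction, not a variance-components ACE
  estimate: no maximum-likelihood or structural-equation machinery is
  implied, and with few MZ pairs the genetics contrast is weakly powered —
  the aliasing flag and the unreliable-stratum flag make those situations
  explicit rather than silently optimistic.
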