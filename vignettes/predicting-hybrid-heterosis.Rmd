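---
title: "Predicting hybrid metabolite heterosis and biomass from parental profiles"
author: "diallelCRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hybrid metabolite heterosis and biomass from parental profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelCRL)
```

## The problem

In a full reciprocal diallel, every ordered pair of inbred parents is
crossed (mother x father, no selfs), so `p` parents give `p(p-1)` hybrids.
The classic maize setting is `p = 4` (two flint, two dent lines), 12
reciprocal hybrids, six biological replicates per genotype, GC-MS
metabolite profiles of young primary roots (about a hundred metabolites)
and the roots' fresh weight as a heterotic trait. Parental biomass is a
poor predictor of hybrid biomass, so the package implements a different
route: express each hybrid metabolite *relative to its two parents*, find
the parental metabolites whose levels predict those relative states across
many hybrid metabolites, and validate the resulting feature ranking by
predicting hybrid biomass from parental profiles alone.

`diallelCRL` implements that chain end-to-end:

1. **Normalization** of raw intensity tables (log10, two-factor batch
   correction, studentized-residual outlier masking, median sample
   scaling).
2. **CRL labeling**: each (hybrid, metabolite) cell is encoded as a
   Combined Relative Level class in {-2, -1, 0, +1, +2} via moderated
   t-tests against each parent.
3. **Balance filtering** of metabolites with too-uniform label sets.
4. **Predictability screening** of each remaining metabolite against
   permuted-label nulls with five classifier families under repeated
   stratified 3-fold cross-validation.
5. **Feature ranking**: SVM feature-weight ranks, aggregated over all
   predictable metabolites by the median scaled rank.
6. **Biomass validation**: epsilon-SVR from ranked feature subsets with
   block-permutation nulls.

A synthetic-data generator with a recorded ground truth makes every stage
testable without any external download.

## The CRL encoding and the moderated t-statistic

For hybrid `h` and metabolite `j`, two null hypotheses are tested: equal
mean with the mother and with the father. With six (or fewer) replicates,
per-metabolite variances are unstable, so the two-sample t-statistic is
*moderated*: the pooled variances `s_j^2` (residual df `d_j`) of all
metabolites in a comparison are modeled as draws from a scaled
inverse-chi-square prior `(s_0^2, d_0)`, fitted by moment matching on
`log s_j^2` (digamma/trigamma equations; the prior df solve a trigamma
inversion). The posterior variance

```
s~_j^2 = (d_0 s_0^2 + d_j s_j^2) / (d_0 + d_j)
```

replaces `s_j^2`, and the statistic is referred to a t distribution with
`d_0 + d_j` df. Two limits matter: with fewer than three usable variances
no shrinkage is applied (`d_0 = 0`, ordinary pooled t); when the observed
log-variance dispersion is *below* the chi-square reference dispersion the
moment equation has no finite root and the coherent limit is `d_0 = Inf`
(all variances shrunk to `s_0^2`, normal reference). We use these limits
rather than forcing `d_0 = 0` in the under-dispersed case, because zero
shrinkage is exactly the wrong response to an ensemble of near-identical
variances.

P-values are two-sided, with the sign read off the mean difference; the
multiple-testing family is the set of metabolites within one
(hybrid, parent) comparison, adjusted by Benjamini-Hochberg at
`alpha = 0.05` (both choices are configurable; the encoding itself does
not prescribe either). The signed significance pattern maps to labels:
beyond both parents +-2, beyond exactly one parent +-1, otherwise 0 —
including the "significantly above one parent and below the other"
crossing pattern, which is mid-parent-like and therefore additivity.

## Balance filter

A metabolite whose modal class label occurs in at least nine of twelve
hybrids (generally more than `ceiling(0.75 * n_hybrids) - 1`) gives the
classifiers a degenerate target and is removed (weight 0). Among retained
metabolites, a class with exactly one member cannot be stratified across
3 folds; rather than discarding the metabolite, the rows of that single
genotype are dropped for that metabolite only and recorded. We read the
historical "removed only the rows of the corresponding genotype" rescue
as this singleton-class rule; a blanket "rescue any 9-of-12 column by
dropping a modal-class genotype" would contradict the removal rule, since
every 9-modal column is trivially curable that way.

## Screening against permuted-label nulls

The classifier input is the parental-pair matrix `X_pp`: one row per
hybrid replicate, the maternal profile concatenated with the paternal one
(2m columns; every metabolite appears as `_m` and `_p`). Maternal and
paternal replicates are paired by a seeded random matching, and columns
are autoscaled once on the full matrix. Per metabolite and repetition:

* one permuted label vector is drawn by permuting labels across hybrid
  genotypes (replicate rows move together);
* stratified 3-fold splits are drawn at the *hybrid* level, so replicate
  rows of one hybrid never straddle train/test (replicate-level splits
  would leak genotype identity); original and permuted runs use
  independent splits;
* each classifier family (linear SVM with cost 1, LDA with a
  principal-component fallback for singular pooled covariances, PLS-LDA
  and PLS-RF with at most 10 components, random forest with 500 trees)
  is trained on each fold complement and the median misclassification
  over folds is recorded.

After 25 repetitions, the two methods with the lowest median error under
both original and permuted labels are selected (rank-sum, ties by mean
error then fixed method order). The primary decision rule is the quartile
rule: predictable iff `Q3(original medians) < Q1(permuted medians)` for
both selected methods — deliberately stricter than comparing medians. An
alternative rule — minimum original median error below minimum permuted
median error — is also computed and reported; it is more liberal and is
the rule under which larger predictable sets are obtained. Neither rule
is silently preferred: both verdicts are in the decision table, and
`rule=` picks which one downstream stages consume.

The PLS dimension reduction is computed in-package (per component, the
X-weight is the leading left singular vector of `X'Y`, with standard
deflation); the test suite cross-checks the scores against
`mixOmics::pls(mode = "regression")` to machine precision. Likewise the
moderated-t shrinkage is implemented in-package and cross-checked against
an independently coded oracle and against `limma::squeezeVar`.

## Ranking parental features

For every predictable metabolite, a linear SVM is refit on all rows
(features are ranked regardless of classifier performance, so no
cross-validation here). Multiclass problems use one-vs-one machines; a
feature's importance is its maximum absolute primal weight over the
machines, recovered exactly from the libsvm dual coefficients. Features
are ranked descending by importance (ties averaged) and scaled into
(0, 1] by dividing by 2m. The global ranking orders features by the
median of their scaled ranks over all predictable metabolites. An
SVM-RFE mode (iterative elimination of the worse half) is available
behind a flag; single-fit weights are the primary definition.

## Biomass validation

An epsilon-SVR (radial kernel, cost 1, epsilon 0.1, e1071's standard
input/output scaling) is trained on 60% of the hybrids — splits are
genotype-coherent, a hybrid's replicates never straddle the split — and
scored by the Pearson correlation between predicted and observed test-set
biomass. Feature subsets follow the scheme grammar `top5`,
`rand5_of_top10/20/50`, `rand5_of_bottom...`, `all`, with block-permuted
biomass (replicates of a hybrid keep their values together) and
cell-permuted profile matrices as nulls. Sampling schemes redraw their
subset each repetition; 500 repetitions by default.

## The synthetic generator

`simulateDiallel()` emulates the study conditions: 4 parents, 12
reciprocal hybrids, 6 replicates, 112 metabolites, 3 measurement batches,
log10-scale intensities (grand means ~ N(5, 1), i.e. log-normal peak
heights), per-(batch, metabolite) offsets, and per-sample fresh weight in
mg. Heterosis is planted through *driver features*: `nDrivers` parental
features (3:1 maternal by default, mirroring the observed maternal
predominance) whose parent-mean combination deterministically sets the
CRL label of each *driven* metabolite (scores cut at fixed 2:3:2:3:2
proportions across hybrids, so planted label sets are balanced). Hybrid
means then follow the label geometry exactly: mid-parent for 0, at the
respective parent for +-1, beyond the parental range by
`effectSize * max(noiseSd, 0.02)` for +-2 (the floor keeps the geometry
strict in noise-free fixtures). Biomass is a baseline plus a signed
linear combination of the standardized driver levels plus noise; each
driver feature reads its own side (maternal features the mother's mean,
paternal the father's), so the planted ranking and the biomass validation
are coherent.

Two generator choices deserve justification:

* **Driver and driven metabolites get well-separated parent means** (a
  jittered equispaced grid scaled by `parentTau`). Dominance (+-1) is
  only *detectable* when the two parents differ; with i.i.d. normal
  parent effects a fraction of parent pairs are too close, and the
  planted label would be unrecoverable by any method. The grid makes the
  planted geometry recoverable by construction, which is what the
  generator's labels claim to be.
* **Background metabolites get a smaller parental spread**
  (`backgroundTau = 0.3 * parentTau`): the bulk of a GC-MS profile
  varies much less between genotypes than the handful of discriminating
  metabolites, and this keeps "uninformative" features genuinely
  uninformative.

What the generator does *not* emulate: metabolite-metabolite correlation
networks, retention-index artifacts, missingness mechanisms, non-additive
(epistatic or dominance-of-dominance) genetics beyond the planted label
geometry, and hybrid-specific biomass deviations (biomass is, by
construction, a function of parent identity plus noise). Passing tests on
synthetic data therefore demonstrate that the pipeline recovers the
structure it assumes — not that real hybrid metabolomes satisfy those
assumptions.

## Identifiability and the choice of test dimensions

A point that shapes the property tests: with `p` parents, every maternal
feature column of `X_pp` is a function of the mother's identity, so the
whole maternal block has rank at most `p - 1` (after centering), and
likewise the paternal block. At the experimental `p = 4`, any 112-column
maternal block lives in a 3-dimensional space: many features are
near-collinear with any given driver, and *which specific column* carries
the signal is not identifiable — neither by an SVM nor by any other
method. The driver-recovery and biomass-chain properties are therefore
exercised on larger synthetic diallels (14 parents, 182 hybrids, 24
metabolites), where the parental feature space is well-conditioned and
recovery of all planted drivers is a fair demand; leave-one-hybrid-out
stability uses 6 parents. The experimental-scale geometry (4 parents) is
still exercised for everything that does not require per-column
identifiability: CRL recovery, null calibration, balance filtering,
screen calibration, and the end-to-end pipeline.

A related small-diallel phenomenon: because hybrids share parents, *any*
genotype-structured feature subset weakly predicts biomass (test hybrids
share parents with training hybrids, so even chance correlations
generalize — in the extreme, a feature column "fingerprints" the parent).
Bottom-ranked subsets therefore sit above the block-permuted null instead
of collapsing onto it; the biomass comparison is asserted as a monotone
chain (top5 >= rand5-of-top20 >= bottom sets >= block-permuted null, ties
allowed) rather than as equalities. The same effect, seen from the other
side, is why block-permuted predictions are documented to sit above zero
at small genotype counts and to shrink toward zero as the number of
hybrids grows — a property the test suite checks at 12 vs 30 hybrids.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | CRL significance level (BH-adjusted per comparison) |
| `threshold` | 4 | studentized-residual outlier cutoff |
| `maxSame` | 8 (of 12) | largest tolerated modal label count |
| `k`, `reps` | 3, 25 | CV folds and repetitions in the screen |
| `ntree` | 500 | random-forest trees |
| `plsNcomp` | 10 | PLS components before LDA/RF |
| `trainFrac`, SVR `reps` | 0.6, 500 | biomass split and repetitions |
| subset size | 5 | features per biomass scheme |
| `effectSize` | 2 | overdominant shift in units of `noiseSd` |
| `noiseSd`, `batchSd` | 0.15, 0.1 | replicate noise and batch offsets (log10) |
| `maternalFraction` | 0.75 | maternal share of planted drivers |

The test suite and the acceptance script run the stochastic stages at
reduced sizes (screen repetitions 4-10, SVR repetitions 60-100, 16-24
metabolites) chosen so each property is measured with adequate
replication while the whole suite stays comfortably runnable on a single
CPU; the defaults above are what an analysis of a real dataset would use.

## Numerical choices and degenerate inputs

* Outlier masking is a single pass (no refit-and-iterate); masked cells
  propagate as NA, group statistics use available cases, and cells with
  fewer than 2 unmasked replicates per group are skipped and flagged.
  When the classifier matrix is built, masked parental cells are imputed
  from the same genotype's remaining replicates.
* Batch effects use the sum-to-zero parametrization; inestimable
  (aliased) effects are set to 0 with a warning.
* `s2 = 0` cells (noise-free fixtures) give `t = +-Inf` for a nonzero
  mean difference and `t = 0, p = 1` for a zero one.
* Ties in feature importance get averaged ranks, preserving the rank-sum
  invariant `sum = m(2m+1)` per metabolite.
* Method-selection ties in the screen break by mean error, then by the
  fixed order SVM, LDA, PLS-LDA, PLS-RF, RF.
* All randomness (pairing, folds, permutations, subset draws) descends
  from explicit seeds; one master seed derives per-stage seeds in
  `runPipeline()`.

## Known limitations

* The CRL discretization discards the magnitude of the hybrid shift by
  design; only the direction-relative-to-parents survives.
* At 4 parents the ranking identifies *directions* in a 3-dimensional
  parental space, not unique metabolites; interpretation of individual
  top features at that scale needs external evidence.
* Column autoscaling happens once on the full parental-pair matrix, not
  per training fold; the induced optimism is accepted for fidelity to the
  construction of `X_pp` and affects original and permuted runs alike.
* The screen's permutation null preserves the replicate structure but not
  any batch-residual structure that survived normalization.
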