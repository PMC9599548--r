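---
title: "Methods: predicting substrate promiscuity of ester hydrolases from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting substrate promiscuity of ester hydrolases from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promisc)
```

## The problem and the model

Substrate promiscuity — the ability of one enzyme to act on many different
substrates — is an active-site property, but structures are rarely available
at database scale. `promisc` treats promiscuity prediction as binary
classification from sequence alone: an ester hydrolase is labelled
*promiscuous* when it hydrolyzes at least 20 esters of a 96-substrate
reference panel (the threshold is inclusive; `label_from_counts()` uses
`count >= 20`). The classifier never sees the counts, only the binarized
label.

The model is an *abstaining agreement ensemble*: several shallow classifiers
of different inductive biases (maximum-margin SVM, local KNN, global linear
ridge) vote, and the ensemble emits a label only under full agreement. The
assumptions are modest: that promiscuity leaves a signal in sequence-derived
composition statistics and in the evolutionary profile, and that member
disagreement marks the unreliable region of feature space better than any
single model's confidence score. Abstention and the applicability domain
both trade coverage for precision, which is the right trade in a
bioprospecting setting where only a handful of candidates can be validated
experimentally.

## Featurization

Two descriptor families are concatenated, each length-independent so
proteins of different lengths share one feature schema.

**Physicochemical (2,274 dimensions).** The default registry
(`default_physchem_registry()`) contains amino-acid, dipeptide and
dipeptide-deviation compositions; 5-group grouped compositions (single,
pair, triple, and k-spaced pairs for gaps 0–5); composition, transition and
distribution statistics over the classical seven 3-class property partitions
(hydrophobicity, van der Waals volume, polarity, polarizability, charge,
secondary structure, solvent accessibility); conjoint triads over the
seven-class alphabet; Moran, Geary and Moreau–Broto autocorrelations of
eight published residue scales at lags 1–18; and sequence-order /
pseudo-composition descriptors (lag and λ = 21, weights 0.1 and 0.05).
The registry is data, not code: entries can be dropped or re-parameterized,
and each entry carries its own minimum sequence length. The autocorrelation
and sequence-order lags were fixed once so that the default registry totals
exactly 2,274 dimensions; the family membership is the package's
reconstruction of the classical length-independent descriptor suites, and
alternative memberships are configurable.

**Evolutionary (18,730 dimensions).** Input is a PSI-BLAST ASCII PSSM per
sequence (the 20 integer log-odds columns; the percentage block and trailing
statistics are ignored, since log-odds are what the standard PSSM transforms
consume). The 18 default transforms (`default_pssm_registry()`) include
column averages, filtered column sums, squared-difference dipeptides (gap 2),
a smoothed-window average, 20-block row averages, three residue-grouped
composition variants, dipeptide and 2-separated bigram products, a
logistic-probability dipeptide and trigram, a concatenated
composition+dipeptide transform, a 10-letter reduced-alphabet transform, a
pseudo-PSSM (ξ = 2), per-column autocovariances (lags 1–20) and pairwise
cross-covariances (lags 1–17). Transforms that need probabilities apply the
logistic map 1/(1+e^(−s)) internally and are flagged `uses_logistic` in the
registry. Here too the lag parameters were pinned once so the registry
totals exactly 18,730 dimensions — given the fixed families, the
cross-covariance lag is essentially forced (380·c + 20·a + 20·ξ + 20 =
6,920 has c = 17, a = 20, ξ = 2 as its only balanced integer solution).

**Non-canonical residues.** B, Z, J, U, O, stops and gaps are mapped to `X`
on input; `X` is excluded from all composition counts and windows
(denominators use valid residues/windows, keeping every composition a true
frequency), and PSSM rows at `X` positions are zeroed. Length-dependent
descriptor families are deliberately out of scope.

## Cleaning, selection, and the feature-set protocol

Columns whose single most frequent value occupies more than 90% of rows are
dropped (`clean_features()`, idempotent). Ten ranking methods are available
(`featsel_methods()`): chi-square, information gain, mutual information and
Fisher score as univariate filters; mRMR and CIFE as greedy
information-theoretic filters; RFE over a ridge or linear-SVM base as
wrappers; random-forest and boosted-tree importances as embedded methods.
Information measures use 5-bin discretization — equal-frequency bins except
for "information gain", which uses equal-width bins; this is what
distinguishes the two mutual-information estimates in the registry. Greedy
methods order the first 60 features exactly and fall back to relevance
ordering for the tail; importance ties break by column order; stochastic
methods take explicit seeds.

Feature sets are built per family: the physicochemical and PSSM blocks are
ranked *independently* and concatenated with a 75% PSSM quota (rounded up),
reflecting the consistently higher information content of evolutionary
features. Set sizes default to {20, 25, 30, 40, 50, 55} and every set must
stay below half the training-sample count — an overfitting cap that, at 145
samples (116 training), allows at most 57 features. Selection always runs
on a training slice only; the fitting function uses the first repeat's
training ids as the designated selection slice, accepting the mild
repeat-to-repeat reuse that a single selection pass implies.

## Training protocol and metrics

`make_splits()` draws five stratified 80/20 train/test splits. Per split,
`tune_and_train()` standardizes the selected columns on the training rows
(center/scale; zero-sd columns get scale 1), then grid-searches by inner
stratified 5-fold cross-validation maximizing mean MCC, with ties resolved
toward the first grid row. Default grids: SVM kernel {radial, linear} ×
cost {0.1, 1, 10} (γ left at the 1/p heuristic); KNN k {3, 5, 7, 9} (odd,
avoiding vote ties) × weights {uniform, distance}; ridge λ {0.01, 0.1, 1,
10}. The ridge classifier is the closed form w = (XᵀX + λI)⁻¹Xᵀy on ±1
targets with an unpenalized intercept. Standardization before SVM, KNN and
the applicability domain is essential because margins and Euclidean
distances are scale-sensitive.

`score_predictions()` computes TP/TN/FP/FN, precision, recall, F1 and MCC;
any metric with a zero denominator returns 0, so constant predictors score
0 rather than NaN. The test suite checks the implementation against
exhaustive confusion-matrix enumeration for all label patterns up to length
four.

## Ensemble and applicability domain

From the 5 × 3 fitted models, `select_members()` keeps the per-algorithm
quota (2 SVM, 3 ridge, 2 KNN) with the best held-out MCC, ties broken by
lower repeat id. The default agreement rule is unanimity; a majority rule
is available but not default. Ensemble performance is always reported on
non-abstained samples only — that is what the abstention mechanism is for —
alongside the abstention rate.

The applicability domain (`fit_ad()`) follows the KNN family: each training
sample i gets a threshold t_i equal to the mean of its k nearest-neighbour
distances plus Z times their standard deviation (defaults k = 5, Z = 0.5;
Z = 0 reduces to the plain mean). A query is reliable if its distance to
*any* training sample is within that sample's threshold. Distances are
Euclidean in the standardized space of the ensemble's most-used feature
set; the choice of reference space is a genuine design freedom — any of the
member feature spaces would be defensible — and is recorded on the fitted
object.

## The bioprospecting funnel

`run_pipeline()` chains: homology pre-filter (HMMER hits table or live
`hmmbuild`/`hmmsearch` when the binaries are on the PATH; E-value cutoff
10⁻¹⁰, best E-value per target), ensemble prediction, applicability-domain
gating, and cavity ranking. `rank_candidates()` shortlists the predicted
positives with the best E-values (default 100), drops candidates whose
catalytic triad is not in an active conformation, ranks survivors by cavity
hydrophobicity and by enclosure/exposure (ties share the minimum rank, so a
constant metric defers entirely to the other), expands m from the target
size upward until the two top-m lists intersect in at least `n_final` ids,
and orders the final set by rank sum (ties by id). The m-expansion is the
minimal deterministic completion of "intersect at the top of both metrics";
it can return slightly more than `n_final` ids when ties inflate the
intersection. Homology modelling and cavity-descriptor computation are
external concerns: the module consumes a descriptor table
(`id, hydrophobicity, enclosure, exposure, triad_ok`).

Every stage logs input/output cardinalities, and a run re-executed from its
emitted `config_effective.yaml` reproduces its outputs byte for byte.

## The synthetic-data module

`gen_planted_dataset()` defines the study conditions: 145 samples at 40%
positive prevalence by default (chosen to permit stratified 5-fold CV),
sequence length 150, and a signal planted by *biased residue sampling* —
positives draw the signal residues (default I and L, mirroring the elevated
aliphatic/hydrophobic character of promiscuous esterase cavities) at a
frequency shifted so that the `physchem.aac.*` signal columns separate by
the requested effect size (default 3 pooled sd). The shift is calibrated by
a short fixed-point iteration on the pooled binomial sd, and the realized
separation is verified post-featurization to be within 20% of the request
at n ≥ 200. Because the signal lives in the residues, it propagates
naturally into dipeptides, CTD, and — via the synthetic PSSM's +5
own-residue bias — into the evolutionary block, so featurization is
genuinely exercised. Labels can be flipped with a noise probability in
[0, 0.5).

What the generator does *not* emulate: real esterase phylogeny, realistic
PSSM statistics of iterative database searches, sequence-length variation,
or class-conditional dependence structures beyond composition. Passing
tests on planted data therefore demonstrate that the machinery recovers a
known signal under controlled conditions — not that real promiscuity is as
separable.

## Problem sizes and numerical choices

The test suite runs the full-scale conditions where they matter — the
dimension contracts on 150-mers, the feature-set protocol at n = 145 with
a ~2,000-column cleaned matrix, ensemble recovery at n = 200 with the full
21,004-column matrix — and reduced registries (a few hundred columns,
n = 50) for the many behavioural unit tests, keeping the whole suite under
a minute on one CPU. Numerical conventions worth knowing: zero-variance
autocorrelations return 0 (homopolymers); absent CTD classes give zero
distribution landmarks; the amphiphilic pseudo-composition uses |τ| in its
denominator to keep it positive; duplicated training rows give zero AD
thresholds (they only vouch for exact duplicates); KNN caps k at the fold
size in degenerate inner folds.

## Known limitations

Selection reuses one training slice across the five repeats, so the
split-to-split spread understates selection variance. The PSSM transform
and physicochemical registries are reconstructions of the classical suites
with parameters pinned to the package's dimension contracts, not a claim
of uniqueness. The applicability domain's threshold constants (k, Z) and
reference space are heuristic and exposed as configuration. And planted
synthetic data is far easier than real promiscuity data; published
real-data MCCs in this problem family sit near 0.6–0.7, not at the 1.0 the
generator's default effect size yields.
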