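---
title: "Consensus biomarker discovery from label-free proteomics"
author: "lfqmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus biomarker discovery from label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqmarker)
```

## The problem

Breast-cancer cohorts profiled by label-free quantitative (LFQ) mass
spectrometry yield a matrix of log2 protein intensities for a few dozen
tumours, each annotated with a metastasis class: `NM` (no metastasis), `LM`
(late metastasis, relapse after several years) and `M` (early metastasis).
The goal is to find a small panel of proteins whose abundance discriminates
the three classes — biomarker candidates for metastatic propensity — under
severe small-n/large-p conditions (roughly 29 samples against thousands of
proteins). `lfqmarker` implements a full selection pipeline for this
setting and a synthetic-cohort generator that lets every stage be validated
against planted ground truth.

## The pipeline

### Preprocessing

Proteins quantified too sparsely are removed: a protein is kept when its
fraction of missing intensities is at most `max_missing_fraction` (default
0.3). The remaining missing entries are filled by k-nearest-neighbour
imputation in which the *neighbours are proteins*: the distance between two
proteins is the root-mean-square difference over the samples where both are
observed, and a missing entry is the unweighted mean of the values, at that
sample, of the `k` (default 10) nearest proteins observed there. The
defaults reconcile two conventions common in proteome preprocessing — a
strict "identified in all replicates" filter and imputation of what
remains — as a tunable completeness threshold followed by kNN imputation.
The literature rarely states `k`, the metric, or the neighbour axis for
this step; the choices here are the standard expression-matrix scheme and
are documented as package decisions.

### Feature prioritization

Within a training set, every protein is scored by mutual information (MI)
between its discretized abundance and the class label:

$$I(X;Y) = \sum_{x}\sum_{y} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},$$

with $X \in \{\mathrm{NM},\mathrm{LM},\mathrm{M}\}$ the class and
$Y \in \{L, M, H\}$ the abundance tercile (type-7, i.e.
linear-interpolation, empirical quantiles at 1/3 and 2/3). The base-2
logarithm reports bits; the ranking is invariant to the base. Because the
class sizes are unbalanced, MI is averaged over 100 balanced batches, each
drawing the minimum class size per class without replacement; batch
membership comes from the fold-specific seed.

Ties in averaged MI (differences at most `tie_epsilon`, default 1e-9) are
broken by a network-propagation (NP) score. Seed proteins are the
differentially abundant proteins — one-way ANOVA across the three classes,
Benjamini–Hochberg adjusted p strictly below 0.1. The protein–protein
interaction network is trimmed of edges with confidence below 0.5 (STRING
`combined_score`/1000), the binary adjacency is column-normalized to a
column-stochastic walk matrix $W$ (isolated nodes get a self-loop), and
heat diffuses through the insulated operator

$$F = \beta\,(I - (1-\beta)W)^{-1}, \qquad \text{np} = F h,$$

with restart probability $\beta = 0.4$, the customary value for
protein-interaction networks. Seed heat is binary by default (the
literature does not state the heats; an option derives them from
$-\log_{10}$ adjusted p). Because $W$ is column-stochastic, the scores
conserve the total seed heat — a property the test suite checks to 1e-9.
Residual ties after NP fall back to the lexicographic protein id, making
the ranking fully deterministic.

### Recursive feature addition

Features are added along the ranking one at a time. Each prefix is scored
by stratified inner cross-validation (default `inner_k = 5`; the source
protocol states five folds in one place and three in another, so the count
is configurable): per split, the training part is z-scored, an RBF-kernel
SVM (one-vs-one, cost 1, gamma = 1/(d × mean feature variance), i.e. the
"scale" policy) is fitted, and macro accuracy — the unweighted mean of
per-class recall — is measured on the held-out part. Addition stops at
`max_features` (30) or after `patience` (5) consecutive additions without
improving the running maximum. The chosen prefix is the accuracy argmax;
exact ties go to the smallest prefix (parsimony). Stratification matters:
with 9–10 samples per class, unstratified folds can lose a class entirely.

### Leave-one-out consensus

The outer loop holds out one sample at a time. Everything above — ANOVA
seeds, propagation, balanced MI, discretization, recursive addition,
classifier fitting — is recomputed from the remaining samples only, and
the fold's classifier predicts the held-out sample. Fold `f` derives its
seed as `master_seed + f`, so runs are reproducible without artificially
correlating folds. The consensus biomarker set is every protein selected
in at least `min_count` folds (default 3, inclusive). Performance is
reported as *pooled* macro precision/recall/F1 over the held-out
predictions: with one test sample per fold, per-fold macro metrics are
degenerate, so pooling the n predictions into one confusion matrix is the
only coherent aggregate.

The selection-frequency p-value answers "how surprising is a protein
selected in at least `min_count` of n folds?" under an explicit null:
each fold selects its set uniformly at random, so inclusion is
$X \sim \mathrm{Binomial}(n, \bar{s}/p)$ with $\bar{s}$ the mean selected
set size and $p$ the pool size, and the upper tail is summed directly from
the pmf.

## The synthetic-data generator

`simulateCohort()` emulates the study conditions the pipeline targets:
29 samples (10 NM / 9 LM / 10 M), 2000 proteins with per-protein baselines
$\mathcal{N}(28.5, 1)$ on the log2-LFQ scale (discovery-set LFQ values of
~27–30 indicate log2 units), within-class noise of 0.5, and 9 planted
markers whose class means fall by `effect_step` (0.7 log2 units) per step
along NM → LM → M — the monotone signature a genuine metastasis marker
shows. Missingness is 5% MCAR by default, chosen for analytic
transparency; a `left_censored` mode masks the lowest quantile instead,
mimicking intensity-dependent dropout. `simulateNetwork()` wires the
planted proteins into a connected module whose edges carry confidence 0.9
(surviving the 0.5 trim together) on top of a preferential-attachment
background whose right-skewed degrees stress the diffusion normalization.

What the generator does *not* emulate: peptide/spectrum-level structure,
batch effects, correlated background proteins, sample-level normalization
artefacts, or survival outcomes. Tests passing on these cohorts therefore
validate the machinery — ranking, diffusion, selection, aggregation — not
the biology of any real cohort.

## Numerical conventions and degenerate inputs

* Quantiles are type 7 everywhere (R's default, linear interpolation).
* A constant protein discretizes to all-`L` with a warning (its MI is 0),
  and its ANOVA p is defined as 1 rather than erroring.
* Proteins absent from the network receive NP score 0; an empty seed set
  yields all-zero NP scores with a warning, and ranking falls back to MI
  then protein id.
* $0 \log 0 \equiv 0$ in the MI sum; heat conservation is exact up to
  sparse-solver tolerance.
* Balanced-MI batch membership is drawn in R's RNG; the per-batch
  discretization and MI run in compiled code asserted equal to a pure-R
  reference to 1e-12.
* All randomness descends from a single master seed; repeated runs are
  byte-identical, which the test suite checks on the written artifacts.

## Problem sizes used by the test suite

Structural and oracle tests use small matrices (about 10–80 proteins,
9–12 samples) where brute-force references are exact. The end-to-end
checks run the default cohort geometry (29 × 2000, five master seeds) for
marker recovery and a matching zero-effect null; these sizes keep the full
suite comfortably within a coffee break on one CPU while exercising the
pipeline at the intended scale.

## Known limitations

* **Correlated folds.** Leave-one-out folds share all but one training
  sample, so per-fold rankings — and hence selections — are strongly
  dependent. On *zero-effect* data the pipeline still concentrates
  selections on whichever noise proteins happen to score highest in the
  shared data, so the consensus set under the null is typically *not*
  empty. The binomial selection p-value, which assumes independent
  per-fold selections, is correspondingly optimistic and should be read
  as a descriptive index, not a calibrated error rate. The honest null
  guarantee, verified by the test suite, is that held-out *predictive*
  performance stays at chance (macro F1 ≈ 1/3).
* **Redundant markers.** Planted markers carry the same class signal, so
  a parsimonious prefix can represent several of them by one; recovery of
  the full planted set relies on selection variability across folds, and
  one or two planted markers may be missed in a given cohort.
* The SVM hyperparameters are fixed, not tuned; the classifier interface
  is deliberately minimal.
* No across-sample normalization is performed; inputs are assumed
  normalized upstream.
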