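# lfqmarker

Consensus biomarker discovery from label-free quantitative (LFQ)
proteomics. Given a log2 LFQ abundance matrix for a small cohort labelled
with three metastasis classes — `NM` (no metastasis), `LM` (late
metastasis) and `M` (early metastasis) — and a weighted protein–protein
interaction network, `lfqmarker` produces a consensus panel of candidate
marker proteins together with an honest estimate of how well that panel
predicts the class of unseen samples.

The pipeline, designed for the ~29-samples-versus-thousands-of-proteins
regime:

1. **Preprocess** — completeness filtering (keep proteins with at most a
   fraction `max_missing_fraction` of missing values), then k-nearest-
   neighbour imputation with proteins as neighbours.
2. **Prioritize** — rank proteins by mutual information between the class
   label X ∈ {NM, LM, M} and the tercile-discretized abundance
   Y ∈ {L, M, H},
   I(X;Y) = Σ p(x,y) log2 [ p(x,y) / (p(x) p(y)) ],
   averaged over 100 class-balanced resampling batches. MI ties are broken
   by network-propagation scores: heat from ANOVA/Benjamini–Hochberg
   differential-abundance seeds (adjusted p < 0.1) diffused through the
   insulated operator F = β (I − (1−β) W)⁻¹ on the confidence-trimmed
   (≥ 0.5) interaction network, β = 0.4.
3. **Select** — recursive feature addition along the ranking: each prefix
   is scored by stratified inner cross-validation of an RBF-kernel SVM,
   and the macro-accuracy-maximizing prefix is kept (smallest on ties).
4. **Consensus** — an outer leave-one-out loop repeats all of the above
   with each sample excluded in turn; proteins selected in at least 3
   folds form the consensus set, and the pooled held-out predictions give
   macro precision / recall / F1.

A synthetic-cohort generator (`simulateCohort()` / `simulateNetwork()`)
plants markers with a monotone NM → LM → M abundance decrease inside a
connected network module, so the entire pipeline is testable against known
ground truth without any external data.

## Worked example

```r
library(lfqmarker)

cfg <- simulationConfig(rng_seed = 1)          # 29 samples, 2000 proteins, 9 planted markers
sim <- simulateCohort(cfg)
net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))

x <- knnImpute(filterByCompleteness(sim$experiment, 0.3), 10)
folds  <- runLoocv(x, net, loocvConfig(seed = 1))
report <- consensusFeatures(folds, min_count = 3, pool = rownames(x))
report
#> ConsensusReport: 29 leave-one-out folds over 2000 proteins
#> consensus set (count >= 3 ): 12 proteins
#>   PROT00025, PROT00270, PROT00299, PROT00471, PROT00611, PROT00679, PROT00823, PROT00930, PROT01017, PROT01421 ...
#> pooled macro precision 0.677, recall 0.652, F1 0.659
#> mean selected-set size 6.93; selection p-value 0.000142

length(intersect(consensusSet(report), sim$truth$planted_ids))
#> [1] 7      # 7 of the 9 planted markers reach the consensus
```

The report says: across the 29 leave-one-out folds, 12 proteins were
selected at least 3 times; 7 of them are planted markers. The pooled
held-out predictions classify the three metastasis classes well above the
1/3 chance level. The selection p-value is the binomial-tail probability
of a protein reaching 3 selections if folds chose uniformly at random —
a descriptive index (see the vignette for why leave-one-out fold
correlation makes it optimistic).

Where do the markers sit in the two rankings? On the full cohort:

```r
mi <- balancedMI(x, rng_seed = 1)
np <- networkPropagationScores(net, selectSeeds(adjustBH(anovaPvalues(x)), 0.1))
combinedRankTable(rankFeatures(mi, np), sim$truth$planted_ids)
#>   protein_id mi_rank np_rank
#> 1  PROT00129      36      12
#> 2  PROT00270       4       1
#> 3  PROT00299       1       8
#> 4  PROT00471      11       2
#> 5  PROT00679      14       4
#> 6  PROT00930       5       7
#> 7  PROT01017       2       3
#> 8  PROT01533      12       5
#> 9  PROT01860       7       6
```

Eight of the nine planted markers occupy top-15 positions in both the MI
and the network-propagation orderings.

`runPipeline()` wires the same stages to files (plain or MaxQuant
proteinGroups-style matrix TSV, label TSV, STRING-style edge list) and
writes `consensus.tsv`, `metrics.json` and `fold_results.json`.

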