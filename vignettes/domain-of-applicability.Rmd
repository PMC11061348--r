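---
title: "Evaluating reduced ER assay models across structural chemical clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reduced ER assay models across structural chemical clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erconcord)
```

## The problem

High-throughput screening programs for endocrine-disrupting chemicals face a
practical question: a full estrogen receptor (ER) agonist model integrating
16 *in vitro* assays is expensive to run, and reduced models built from as
few as four assays reproduce its activity calls with high sensitivity and
specificity *on average*. But averages can hide structure. A reduced model
may work well for most chemistry and fail for particular structural classes
— steroids, phenols, known antagonists. `erconcord` implements a
cluster-resolved evaluation: group a chemical inventory into structural
clusters, map the assay-tested chemicals into those clusters, and ask, per
cluster, where the reduced model's calls agree with the full model's and
what to do with the disagreements.

The package treats the full-model call as the reference ("truth"): a **true
positive** is active under both models, a **false positive** is active only
under the reduced model, and so on. This is an evaluation convention, not a
biological claim — the closing stages of the analysis explicitly revisit
false positives that may in fact be weak agonists missed by the full model.

## Pipeline and model

### Structural clustering

Chemicals are represented by binary substructure fingerprints (the ToxPrint
chemotype library of 729 predefined features is the canonical choice; any
width is accepted). Similarity between two fingerprints is the Tanimoto
(Jaccard) coefficient over on-bits, and the distance is its complement:

$$ d(A, B) = 1 - \frac{|A \cap B|}{|A \cup B|} $$

Two all-zero fingerprints (no recognized substructures) are treated as
identical with a warning; an all-zero fingerprint against a non-zero one is
maximally distant. The universe is clustered by agglomerative Ward linkage
on this distance matrix and the tree is cut at an absolute height
(default 1). Two numerical points deserve emphasis:

* **Ward dialect.** R's `hclust` offers `ward.D` (Lance–Williams update on
  the raw dissimilarities) and `ward.D2` (on squared dissimilarities; the
  variant consistent with Ward's variance-minimization objective). Cluster
  counts at a fixed cut height differ between dialects, so the package
  implements both, defaults to `ward_d2`, and records the dialect in every
  `cluster_assignment`. Reproducibility claims about a cluster count are
  meaningless without naming the dialect.
* **Label stability.** Cut labels are relabelled 1..K in order of first
  member appearance, so labels are deterministic for a fixed input order;
  permuting the input permutes labels but not the partition. Tie-breaking
  among equal-height merges follows `hclust` and is implementation-defined.

The cut height is a tuning choice balancing singleton avoidance against
merging dissimilar chemistry; `cluster_size_profile()` reports the
singleton/doubleton counts used to judge it.

### KNN mapping

Tested chemicals outside the clustered universe are placed into clusters by
k-nearest neighbours under the same Tanimoto distance. The neighbourhood
size is selected by an 80/20 uniform random split of the clustered universe
(`select_k()`): for each candidate k (default 1–5) the held-out 20% is
re-assigned from the 80% and scored against the dendrogram labels; the best
k wins, ties going to the smallest. The split is deliberately *not*
stratified by cluster, so held-out members of singleton clusters are
unclassifiable and cap the attainable accuracy — matching what an
unstratified protocol can honestly achieve. Two tie rules make `knn_assign()`
fully deterministic: equal distances are broken by the lexicographically
lowest training identifier, and tied majority votes fall back to the single
nearest neighbour's cluster. A query identical to a training chemical is
therefore always assigned that chemical's own cluster at k = 1 — the
self-consistency property the tests exercise by re-presenting universe
members as queries.

### Subset-model scoring

The reduced model's agonist score for a chemical is the weighted mean of its
per-assay AUC values over the model's assays,
$\mathrm{AUC}_{subset} = \sum_i w_i\,a_i / \sum_i w_i$. Normalizing by the
weight sum keeps the score on the same \[0, 1\] scale as the full model's
AUC, so one activity threshold applies to both; `normalize_weights = FALSE`
gives the raw weighted sum for replication against externally computed
scores. Confidence bounds are propagated by applying the same linear score
to the lower- and upper-bound AUC tables (exact for a linear statistic;
no resampling). Calls are dichotomized at the threshold with a *closed*
comparison — a score of exactly 0.1 is active; 0.0976 is a borderline
negative. Active-assay counting uses a *strict* floor — any AUC above 0
counts — because it mirrors how per-assay hit activity is recorded.

A chemical is scored only if all of the model's assays are present in the
median table; incomplete chemicals are excluded and listed, never silently
dropped.

### Per-cluster concordance

For every cluster with at least two tested chemicals (`min_cluster_n = 2`;
statistics on one chemical are noise), a 2×2 confusion matrix yields
sensitivity, specificity, accuracy, balanced accuracy, PPV, NPV and
prevalence, plus AUC agreement summaries. Ratios with zero denominators are
`NA`, never 0 or 1, and balanced accuracy is `NA` whenever either component
is undefined — reporting the surviving component alone would silently halve
the information. `NA` values are excluded from cross-cluster averages, so
averages are effectively taken over mixed-prevalence clusters where all
terms exist. Small clusters make these statistics volatile: one wrong call
in a cluster with a single true negative drops specificity (and balanced
accuracy) to 0 while accuracy stays high, which is why the partition report
and the per-cluster tables are read together.

### False-positive triage

False positives are assigned to the first matching rule of an ordered
cascade — antagonist flag, subset score strictly below the lower quartile of
true-positive scores, fewer than three active assays, residual. First-match
assignment reproduces successive set subtraction on the false-positive pool,
so categories are exhaustive and disjoint. Order matters (an antagonist with
a low score is counted as an antagonist, not as low-score) and a test guards
against accidental reordering. The quartile uses the linear-interpolation
quantile (R type 7); the definition is configurable because reproducing an
externally printed quartile value depends on it. The quartile comparison is
strict (`<`), so a false positive exactly at the quartile is not
down-weighted. Prioritization ranks subset positives by the active-assay
rule first, then descending score, ties by identifier; clusters containing
positives are marked and their negative members surfaced as
"cluster-rescued" candidates for re-evaluation.

## The synthetic-data generator

No external inventory, fingerprint set or assay archive is redistributable
at package scale, so the generator is a first-class module that emulates the
*structure* of the real inputs with known ground truth.

**Fingerprint universes** (`gen_universe()`): each planted cluster owns a
random mask of `mask_size = 40` of the 729 feature bits; members switch mask
bits on with probability 0.9 and background bits with probability 0.02.
These defaults put expected within-cluster Tanimoto distances near 0.5 and
between-cluster distances near 1, a contrast typical of congeneric series
versus unrelated chemistry in substructure fingerprints, and make the
planted partition recoverable by a Ward cut at height 1 (the `ward_d2`
merge heights for within-cluster joins stay well below 1 while
between-cluster joins sit far above it at these cluster sizes).

**Assay tables** (`gen_assay_table()`): each tested chemical draws one of
five archetypes. The default mixture — strong agonist 5.5%, weak agonist
1.2%, antagonist-like 0.7%, borderline 6.4%, inactive 86.2% — was chosen
once to mirror the composition of a screened inventory in which roughly 6%
of chemicals are true positives (about a tenth of them weak, active in only
two assays), roughly 7% are subset-model false positives (about one in ten
antagonist-driven, the rest borderline actives of which about 80% are
active in fewer than three assays), and false negatives are rare borderline
cases. Antagonist-like chemicals score high only in the binding and
dimerization assays — the ones shared between agonist and antagonist
pathways — which is exactly why a reduced agonist battery mistakes them for
agonists. Noise is truncated-normal (sd 0.03, clipped to \[0, 1\]) and is
applied only to assay–archetype pairs with a nonzero mean: inactive pairs
score exactly 0, as in real AUC tables, which keeps active-assay counts
archetype-determined and makes planted confusion and triage counts exact at
zero noise. Confidence bounds are `med ± 0.08` per assay (clipped and
order-corrected), wide enough that borderline chemicals' subset intervals
straddle the 0.1 threshold.

What the generator does *not* emulate: correlated assay noise, chemical
series straddling cluster boundaries (activity cliffs), heteroscedastic
confidence intervals, and full-model confidence bounds. Passing tests
therefore demonstrate the pipeline's correctness and its behaviour under
idealized cluster/activity structure — not performance claims about any
real inventory.

## Problem sizes and determinism

The analysis drivers and the acceptance script run a 600-chemical universe
(40 clusters × 15) with a 450-chemical tested set; the test suite uses
universes of 60–600 chemicals. These sizes were chosen so that every stage's
behaviour — partition recovery, mapping self-consistency, confusion
conservation, triage bands — is already stable while a full run completes in
seconds; the pipeline itself is O(n²) in memory for the distance matrix and
has been run at a few thousand chemicals without issue. Every stochastic
step (universe draw, archetype draw, 80/20 split) flows from a single
required seed; no function has a hidden default seed, and generators restore
the caller's RNG state.

## Known limitations

* Ward linkage on a full distance matrix does not scale to inventories of
  hundreds of thousands of chemicals without sub-sampling or approximate
  methods; the intended scale is the 10^3–10^4 range of screening
  inventories.
* The antagonist axis enters only as an input flag from the full pathway
  model; no antagonist model is fit here, so the triage's first rule is only
  as good as the upstream flag.
* Fingerprint generation from structures (SMILES → ToxPrint) is out of
  scope; fingerprints are consumed as data.
* With duplicate fingerprints placed in different clusters by the upstream
  partition, KNN tie rules make assignment deterministic but necessarily
  arbitrary; such cases are reported by the self-consistency check rather
  than resolved.
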