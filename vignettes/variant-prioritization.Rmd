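---
title: "Prioritizing nonsynonymous SNVs with variantForest: model and methods"
author: "variantForest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing nonsynonymous SNVs with variantForest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variantForest)
```

## The problem and the model

Exome sequencing of a patient cohort typically leaves dozens to thousands
of rare nonsynonymous single-nucleotide variants (nsSNVs) after frequency
and database filtering. Deleteriousness predictors (SIFT, PolyPhen2, CADD,
conservation scores, ...) say whether a variant is likely to damage its
protein, but damage is not disease-specific: a variant can be maximally
deleterious and still be irrelevant to the disease under study. Conversely,
gene-level guilt-by-association methods connect genes to a disease but
cannot distinguish a causative variant from a benign polymorphism in the
same gene.

`variantForest` treats the two signals as complementary coordinates of a
single supervised problem. A (disease, variant) pair is described by a
19-dimensional feature vector:

* **11 variant-level deleteriousness scores** — SIFT, PolyPhen2, LRT,
  MutationTaster, MutationAccessor, MSRV, GERP, Phylop, SiPhy, CADD,
  SInBaD — consumed from a precomputed score table, never recomputed.
* **8 gene-level association scores** — one per genomic data source
  (expression, gene ontology, pathway, protein sequence, protein domain,
  protein–protein interaction, transcriptional regulation, microRNA
  regulation), each the summed functional similarity between the variant's
  host gene and the query disease's *seed genes*.

A probability random forest is trained on labeled pairs (causative =
positive, irrelevant = negative); its predicted positive-class probability
is the prediction score, and candidates are ranked by it.

## Gene functional similarities

Each genomic source yields a raw gene-by-gene similarity $r_{gh} \in
[0, 1]$:

| source | gene representation | raw similarity |
|--------|---------------------|----------------|
| Exp | expression profile across tissues | absolute Pearson correlation |
| GO | information-content weighted term vector | cosine |
| KEGG, Pfam, miRNA | binary membership vector | cosine |
| TSFC | binding-site count vector per transcription factor | cosine |
| Seq, PPI | node in an undirected network | $1 - d_{gh}/D$ from BFS distance |

with the information content of a term defined as the negative log of its
relative annotation frequency, and $D$ the largest finite distance in the
network (disconnected pairs get 0). Every raw matrix is then sharpened by
the exponential transformation

$$ S_{gh} = \exp\!\left(\frac{r_{gh} - 1}{\sigma}\right), $$

where $\sigma$ is the standard deviation of all off-diagonal raw
similarities. The transform fixes $r = 1 \mapsto 1$, is strictly
increasing, and compresses weak background similarity toward zero, so
association sums are dominated by genuinely similar seed genes.

Numerical conventions, chosen once and asserted by the test suite:

* $\sigma$ is computed over off-diagonal entries only — the structurally-1
  diagonal would otherwise shrink it.
* A constant expression profile has undefined correlation and gets raw
  similarity 0.
* Information content and IDF use the natural logarithm; cosine similarity
  is invariant to the base, which the tests verify numerically.
* Genes absent from a source keep zero rows ("coverage convention"), so an
  uncovered gene contributes nothing to any association sum.
* Sequence-similarity networks are consumed pre-thresholded (edges are
  alignment hits below an e-value cutoff applied upstream); the package
  never runs an aligner.

## Phenotype similarity and seed genes

Disease records arrive as a disease × standardized-term count matrix (the
output of an upstream medical text-mining step; producing it is out of
scope). Records are TF-IDF weighted — term frequency is the within-record
relative frequency, inverse document frequency the negative log of the
fraction of records containing the term — and compared by cosine
(`phenotypeSimilarity()`).

For a query disease, `topSimilarDiseases()` returns its `k = 10` most
similar diseases (the query always excluded, boundary ties broken by
lexicographic id so results are deterministic), and `collectSeedGenes()`
takes the union of genes known to be associated with the query or any of
those diseases. The association score of a candidate gene under source $s$
is $\sum_{g \in \text{seeds}} S^{(s)}_{\text{cand},\, g}$.

## Feature normalization

All 19 features are mapped to $[0, 1]$ with "larger = stronger evidence":
SIFT and LRT are flipped to $1 - x$ first (their native convention is
smaller-is-worse), then every score is min–max normalized with bounds taken
from the *whole* reference score table (on the flipped scale for
SIFT/LRT). Association scores are min–max normalized per source with
bounds over the full disease × gene association score matrix — a design
choice: raw association sums would otherwise live on incomparable scales
across sources. Missing values — a
variant absent from a score column, a gene uncovered by a source — are
exactly 0 after normalization. Out-of-range raw values are clipped rather
than rejected, since new data may exceed historical bounds.

## Training pairs, negative sampling, leakage control

Positives are the known (disease, causative variant) pairs among the
training diseases. Negatives are sampled uniformly without replacement
from the Cartesian product of training diseases × neutral training
variants, exactly as many as there are positives. Two rules remove
train/test information sharing in cross-validation:

1. **Seed filtering** (`filterSeedsUnbiased()`): seed genes associated
   with any test disease, or hosting any test variant, are removed before
   association scores are computed.
2. **Gene-level holdout** (`eliminateLeakage()`): training pairs whose
   variant lies in a gene hosting any held-out test variant are discarded.

`runCrossValidation()` partitions diseases into five test subsets
(shuffled round-robin; with equal positives per disease this balances
positive variants per fold, the quantity that matters) and the neutral
variants into two halves, one for training and one for testing. Each
positive test variant is prioritized against the configured negative test
sample: `"neutral"` (the held-out neutral half), `"disease"` (causative
variants of the training diseases, a self-contained analogue of an
external disease-variant control set), or `"combined"`. The disease
control is drawn from the training knowledge base — as an external control
catalogue would be — so it does not enter the gene-holdout filter; the
genuinely held-out variants (test positives and the neutral test half) do.

## Evaluation metrics

* **Rank ratio** — a variant's rank divided by its list length; ties get
  average ranks. One positive against $n$ negatives has list length
  $n + 1$.
* **MRR** — rank ratios averaged within disease, then across diseases
  (both unweighted).
* **Rank-ROC AUC** — per disease, sensitivity (positive ratios $\le t$)
  against 1 − specificity (negative ratios $\le t$) over the distinct
  observed rank-ratio values plus endpoints, trapezoid-integrated. This
  equals the Mann–Whitney statistic, which the tests verify by exhaustive
  pairwise comparison. Negative rank ratios are pooled over the
  per-positive ranking lists, matching the definition of the curve over
  "these lists".
* **FPR at a score threshold** — per-disease fraction of neutral variants
  scoring at or above the threshold, averaged over diseases.
* **Top-k enrichment** — one-sided hypergeometric tail
  $P(X \ge x)$ for $x$ functional variants among the top $n$ of $N$
  candidates containing $K$ functional ones, computed through the
  log-space CDF (`stats::phyper`), never via factorials.
* **Random-guess baseline** — each positive uniformly placed among
  $n_{neg} + 1$ positions gives expected top-k count
  $n_{pos} \cdot \min(k, n_{neg}+1)/(n_{neg}+1)$.

## The synthetic universe

Real-scale inputs (curated variant databases, full genomic sources) are
far beyond a package test bed, so `generateUniverse()` fabricates a
complete, self-contained universe with a *planted* causal chain:

* Diseases come in phenotype clusters that share standardized terms;
  each cluster owns a gene pool and each disease a module drawn from its
  cluster's pool.
* Pool genes are made coherent in every source — co-clustered expression,
  shared memberships and annotations, elevated binding-site counts,
  densified within-pool network edges — in linear proportion to
  `signal_strength`.
* Causative variants lie in module genes and draw each deleteriousness
  score from a damaging-mode Beta(5, 2) (on the unit scale, mapped to the
  score's native range and orientation) with probability
  `signal_strength`; neutral variants always draw from the benign-mode
  Beta(2, 5). 20% of score values are masked missing so the
  missing-data path is always exercised.

At `signal_strength = 0` the pools leave no trace in any source and
causative scores are distributed exactly like neutral ones, giving a true
null. The reference conditions are 300 genes, 40 diseases in 8 clusters,
400 causative and 800 neutral variants, signal 0.8 — large enough for a
stable AUC estimate over 5 seeds, small enough that the full benchmark
(similarity construction, five folds, forest training, prioritization)
runs in well under a minute per seed. Under these conditions the
end-to-end cross-validation reaches mean AUC above 0.9, and the null
stays within [0.4, 0.6]; `scripts/acceptance.R` recomputes both.

What the generator does *not* emulate — and hence what passing benchmarks
cannot certify about real data: realistic allele-frequency spectra and
population structure; correlated missingness (real score coverage is
source- and region-biased, not uniform); heavy-tailed gene-set sizes and
scale-free network topology; disease heterogeneity (every synthetic
disease has the same module size and variant count); and annotation bias
toward well-studied genes.

## Random forest settings and determinism

The forest uses 500 trees, $\lfloor\sqrt{19}\rfloor = 4$ features per
split, unlimited depth, and a fixed seed, grown single-threaded through
`ranger` so that a seed fully determines the fit and its predictions (the
tests assert bit-identical rescoring). These defaults are conventional
for a 19-feature classification problem and are all overridable;
performance on the benchmark is insensitive to moderate changes.

## Design choices made where the design was open

* The exponential transform $\exp((r-1)/\sigma)$ and the
  distance-to-similarity map $1 - d/D$ are this package's frozen
  definitions; they deliver the required range, monotonicity and endpoint
  behavior (r = 1 maps to 1, disconnected pairs to 0) with no tunable
  constants beyond $\sigma$ itself.
* The canonical feature order (11 variant scores, then 8 association
  scores, each in the order of `featureNames()`) is fixed for model
  reproducibility; models refuse to score a mismatching layout.
* Average-rank tie handling everywhere a rank is produced: deterministic
  and unbiased.
* Top-k counts use the integer cutoff after average-rank assignment.
* In free prioritization (outside cross-validation) the candidate's own
  gene may legitimately be a seed; the real-data protocol of excluding
  seed genes that host candidate variants is available through
  `filterSeedsUnbiased()`, and the cross-validation applies it always.

## Known limitations

* Association scores are identical for all variants in one gene, so
  within-gene ordering rests entirely on the 11 variant scores.
* Diseases without phenotype records and genes uncovered by every source
  fall back to variant-only and zero-feature scoring respectively.
* The package consumes precomputed scores, networks and term counts; it
  does not run predictors, aligners, PWM scanners or text mining.
* The disease-control option in cross-validation is an internal analogue
  of an external disease-variant catalogue, not a drop-in replacement for
  one.
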