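---
title: "Ontology-aware hierarchical phenotype prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-aware hierarchical phenotype prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierpheno)
```

# The problem and the model

Loss of function of a single gene manifests as a set of abnormal
phenotypes, catalogued as Human Phenotype Ontology (HPO) classes. The
premise of this package is that those phenotypes are largely predictable
from what the gene product does — its Gene Ontology (GO) annotations —
and from where the gene is expressed. Prediction is a massively
multi-label problem whose label space is not flat: HPO is a DAG under
`is_a`, and a valid annotation set must respect the true path rule (an
annotation to a class implies all its superclasses).

The predictor is a small fully connected network. The input is the
concatenation of a sparse binary vector over the GO feature vocabulary
(all GO classes occurring in the propagated training annotations) and a
per-gene standardised tissue expression profile. One ReLU reduction
layer compresses the GO block; dropout follows it; the expression block
is concatenated to the reduced representation; a sigmoid layer emits one
score per predictable phenotype class.

The distinctive component is the **hierarchical classification layer**.
Let `S` be the reflexive subclass indicator over the ordered class set
(`S[i, j] = 1` iff class *j* is a subclass of class *i*, built by
`subclass_matrix()`). The layer maps a score vector `x` to

```
h(x)[i] = max over { j : S[i, j] = 1 } of x[j]
```

— elementwise masking by the subclass rows followed by a max-reduction.
Its output always satisfies `score(ancestor) >= score(descendant)`, so
predictions are ontology-consistent *by construction* rather than by
post-processing. The operator is idempotent, monotone, and inflationary
(`h(x) >= x`), properties the test suite asserts against a brute-force
descendant-max oracle on hundreds of random DAGs. Because the max is
almost-everywhere differentiable, the layer sits inside the network
during training: the loss is evaluated on the pooled scores and the
gradient of each output is routed to the descendant that achieved the
maximum. A flat variant omits the layer; `true_path_fix()` applies the
identical operator post hoc, which lets the package quantify what
training *through* the hierarchy adds over fixing afterwards.

## Training procedure and numerical choices

Training minimises binary cross-entropy summed over classes — the
standard pairing for a sigmoid multi-label head; in hierarchical mode it
is computed on the post-pooling scores, so the hierarchy participates in
optimisation. The optimiser is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8)
with mini-batches. Early stopping monitors validation loss and restores
the best weights. Scores are clamped to [1e-7, 1 − 1e-7] inside the loss
and its gradient; at the routed maximum the sigmoid factor cancels
analytically, keeping the update numerically stable. Max ties are broken
by the first descendant in class order; since tied scores receive the
same pooled value, the choice only affects which unit receives the
gradient, not the output. Weights use He initialisation on the ReLU
layer and 1/√d scaling on the output layer. A NaN loss aborts with a
diagnostic rather than training on.

Defaults (`model_config()`): one reduction layer of 1024 units, dropout
0.5, learning rate 0.001, batch size 32, patience 5, at most 100 epochs.
These sit inside the random-search grid exposed by `random_search()`
(units 250–4000 in steps of 250, dropout {0.2, 0.5}, learning rate
{0.01, 0.001, 0.0001}). The reproducibility contract is: a fixed
`seed` plus single-threaded execution reproduces scores to ~1e-6;
bit-exactness across platforms/BLAS builds is not promised, though
repeated prediction from a saved model is byte-identical.

The expression block joins *after* the reduction layer: the reduction
exists to compress the very sparse, high-dimensional GO indicator,
whereas the 53-tissue profile is already dense and low-dimensional;
compressing it jointly would let the large GO block dominate the shared
weights. The concatenation point is configurable in the architecture
sense (a model without expression simply omits the block).

## Ontology handling

Only `is_a` edges define the hierarchy — HPO is `is_a`-structured, and
phenotype propagation semantics are defined on subclass axes;
`part_of` relationships encountered in an OBO file are ignored with a
warning. Obsolete terms are dropped, `alt_id`s resolve to primary ids,
and `replaced_by` is followed once. Construction fails on cycles
(Kahn's algorithm), and the topological order is reused for closure
computations.

Two information-content variants are maintained because they serve
different metrics:

* **conditional** (for Smin): IC(c) = −log Pr(c | parents(c)), the count
  of genes with c over the count of genes carrying *all* parents of c.
  The multi-parent denominator is the intersection — the strictest
  reading, and the one under which propagated counts always give
  probabilities ≤ 1.
* **marginal** (for Resnik): IC(c) = −log(n_c / n).

Log base is 2 by default and configurable — Smin magnitudes scale with
it, so it is stated rather than implied. Zero-probability classes get
IC 0 in conditional mode, and lookups of classes absent from a marginal
table return the maximum observed IC; both choices keep Smin and Resnik
finite instead of propagating infinities. The IC corpus is the training
genes' annotations by default (for the gene–disease application, the
disease corpus can be used instead; the ranking only needs a fixed,
non-degenerate corpus, and which corpus is used is an explicit
argument).

## Evaluation metrics

Protein-centric precision/recall scan thresholds t ∈ {0, 0.01, …, 1};
class membership in a prediction set requires a score **strictly**
greater than t. Precision is averaged over the m(t) genes with at least
one prediction, recall over all n genes; Fmax is the maximum harmonic
mean. Thresholds with m(t) = 0 contribute precision 0 and are skipped in
the maximisation, so an all-zero predictor scores Fmax 0 by definition.
Genes with empty truth sets are excluded from the protein-centric
averages (their recall is undefined) but retained as negatives in the
term-centric AUROC. Ontology roots are excluded from the class universe
(they are annotated to every gene after propagation and carry no
information); this is configurable.

Smin is min over t of √(ru(t)² + mi(t)²) with ru/mi the mean summed
conditional IC of missed and wrongly predicted classes. AUPR integrates
the same averaged curve (trapezoid over recall-sorted points, anchored
at recall 0 with the lowest-recall precision); a micro-averaged variant
pooling gene–class pairs is available behind a flag since both
conventions are in circulation. Term-centric AUROC uses the rank
statistic with mid-rank ties — a constant predictor scores exactly 0.5 —
and skips classes lacking a positive or a negative gene.

The interaction-network overlap test asks whether predicted-but-unknown
(false positive) genes are adjacent to known phenotype genes more often
than random gene sets of the same size would be; the p-value uses the
add-one permutation rule (1 + #{null ≥ observed})/(1 + N), which cannot
return 0. Phenotypes whose predictions contain no false positive are
skipped in the mean on both the observed and null sides.

## Gene–disease ranking

Genes and diseases are compared by best-match-average Resnik similarity:
all pairwise class similarities (IC of the most informative common
ancestor, reflexive) are computed, each class is matched to its best
counterpart, and the two directional averages are averaged. Candidate
diseases are ranked per gene with **mid-rank** tie handling — with heavily
tied similarity scores (e.g. identical annotation sets for every gene)
optimistic ranking would overstate performance, and mid-ranks are what
make a chance ranking come out at AUROC 0.5 exactly in expectation.
Per-pair AUROC is (n_candidates − rank)/(n_candidates − 1), macro-averaged
over the true pairs; Hits@k is the percentage of pairs ranked ≤ k.
Genes with identical annotation profiles share one scoring pass.

## The synthetic-data generator

`gen_ontology()` grows a single-rooted DAG: class *i* draws 1..max_parents
parents among classes 1..*i*−1, acyclic by construction.
`gen_planted()` emulates the annotation corpora the pipeline consumes:

* each gene samples direct GO annotations (1 + Poisson-distributed
  count, mean 8 by default) which are ancestor-closed into features;
* each *leaf* phenotype receives a rule — `rule_size` GO classes drawn
  from the propagated GO set of a randomly chosen gene, so rules have
  realistic co-occurrence support instead of being unsatisfiable random
  conjunctions;
* a gene is labelled with a leaf iff it carries the full rule; labels
  are flipped with probability `noise_rate` and then ancestor-closed.
  Planting on leaves and closing upward mirrors how specific clinical
  annotations propagate in HPO;
* expression is standard normal per gene and tissue (53 tissues by
  default, matching the GTEx panel width), with a +1 sd shift in one
  phenotype-specific tissue for labelled genes, so the expression block
  carries signal whose contribution can be probed qualitatively.

What the generator does *not* emulate: the long-tailed class-frequency
spectrum of real HPO annotations, inter-tissue expression covariance,
annotation incompleteness bias, and literature-driven correlation
between GO and HPO curation. Passing the planted-recovery tests
therefore demonstrates that the implementation learns and evaluates
what it claims on data whose generating process is known — not that the
reported synthetic metric levels transfer to real corpora, where
published results of comparable methods sit far below the noiseless
planted ceiling.

## Problem sizes used in the shipped experiments

The test suite and acceptance script run at desk scale, chosen so the
full pipeline (including two trained networks) completes in a few
minutes on one CPU: planted recovery uses 500 genes, 200 GO classes,
100 HPO classes, rule size 2, noise 0, an 80/10/10 gene-level split and
the default model configuration; the ranking experiments use 300 genes
and 400 diseases over a 150-class ontology; oracle-equivalence suites
use 100–200 random DAGs of up to 60 classes. The same code paths scale
to corpus-sized inputs (the dense subclass matrix is the main memory
consumer at ~k² for k predictable classes).

## Known limitations

* Only `is_a` semantics; no OWL reasoning or cross-ontology axioms.
* The predictable class set is limited to classes with enough training
  genes (default ≥ 10); rarer, more specific classes are evaluated as
  unrecoverable false negatives, exactly as in the metric definitions.
* The dense subclass matrix and dense feature blocks are comfortable up
  to a few thousand classes / tens of thousands of features; beyond
  that sparse structures would be warranted.
* Gene/protein identifier reconciliation is left to the caller (a
  two-column mapping table can be applied before reading); no remote
  lookups are performed anywhere.
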