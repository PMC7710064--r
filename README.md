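# hierpheno

Predicting the phenotypic consequences of single-gene loss of function is
a core problem in human genetics: given what a gene product *does*
(its Gene Ontology annotations, plus where it is expressed), which
abnormal phenotypes (Human Phenotype Ontology classes) would its loss
produce? `hierpheno` implements an ontology-aware hierarchical
multi-label classifier for this task, together with the standard
baselines, CAFA-style evaluation metrics, semantic-similarity-based
gene–disease ranking, and a synthetic-data generator with planted
GO→HPO rules so the whole pipeline can be exercised without any external
downloads.

It is aimed at computational biologists working on phenotype and
function prediction: the package reads OBO ontologies, GAF / TSV
annotation tables and gene×tissue expression matrices, and produces
ontology-consistent phenotype scores per gene.

## The method

Gene features are a sparse binary vector over the GO classes seen in the
propagated training annotations, concatenated with per-gene z-scored
tissue expression. A fully connected reduction layer (ReLU, dropout)
compresses the GO block; a sigmoid output layer produces one score per
predictable HPO class (classes with ≥ 10 annotated training genes). On
top sits the **hierarchical classification layer**: with **x** the
sigmoid scores over the class set *P* and *s*(p<sub>i</sub>) the binary
indicator of the reflexive subclasses of p<sub>i</sub>,

&nbsp;&nbsp;&nbsp;&nbsp;h(**x**)<sub>i</sub> = max ( **x** ⊙ s(p<sub>i</sub>) )

i.e. each class's score becomes the maximum over its descendants. The
output is consistent with the true path rule by construction, and the
layer is used *during training* (binary cross-entropy on the pooled
scores, gradients routed through the max) as well as at prediction time.
Flat models are supported too, repaired post hoc with `true_path_fix()`.

Around the classifier the package provides:

* **Baselines** — the naive class-frequency predictor
  S(g,p) = N<sub>p</sub>/N<sub>total</sub>, and the GO↔HPO co-occurrence
  mapping S(p,f) = 2·N<sub>p&f</sub>/(N<sub>p</sub>+N<sub>f</sub>).
* **Evaluation** — protein-centric Fmax (threshold grid 0, 0.01, …, 1),
  Smin from parent-conditional information content, AUPR, term-centric
  mean AUROC, and a permutation test for whether predicted genes overlap
  interaction-network neighbourhoods of known phenotype genes.
* **Gene–disease ranking** — Resnik similarity (IC of the most
  informative common ancestor) aggregated by best-match-average, with
  Hits@10/Hits@100, mean rank and a rank-based AUROC.
* **Simulation** — random single-rooted DAG ontologies and planted-rule
  datasets in which each leaf phenotype is triggered by a small
  conjunction of GO classes, so recovery is checkable exactly.

## Worked example

```r
library(hierpheno)

go  <- gen_ontology(120, 2, seed = 1, prefix = "GO")
hpo <- gen_ontology(60, 2, seed = 2, prefix = "HP")
ds  <- gen_planted(go, hpo, n_genes = 400, rule_size = 2, noise_rate = 0, seed = 3)

sp   <- split_by_gene(ds$features$gene_ids, folds = 5, seed = 4)
fold <- sp$folds[[1]]
classes <- select_classes(subset_genes(ds$labels, fold$train), hpo, min_genes = 10)
S <- subclass_matrix(hpo, classes)

feats <- function(g) build_features(subset_genes(ds$go_annots, g),
                                    ds$features$go_vocab,
                                    ds$expression[g, , drop = FALSE])
model <- train_model(feats(c(fold$train, fold$valid)), ds$labels, S,
                     model_config(seed = 5), valid_genes = fold$valid)
model
#> pheno_model (hierarchical): 120 GO features + 53 expression -> 1024 hidden
#>   -> 59 classes; best valid loss 0.02023 (epoch 59)

preds <- predict(model, feats(fold$test))
truth <- subset_genes(ds$labels, fold$test)
ic    <- conditional_ic(subset_genes(ds$labels, fold$train), hpo)
evaluate_predictions(truth, preds, hpo, ic)
#> Fmax 0.996 (t=0.44, pr 0.995, rc 0.996)  Smin 0.145  AUPR 1.000  AUROC 1.000

prior <- naive_fit(subset_genes(ds$labels, fold$train))
evaluate_predictions(truth, naive_predict(prior, fold$test), hpo, ic)
#> Fmax 0.848 (t=0.39, pr 0.811, rc 0.889)  Smin 5.437  AUPR 0.939  AUROC 0.500
```

The hierarchical model recovers the planted rules almost perfectly on
held-out genes (Fmax 0.996, near-zero remaining uncertainty), while the
naive predictor — identical scores for every gene — reaches a deceptively
high Fmax driven by frequent shallow classes but is uninformative at the
term level (AUROC exactly 0.5). `run()` (and the `inst/cli/hierpheno`
script) wires the same steps into `simulate`, `train`, `predict`,
`evaluate`, `rank-diseases` and `overlap-test` subcommands driven by a
YAML config.

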