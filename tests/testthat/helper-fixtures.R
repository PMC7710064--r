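# Small fixtures shared across test files; everything is built in code.

# linear chain ontology: ids[1] is the root, each later id is_a its
# predecessor
chain_ontology <- function(ids = c("A", "B", "C")) {
  edges <- if (length(ids) > 1)
    data.frame(child = ids[-1], parent = ids[-length(ids)])
  ontology(ids, edges)
}

# diamond: D is_a B, D is_a C, B is_a A, C is_a A
diamond_ontology <- function() {
  ontology(c("A", "B", "C", "D"),
           data.frame(child = c("B", "C", "D", "D"),
                      parent = c("A", "A", "B", "C")))
}

# random annotation corpus over an ontology (direct, unpropagated)
random_annotations <- function(ont, n_genes, mean_classes = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_genes), function(i) {
    k <- 1 + rpois(1, mean_classes - 1)
    sample(ont$classes, min(k, length(ont$classes)))
  })
  names(sets) <- genes
  annotation_set(genes, sets)
}

# the worked 2-gene / 5-class chain fixture used in the metric tests:
# chain A <- B <- C <- D <- E, truth and scores hand-specified,
# conditional IC from a 4-gene corpus
worked_fixture <- function() {
  ont <- chain_ontology(c("A", "B", "C", "D", "E"))
  truth <- annotation_set(c("g1", "g2"),
                          list(g1 = c("A", "B", "C"),
                               g2 = c("A", "B", "C", "D", "E")),
                          propagated = TRUE)
  scores <- rbind(g1 = c(A = 0.9, B = 0.7, C = 0.55, D = 0.3, E = 0.1),
                  g2 = c(A = 1.0, B = 0.8, C = 0.6, D = 0.4, E = 0.2))
  preds <- prediction_matrix(c("g1", "g2"), colnames(scores), scores)
  ic_corpus <- annotation_set(
    sprintf("c%d", 1:4),
    list(c1 = "A", c2 = c("A", "B"), c3 = c("A", "B", "C"),
         c4 = c("A", "B", "C", "D", "E")),
    propagated = TRUE)
  ic <- conditional_ic(ic_corpus, ont)
  list(ont = ont, truth = truth, preds = preds, ic = ic,
       scores = scores,
       truth_sets = list(g1 = c("A", "B", "C"),
                         g2 = c("A", "B", "C", "D", "E")))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
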