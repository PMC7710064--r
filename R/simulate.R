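#' Generate a random single-rooted ontology
#'
#' Builds a DAG of `n_classes` classes: the first class is the root and
#' every later class draws 1..`max_parents` parents uniformly among
#' earlier classes, so the graph is acyclic by construction. Deterministic
#' under a fixed seed.
#'
#' @param n_classes number of classes (>= 1).
#' @param max_parents maximum parents per non-root class (>= 1).
#' @param seed integer seed.
#' @param prefix identifier prefix (ids look like "SIM:0000001").
#' @return An [ontology()].
#' @export
gen_ontology <- function(n_classes, max_parents = 2, seed = 1,
                         prefix = "SIM") {
  if (n_classes < 1) stop("n_classes must be at least 1")
  if (max_parents < 1) stop("max_parents must be at least 1")
  ids <- sprintf("%s:%07d", prefix, seq_len(n_classes))
  edges <- NULL
  if (n_classes > 1) {
    edges <- with_seed(seed, do.call(rbind, lapply(2:n_classes, function(i) {
      k <- sample.int(min(max_parents, i - 1L), 1)
      data.frame(child = ids[i],
                 parent = ids[sample.int(i - 1L, k)])
    })))
  }
  ontology(ids, edges)
}

#' Generate a planted-rule phenotype prediction dataset
#'
#' Emulates the gene -> (GO annotations, expression) -> phenotype setting
#' with a known ground truth. Each gene samples direct GO annotations
#' (propagated into binary features). Every leaf phenotype class is
#' assigned a rule: a set of `rule_size` GO classes drawn from the
#' propagated GO set of a randomly chosen gene (so rules have realistic
#' co-occurrence support); a gene carries the phenotype iff its propagated
#' GO set contains every rule class. Direct labels are then flipped
#' independently with probability `noise_rate` and closed under HPO
#' ancestors. The expression block is standard normal per gene and tissue,
#' with a `expression_shift` mean shift in one phenotype-specific tissue
#' for labelled genes, making expression informative.
#'
#' With `noise_rate = 0` the labels are a deterministic function of the
#' features through the rules, and regeneration under the same seed is
#' bit-identical.
#'
#' @param go_ont,hpo_ont ontologies from [gen_ontology()].
#' @param n_genes number of genes.
#' @param rule_size GO classes per phenotype rule (>= 1).
#' @param noise_rate per-(gene, leaf) label flip probability.
#' @param expression_tissues number of expression features (53 mirrors the
#'   GTEx tissue panel; 0 disables the block).
#' @param seed integer seed.
#' @param mean_go_annotations mean number of direct GO annotations per
#'   gene (1 + Poisson(mean - 1)).
#' @param expression_shift mean shift (in sd units) added to the
#'   phenotype tissue of labelled genes.
#' @return An object of class `"planted_dataset"`: `go_ontology`,
#'   `hpo_ontology`, `features`, `labels` (propagated), `go_annots`
#'   (propagated), `direct_labels`, `rules`, `expression`, `noise_rate`,
#'   `seed`.
#' @export
gen_planted <- function(go_ont, hpo_ont, n_genes = 500, rule_size = 2,
                        noise_rate = 0, expression_tissues = 53, seed = 1,
                        mean_go_annotations = 8, expression_shift = 1) {
  if (rule_size < 1) stop("rule_size must be at least 1")
  if (rule_size > length(go_ont$classes))
    stop("rule_size exceeds the number of GO classes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    n_direct <- 1L + stats::rpois(n_genes, max(0, mean_go_annotations - 1))
    direct_go <- lapply(n_direct, function(k)
      sample(go_ont$classes, min(k, length(go_ont$classes))))
    names(direct_go) <- genes
    go_annots <- propagate(go_ont, annotation_set(genes, direct_go,
                                                  ontology_id = "GO"))

    has_kids <- vapply(hpo_ont$children, length, 1L) > 0
    leaves <- setdiff(hpo_ont$classes[!has_kids], hpo_ont$roots)
    if (length(leaves) == 0) leaves <- setdiff(hpo_ont$classes, hpo_ont$roots)
    rules <- lapply(leaves, function(p) {
      src <- go_annots$assignments[[sample(genes, 1)]]
      sample(src, min(rule_size, length(src)))
    })
    names(rules) <- leaves

    direct_labels <- matrix(FALSE, n_genes, length(leaves),
                            dimnames = list(genes, leaves))
    for (p in leaves) {
      rule <- rules[[p]]
      direct_labels[, p] <- vapply(genes, function(g)
        all(rule %in% go_annots$assignments[[g]]), TRUE)
    }
    if (noise_rate > 0) {
      flips <- matrix(stats::runif(length(direct_labels)) < noise_rate,
                      nrow(direct_labels), ncol(direct_labels))
      direct_labels <- xor(direct_labels, flips)
    }
    label_sets <- apply(direct_labels, 1, function(row)
      colnames(direct_labels)[row], simplify = FALSE)
    labels <- propagate(hpo_ont, annotation_set(genes, label_sets,
                                                ontology_id = "HP"))

    expression <- NULL
    if (expression_tissues > 0) {
      expression <- matrix(stats::rnorm(n_genes * expression_tissues),
                           n_genes, expression_tissues,
                           dimnames = list(genes,
                                           sprintf("tissue_%02d",
                                                   seq_len(expression_tissues))))
      pheno_tissue <- sample.int(expression_tissues, length(leaves),
                                 replace = TRUE)
      names(pheno_tissue) <- leaves
      for (p in leaves) {
        hit <- direct_labels[, p]
        if (any(hit))
          expression[hit, pheno_tissue[[p]]] <-
            expression[hit, pheno_tissue[[p]]] + expression_shift
      }
    }
    vocab <- sort(unique(unlist(go_annots$assignments, use.names = FALSE)))
    features <- build_features(go_annots, vocab, expression)
    structure(list(go_ontology = go_ont, hpo_ontology = hpo_ont,
                   features = features, labels = labels,
                   go_annots = go_annots, direct_labels = direct_labels,
                   rules = rules, expression = expression,
                   noise_rate = noise_rate, seed = seed),
              class = "planted_dataset")
  })
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat(sprintf(paste0("PlantedDataset: %d genes, %d GO classes, %d HPO classes,",
                     " %d planted rules, noise %.2f, seed %d\n"),
              length(x$features$gene_ids), length(x$go_ontology$classes),
              length(x$hpo_ontology$classes), length(x$rules),
              x$noise_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic gene-gene interaction graph with planted modules
#'
#' The genes of each known phenotype set are interconnected with
#' probability `clique_density`; all other gene pairs connect with
#' probability `background_density`. With clique density 1 and background
#' 0 each known set forms a clique and no other edge exists.
#'
#' @param known_sets named list: phenotype -> gene ids (subsets of
#'   `genes`).
#' @param n_genes number of genes in the universe; ids follow the
#'   `gen_planted` naming (g00001, ...) unless `genes` is given.
#' @param clique_density within-module edge probability.
#' @param background_density edge probability elsewhere.
#' @param seed integer seed.
#' @param genes optional explicit gene id vector (overrides `n_genes`).
#' @return Edge data.frame (gene_a, gene_b, score) with score 0.9.
#' @export
gen_interaction_graph <- function(known_sets, n_genes,
                                  clique_density = 1,
                                  background_density = 0, seed = 1,
                                  genes = NULL) {
  stopifnot(clique_density >= 0, clique_density <= 1,
            background_density >= 0, background_density <= 1)
  if (is.null(genes)) genes <- sprintf("g%05d", seq_len(n_genes))
  idx <- stats::setNames(seq_along(genes), genes)
  n <- length(genes)
  in_module <- matrix(FALSE, n, n)
  for (set in known_sets) {
    ii <- idx[intersect(set, genes)]
    if (length(ii) >= 2) in_module[ii, ii] <- TRUE
  }
  pairs <- which(upper.tri(in_module), arr.ind = TRUE)
  prob <- ifelse(in_module[pairs], clique_density, background_density)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < prob)
  data.frame(gene_a = genes[pairs[keep, 1]],
             gene_b = genes[pairs[keep, 2]],
             score = rep(0.9, sum(keep)))
}

#' Write an ontology as an OBO flat file
#'
#' Emits minimal `[Term]` stanzas (id, name, is_a) readable by
#' [parse_obo()].
#'
#' @param ont an [ontology()].
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (c in ont$classes) {
    writeLines(c("[Term]", paste0("id: ", c), paste0("name: ", c),
                 paste0("is_a: ", ont$parents[[c]]), ""), con)
  }
  invisible(path)
}
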