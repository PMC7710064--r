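#' Resnik semantic similarity between two ontology classes
#'
#' The information content of the most informative common ancestor (MICA)
#' of the two classes, under the marginal IC of the annotation corpus.
#' Ancestor sets are reflexive, so `resnik(c, c)` equals IC(c); two
#' classes whose only common ancestor is a root with IC 0 score 0.
#'
#' @param c1,c2 class identifiers in `ont`.
#' @param ic a marginal-mode `"ic_table"` (see [marginal_ic()]).
#' @param ont an [ontology()].
#' @return Non-negative scalar similarity.
#' @export
resnik <- function(c1, c2, ic, ont) {
  for (c in c(c1, c2))
    if (!(c %in% ont$classes)) stop("class not in ontology: ", c)
  common <- intersect(closure(ont, c1, "ancestors"),
                      closure(ont, c2, "ancestors"))
  if (length(common) == 0) return(0)
  max(ic_value(ic, common))
}

# pairwise Resnik similarities between two class vectors, sharing one
# ancestor-closure table; used by bma() and the disease ranking
sim_matrix <- function(A, B, ic, ont, anc = NULL) {
  if (is.null(anc)) anc <- ancestor_sets(ont)
  for (c in unique(c(A, B)))
    if (!(c %in% ont$classes)) stop("class not in ontology: ", c)
  icc <- ic_value(ic, ont$classes)
  M <- matrix(0, length(A), length(B), dimnames = list(A, B))
  for (i in seq_along(A)) {
    ia <- icc[anc[[A[i]]]]
    for (j in seq_along(B)) {
      common <- intersect(names(ia), anc[[B[j]]])
      if (length(common)) M[i, j] <- max(ia[common])
    }
  }
  M
}

#' Best-match-average similarity of two annotation sets
#'
#' Averages, for each class of one set, its best Resnik match in the
#' other, and takes the mean of the two directions:
#' (avg_a max_b s(a,b) + avg_b max_a s(a,b)) / 2. Symmetric in A and B.
#'
#' @param A,B non-empty character vectors of class ids.
#' @param ic a marginal-mode `"ic_table"`.
#' @param ont an [ontology()].
#' @return Non-negative scalar similarity.
#' @export
bma <- function(A, B, ic, ont) {
  if (length(A) == 0 || length(B) == 0)
    stop("best-match-average requires two non-empty class sets")
  M <- sim_matrix(unique(A), unique(B), ic, ont)
  (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
}

#' Rank candidate diseases for genes by phenotype similarity
#'
#' For every gene appearing in the truth pairs, all candidate diseases are
#' scored by best-match-average Resnik similarity between the gene's and
#' the disease's phenotype annotation sets, and ranked in descending order
#' (mid-rank tie handling by default). For each true gene-disease pair the
#' report records the disease's rank; Hits@k is the percentage of pairs
#' ranked at or above k, and the per-pair AUROC is
#' (n_candidates - rank) / (n_candidates - 1), averaged over pairs.
#'
#' @param gene_phenos [annotation_set()] of gene phenotype annotations
#'   (predicted or curated).
#' @param disease_phenos [annotation_set()] of disease phenotype
#'   annotations (diseases play the role of "genes" in the container).
#' @param truth_pairs data.frame with columns `gene` and `disease`.
#' @param ic marginal-mode `"ic_table"` for the Resnik similarity.
#' @param ont the phenotype [ontology()].
#' @param ties `"midrank"` (default), `"optimistic"` (min rank) or
#'   `"pessimistic"` (max rank).
#' @return An object of class `"ranking_report"` with `hits_at_10`,
#'   `hits_at_100` (percent), `mean_rank`, `auroc` and the `per_pair`
#'   data.frame.
#' @export
rank_diseases <- function(gene_phenos, disease_phenos, truth_pairs, ic, ont,
                          ties = c("midrank", "optimistic", "pessimistic")) {
  ties <- match.arg(ties)
  stopifnot(inherits(gene_phenos, "annotation_set"),
            inherits(disease_phenos, "annotation_set"))
  truth_pairs <- as.data.frame(truth_pairs)
  if (!all(c("gene", "disease") %in% names(truth_pairs)))
    stop("truth_pairs needs 'gene' and 'disease' columns")
  diseases <- disease_phenos$gene_ids
  bad <- setdiff(truth_pairs$disease, diseases)
  if (length(bad) > 0)
    stop("truth pair references unknown disease: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(truth_pairs$gene, gene_phenos$gene_ids)
  if (length(bad) > 0)
    stop("truth pair references unannotated gene: ",
         paste(utils::head(bad, 5), collapse = ", "))

  anc <- ancestor_sets(ont)
  n_cand <- length(diseases)
  tie_method <- switch(ties, midrank = "average", optimistic = "min",
                       pessimistic = "max")
  # genes with identical annotation profiles share one scoring pass
  profiles <- vapply(gene_phenos$assignments[unique(truth_pairs$gene)],
                     function(s) paste(sort(s), collapse = "|"), "")
  rank_cache <- new.env(parent = emptyenv())
  ranks_for <- function(gene) {
    key <- profiles[[gene]]
    if (!is.null(rank_cache[[key]])) return(rank_cache[[key]])
    A <- gene_phenos$assignments[[gene]]
    if (length(A) == 0) stop("gene has an empty phenotype set: ", gene)
    scores <- vapply(diseases, function(d) {
      B <- disease_phenos$assignments[[d]]
      if (length(B) == 0) return(0)
      M <- sim_matrix(unique(A), unique(B), ic, ont, anc)
      (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
    }, 1)
    r <- rank(-scores, ties.method = tie_method)
    rank_cache[[key]] <- r
    r
  }
  per_pair <- do.call(rbind, lapply(seq_len(nrow(truth_pairs)), function(i) {
    g <- truth_pairs$gene[i]; d <- truth_pairs$disease[i]
    r <- ranks_for(g)[[d]]
    data.frame(gene = g, disease = d, rank = r, n_candidates = n_cand)
  }))
  auroc <- mean((n_cand - per_pair$rank) / (n_cand - 1))
  structure(list(hits_at_10 = 100 * mean(per_pair$rank <= 10),
                 hits_at_100 = 100 * mean(per_pair$rank <= 100),
                 mean_rank = mean(per_pair$rank),
                 auroc = auroc, per_pair = per_pair),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("Gene-disease ranking: Hits@10 %.1f%%, Hits@100 %.1f%%, mean rank %.2f, AUROC %.3f (%d pairs)\n",
              x$hits_at_10, x$hits_at_100, x$mean_rank, x$auroc,
              nrow(x$per_pair)))
  invisible(x)
}

#' Write a ranking report (JSON summary + optional TSV ranking table)
#'
#' @param report a `"ranking_report"`.
#' @param path JSON output path.
#' @param table_path optional TSV path for the per-pair ranks.
#' @export
write_ranking <- function(report, path, table_path = NULL) {
  x <- unclass(report)
  pp <- x$per_pair; x$per_pair <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(table_path))
    utils::write.table(pp, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
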