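#' Naive frequency predictor
#'
#' The CAFA naive baseline assigns every query gene the same score for a
#' phenotype class p: S(g, p) = N_p / N_total, the fraction of training
#' genes annotated with p. Classes unseen in training score 0.
#'
#' @param train_phenos a propagated phenotype [annotation_set()].
#' @return An object of class `"naive_prior"` with `class_scores` (named
#'   numeric in \[0,1\]) and `n_total`.
#' @export
naive_fit <- function(train_phenos) {
  stopifnot(inherits(train_phenos, "annotation_set"))
  if (length(train_phenos$gene_ids) == 0) stop("empty training set")
  if (!isTRUE(train_phenos$propagated))
    stop("naive_fit expects a propagated annotation set")
  counts <- class_counts(train_phenos)
  structure(list(class_scores = counts / length(train_phenos$gene_ids),
                 n_total = length(train_phenos$gene_ids)),
            class = "naive_prior")
}

#' Predict with the naive prior
#'
#' Every test gene receives the identical class-frequency score vector.
#' Under propagated training annotations a parent is always at least as
#' frequent as any child, so the rows are hierarchically consistent as-is.
#'
#' @param prior a `"naive_prior"` from [naive_fit()].
#' @param test_gene_ids genes to score.
#' @param class_order optional class ordering; defaults to the sorted
#'   training classes.
#' @return A [prediction_matrix()].
#' @export
naive_predict <- function(prior, test_gene_ids, class_order = NULL) {
  stopifnot(inherits(prior, "naive_prior"))
  if (is.null(class_order)) class_order <- sort(names(prior$class_scores))
  row <- prior$class_scores[class_order]
  row[is.na(row)] <- 0
  scores <- matrix(rep(as.numeric(row), each = length(test_gene_ids)),
                   nrow = length(test_gene_ids),
                   dimnames = list(test_gene_ids, class_order))
  prediction_matrix(test_gene_ids, class_order, scores, consistent = TRUE)
}

#' Fit the GO-to-phenotype co-occurrence mapping
#'
#' Scores every (phenotype class p, GO class f) pair by the Dice-style
#' co-occurrence S(p, f) = 2 N_{p&f} / (N_p + N_f), where counts are taken
#' over the genes shared by the two propagated annotation sets. Pairs with
#' no co-annotated gene are absent (score 0).
#'
#' @param go_annots propagated GO [annotation_set()].
#' @param pheno_annots propagated phenotype [annotation_set()].
#' @return An object of class `"hpo2go_map"` holding the dense score
#'   matrix (phenotype x GO, dimnames set).
#' @export
hpo2go_fit <- function(go_annots, pheno_annots) {
  stopifnot(inherits(go_annots, "annotation_set"),
            inherits(pheno_annots, "annotation_set"))
  shared <- intersect(go_annots$gene_ids, pheno_annots$gene_ids)
  if (length(shared) == 0)
    stop("disjoint gene universes: no gene carries both GO and phenotype ",
         "annotations")
  P <- membership_matrix(subset_genes(pheno_annots, shared))
  F <- membership_matrix(subset_genes(go_annots, shared))
  Npf <- crossprod(P, F)                       # phenotype x GO co-counts
  Np <- colSums(P); Nf <- colSums(F)
  S <- 2 * Npf / outer(Np, Nf, `+`)
  S[Npf == 0] <- 0
  structure(list(pair_scores = S), class = "hpo2go_map")
}

# genes x classes binary membership (classes sorted)
membership_matrix <- function(annots) {
  classes <- sort(names(class_counts(annots)))
  M <- matrix(0, length(annots$gene_ids), length(classes),
              dimnames = list(annots$gene_ids, classes))
  pos <- stats::setNames(seq_along(classes), classes)
  for (g in annots$gene_ids) {
    cs <- annots$assignments[[g]]
    if (length(cs)) M[g, pos[cs]] <- 1
  }
  M
}

#' Predict phenotypes from GO annotations via the co-occurrence mapping
#'
#' A gene's score for phenotype p aggregates the mapping scores of its GO
#' classes (max by default, mean as an alternative); genes with no GO
#' annotation get an all-zero row. The result is made hierarchically
#' consistent with [true_path_fix()].
#'
#' @param mapping an `"hpo2go_map"` from [hpo2go_fit()].
#' @param go_annots propagated GO [annotation_set()] for the query genes.
#' @param gene_ids genes to score.
#' @param ont phenotype [ontology()] used for the consistency fix.
#' @param aggregate `"max"` (default) or `"mean"` over a gene's GO classes.
#' @return A consistent [prediction_matrix()].
#' @export
hpo2go_predict <- function(mapping, go_annots, gene_ids, ont,
                           aggregate = c("max", "mean")) {
  stopifnot(inherits(mapping, "hpo2go_map"))
  aggregate <- match.arg(aggregate)
  S <- mapping$pair_scores
  phenos <- rownames(S)
  scores <- matrix(0, length(gene_ids), length(phenos),
                   dimnames = list(gene_ids, phenos))
  for (g in gene_ids) {
    fs <- intersect(go_annots$assignments[[g]] %||% character(), colnames(S))
    if (length(fs) == 0) next
    sub <- S[, fs, drop = FALSE]
    scores[g, ] <- if (aggregate == "max") apply(sub, 1, max)
                   else rowMeans(sub)
  }
  preds <- prediction_matrix(gene_ids, phenos, scores, consistent = FALSE)
  true_path_fix(preds, ont)
}

#' Write / read a GO-to-phenotype mapping as TSV
#'
#' Three columns: hpo_id, go_id, score; only non-zero pairs are stored.
#'
#' @param mapping an `"hpo2go_map"`.
#' @param path TSV path.
#' @export
write_hpo2go <- function(mapping, path) {
  S <- mapping$pair_scores
  idx <- which(S > 0, arr.ind = TRUE)
  df <- data.frame(hpo_id = rownames(S)[idx[, 1]],
                   go_id = colnames(S)[idx[, 2]],
                   score = S[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hpo2go
#' @export
read_hpo2go <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  phenos <- sort(unique(df$hpo_id)); gos <- sort(unique(df$go_id))
  S <- matrix(0, length(phenos), length(gos),
              dimnames = list(phenos, gos))
  S[cbind(match(df$hpo_id, phenos), match(df$go_id, gos))] <- df$score
  structure(list(pair_scores = S), class = "hpo2go_map")
}
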