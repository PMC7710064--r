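#' Construct an annotation set
#'
#' A mapping gene -> set of ontology classes, with a flag recording whether
#' the sets are closed under ancestors (true-path-rule propagated).
#'
#' @param gene_ids ordered character vector of unique gene identifiers.
#' @param assignments named list (gene -> character vector of class ids);
#'   genes missing from the list get empty sets.
#' @param propagated logical flag.
#' @param ontology_id optional label for the ontology the classes belong to.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(gene_ids, assignments = list(), propagated = FALSE,
                           ontology_id = NA_character_) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  extra <- setdiff(names(assignments), gene_ids)
  if (length(extra) > 0)
    stop("assignments for genes not in gene_ids: ",
         paste(utils::head(extra, 5), collapse = ", "))
  full <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  for (g in gene_ids)
    full[[g]] <- unique(as.character(assignments[[g]] %||% character()))
  structure(list(gene_ids = gene_ids, assignments = full,
                 propagated = isTRUE(propagated), ontology_id = ontology_id),
            class = "annotation_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d distinct classes%s\n",
              length(x$gene_ids), length(class_counts(x)),
              if (x$propagated) " (propagated)" else ""))
  invisible(x)
}

# number of genes annotated with each class
class_counts <- function(annots) {
  all <- unlist(annots$assignments, use.names = FALSE)
  if (length(all) == 0) return(stats::setNames(integer(), character()))
  tab <- table(all)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a gene-to-phenotype annotation table
#'
#' Reads a TSV with one row per (gene, class) pair, in the style of the
#' HPO `genes_to_phenotype` releases. Column mapping is configurable since
#' the file dialect varies across releases.
#'
#' @param path TSV path.
#' @param gene_col,class_col column names (or integer positions) holding
#'   the gene and class identifiers.
#' @param ontology_id label stored on the result.
#' @return An unpropagated [annotation_set()]; duplicate rows deduplicated.
#' @export
read_gene_phenotypes <- function(path, gene_col = "gene_id",
                                 class_col = "hpo_id",
                                 ontology_id = "HP") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  g <- pick_column(df, gene_col, path)
  c <- pick_column(df, class_col, path)
  build_pair_annotations(g, c, ontology_id)
}

pick_column <- function(df, col, path) {
  if (is.numeric(col)) {
    if (col > ncol(df)) stop(sprintf("file %s has no column %d", path, col))
    return(as.character(df[[col]]))
  }
  if (!(col %in% names(df)))
    stop(sprintf("file %s is missing required column '%s'", path, col))
  as.character(df[[col]])
}

build_pair_annotations <- function(genes, classes, ontology_id) {
  keep <- !is.na(genes) & !is.na(classes) & genes != "" & classes != ""
  genes <- genes[keep]; classes <- classes[keep]
  gene_ids <- unique(genes)
  assignments <- lapply(split(classes, factor(genes, levels = gene_ids)), unique)
  annotation_set(gene_ids, assignments, propagated = FALSE,
                 ontology_id = ontology_id)
}

#' Experimental GO evidence codes
#'
#' The evidence codes regarded as experimental when filtering GO
#' annotations: EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC, HTP, HDA, HMP, HGI,
#' HEP. Electronically inferred annotations (IEA) are excluded.
#'
#' @return Character vector of evidence codes.
#' @export
experimental_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC",
    "HTP", "HDA", "HMP", "HGI", "HEP")
}

#' Read gene-product GO annotations
#'
#' Supports GAF 2.x (17-column, `!` comments, `NOT`-qualified rows dropped)
#' and a simple TSV with configurable columns. An evidence-code filter
#' drops rows whose code is not in the given list; `NULL` keeps everything.
#'
#' @param path input path.
#' @param format `"gaf"` or `"tsv"`.
#' @param evidence_filter character vector of evidence codes to keep, e.g.
#'   [experimental_evidence_codes()], or `NULL` for no filtering.
#' @param gene_col,class_col,evidence_col TSV column names/positions
#'   (ignored for GAF).
#' @return An unpropagated [annotation_set()] over the GO.
#' @export
read_go_annotations <- function(path, format = c("tsv", "gaf"),
                                evidence_filter = NULL,
                                gene_col = "gene_id", class_col = "go_id",
                                evidence_col = "evidence") {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (length(lines) == 0)
      return(annotation_set(character(), ontology_id = "GO"))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- vapply(parts, length, 1L)
    if (any(nc < 7)) stop("GAF rows with fewer than 7 columns in ", path)
    genes <- vapply(parts, `[[`, "", 2L)      # DB Object ID
    qual <- vapply(parts, `[[`, "", 4L)
    gos <- vapply(parts, `[[`, "", 5L)
    evid <- vapply(parts, `[[`, "", 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#",
                            check.names = FALSE)
    genes <- pick_column(df, gene_col, path)
    gos <- pick_column(df, class_col, path)
    evid <- if (is.numeric(evidence_col) || evidence_col %in% names(df))
      pick_column(df, evidence_col, path) else rep(NA_character_, nrow(df))
    keep <- rep(TRUE, nrow(df))
  }
  if (!is.null(evidence_filter))
    keep <- keep & !is.na(evid) & evid %in% evidence_filter
  build_pair_annotations(genes[keep], gos[keep], "GO")
}

#' Read a gene-by-tissue expression table
#'
#' TSV with the gene identifier in the first column and one column per
#' tissue. Non-numeric cells become missing values (later zero-filled by
#' [build_features()]); duplicated gene ids keep the last row with a
#' warning.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "\"")
  if (length(unique(nf)) > 1)
    stop("ragged rows in expression table ", path,
         " (field counts ", paste(unique(nf), collapse = "/"), ")")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    warning("duplicated gene ids in expression table; last row wins")
    keep <- !duplicated(genes, fromLast = TRUE)
    df <- df[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  mat <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(genes, names(df)[-1]))
  mat
}

#' Select predictable phenotype classes
#'
#' Classes annotated to at least `min_genes` genes in a propagated corpus,
#' in lexicographic order. Ontology roots are excluded when `ont` is
#' supplied: the root is annotated to every gene after propagation and
#' carries no signal.
#'
#' @param annots a propagated [annotation_set()].
#' @param ont optional [ontology()] whose roots are excluded.
#' @param min_genes minimum number of annotated genes (default 10).
#' @return Ordered character vector of class ids.
#' @export
select_classes <- function(annots, ont = NULL, min_genes = 10) {
  stopifnot(inherits(annots, "annotation_set"))
  if (!isTRUE(annots$propagated))
    stop("select_classes requires a propagated annotation set")
  counts <- class_counts(annots)
  sel <- names(counts)[counts >= min_genes]
  if (!is.null(ont)) sel <- setdiff(sel, ont$roots)
  sort(sel)
}

#' Build the gene feature matrix
#'
#' Binary GO-annotation features over a fixed vocabulary, optionally
#' concatenated with per-gene z-scored tissue expression. GO classes
#' outside the vocabulary are ignored (unseen classes at prediction time
#' carry no feature). Expression rows are standardised per gene (mean 0,
#' sd 1 over observed tissues), then missing values are set to 0; genes
#' absent from the expression table get an all-zero expression row.
#'
#' @param go_annots a propagated GO [annotation_set()].
#' @param vocab ordered character vector of GO feature classes (fixed from
#'   training data).
#' @param expression optional gene x tissue numeric matrix from
#'   [read_expression()].
#' @return An object of class `"feature_matrix"` with fields `gene_ids`,
#'   `go_vocab`, `go_block`, `expr_block` (or NULL), `n_tissues`.
#' @export
build_features <- function(go_annots, vocab, expression = NULL) {
  stopifnot(inherits(go_annots, "annotation_set"))
  vocab <- as.character(vocab)
  if (length(vocab) == 0) stop("empty GO feature vocabulary")
  if (anyDuplicated(vocab)) stop("duplicate classes in vocabulary")
  genes <- go_annots$gene_ids
  go_block <- matrix(0L, length(genes), length(vocab),
                     dimnames = list(genes, vocab))
  pos <- stats::setNames(seq_along(vocab), vocab)
  for (g in genes) {
    hit <- intersect(go_annots$assignments[[g]], vocab)
    if (length(hit)) go_block[g, pos[hit]] <- 1L
  }
  expr_block <- NULL
  n_tissues <- 0L
  if (!is.null(expression)) {
    n_tissues <- ncol(expression)
    expr_block <- matrix(0, length(genes), n_tissues,
                         dimnames = list(genes, colnames(expression)))
    common <- intersect(genes, rownames(expression))
    for (g in common) {
      row <- expression[g, ]
      obs <- !is.na(row)
      if (sum(obs) >= 2 && stats::sd(row[obs]) > 0)
        row[obs] <- (row[obs] - mean(row[obs])) / stats::sd(row[obs])
      else row[obs] <- 0
      row[!obs] <- 0
      expr_block[g, ] <- row
    }
  }
  structure(list(gene_ids = genes, go_vocab = vocab, go_block = go_block,
                 expr_block = expr_block, n_tissues = n_tissues),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d genes x (%d GO + %d expression) features\n",
              length(x$gene_ids), length(x$go_vocab), x$n_tissues))
  invisible(x)
}

# dense input matrix for the model: [GO block | expression block]
feature_input <- function(fm) {
  if (is.null(fm$expr_block)) fm$go_block * 1.0
  else cbind(fm$go_block * 1.0, fm$expr_block)
}

#' Gene-level train/validation/test splits
#'
#' Splits genes (never individual annotations) so that each gene falls in
#' exactly one partition. With `folds > 1` the test sets form a k-fold
#' partition of the genes (each fold holds 1/folds of them, so five folds
#' reproduce an 80/20 split); with `folds = 1`, `test_fraction` sets the
#' test size. A `valid_fraction_of_train` share of the non-test genes is
#' held out for validation. Deterministic under a fixed seed.
#'
#' @param gene_ids character vector of genes.
#' @param test_fraction test share for the single-split case (default 0.2).
#' @param valid_fraction_of_train validation share of the training pool
#'   (default 0.1).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed.
#' @return An object of class `"split_spec"`: `fold_count`, `seed`, and
#'   `folds`, a list of lists with `train`, `valid`, `test` gene vectors.
#' @export
split_by_gene <- function(gene_ids, test_fraction = 0.2,
                          valid_fraction_of_train = 0.1, folds = 5,
                          seed = 1) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < folds) stop("fewer genes than folds")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (valid_fraction_of_train <= 0 || valid_fraction_of_train >= 1)
    stop("valid_fraction_of_train must lie in (0, 1)")
  shuffled <- with_seed(seed, sample(gene_ids))
  n <- length(shuffled)
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- if (folds > 1) shuffled[((seq_len(n) - 1) %% folds) + 1 == f]
            else shuffled[seq_len(round(n * test_fraction))]
    pool <- setdiff(shuffled, test)
    n_valid <- max(1L, round(length(pool) * valid_fraction_of_train))
    valid <- with_seed(seed + f, sample(pool, n_valid))
    train <- setdiff(pool, valid)
    out[[f]] <- list(train = train, valid = valid, test = test)
  }
  structure(list(fold_count = folds, folds = out, seed = seed),
            class = "split_spec")
}

#' Restrict an annotation set to a subset of genes
#'
#' @param annots an [annotation_set()].
#' @param genes gene ids to keep (order preserved).
#' @return An [annotation_set()] over `genes`.
#' @export
subset_genes <- function(annots, genes) {
  genes <- intersect(genes, annots$gene_ids)
  annotation_set(genes, annots$assignments[genes],
                 propagated = annots$propagated,
                 ontology_id = annots$ontology_id)
}

#' Write an annotation set as a two-column TSV
#'
#' One row per (gene, class) pair, readable back with
#' [read_gene_phenotypes()] / [read_go_annotations()].
#'
#' @param annots an [annotation_set()].
#' @param path output path.
#' @param gene_col,class_col header names.
#' @export
write_annotations <- function(annots, path, gene_col = "gene_id",
                              class_col = "hpo_id") {
  rows <- do.call(rbind, lapply(annots$gene_ids, function(g) {
    cs <- annots$assignments[[g]]
    if (length(cs) == 0) return(NULL)
    data.frame(a = g, b = cs)
  }))
  if (is.null(rows)) rows <- data.frame(a = character(), b = character())
  names(rows) <- c(gene_col, class_col)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param mat gene x tissue matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
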