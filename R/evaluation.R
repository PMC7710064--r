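# Align truth and predictions on a shared gene list and class universe.
# The class universe is the union of all (propagated) truth classes and the
# prediction class order, minus ontology roots when an ontology is given:
# truth classes outside the predictable set count as false negatives, and
# predicted classes nobody is annotated with count as false positives.
eval_frame <- function(truth, preds, ont = NULL, exclude_roots = TRUE,
                       drop_empty = TRUE) {
  stopifnot(inherits(truth, "annotation_set"),
            inherits(preds, "prediction_matrix"))
  if (!setequal(truth$gene_ids, preds$gene_ids))
    stop("truth and prediction gene lists differ (",
         length(setdiff(truth$gene_ids, preds$gene_ids)), " truth-only, ",
         length(setdiff(preds$gene_ids, truth$gene_ids)), " prediction-only)")
  genes <- preds$gene_ids
  classes <- sort(union(names(class_counts(truth)), preds$class_order))
  if (!is.null(ont) && exclude_roots) classes <- setdiff(classes, ont$roots)
  k <- length(classes)
  Tm <- matrix(FALSE, length(genes), k, dimnames = list(genes, classes))
  pos <- stats::setNames(seq_len(k), classes)
  for (g in genes) {
    cs <- intersect(truth$assignments[[g]] %||% character(), classes)
    if (length(cs)) Tm[g, pos[cs]] <- TRUE
  }
  Sc <- matrix(0, length(genes), k, dimnames = list(genes, classes))
  common <- intersect(classes, preds$class_order)
  Sc[, common] <- preds$scores[genes, common]
  has_truth <- rowSums(Tm) > 0
  if (drop_empty && !all(has_truth)) {
    # genes with nothing to recover make per-gene recall undefined; they
    # stay in the term-centric metrics as negatives
    Tm <- Tm[has_truth, , drop = FALSE]
    Sc <- Sc[has_truth, , drop = FALSE]
  }
  if (drop_empty && nrow(Tm) == 0)
    stop("no gene has a non-empty truth set")
  list(truth = Tm, scores = Sc, genes = rownames(Tm), classes = classes)
}

# per-threshold averaged precision/recall curve over t = 0, step, ..., 1;
# membership in a prediction set requires score strictly greater than t
pr_curve <- function(Tm, Sc, step = 0.01) {
  ts <- seq(0, 1, by = step)
  n <- nrow(Tm)
  true_i <- rowSums(Tm)
  out <- data.frame(t = ts, avg_pr = NA_real_, avg_rc = NA_real_,
                    m = NA_integer_)
  for (j in seq_along(ts)) {
    Pm <- Sc > ts[j]
    tp <- rowSums(Pm & Tm)
    npred <- rowSums(Pm)
    m <- sum(npred > 0)
    avg_pr <- if (m == 0) 0 else sum((tp / npred)[npred > 0]) / m
    avg_rc <- sum(tp / true_i) / n
    out$avg_pr[j] <- avg_pr; out$avg_rc[j] <- avg_rc; out$m[j] <- m
  }
  out
}

#' Protein-centric Fmax
#'
#' Scans score thresholds t = 0, 0.01, ..., 1. At each threshold a class is
#' predicted for a gene when its score is strictly greater than t.
#' Precision is averaged over the m(t) genes with at least one prediction;
#' recall over all n genes. Fmax is the maximum harmonic mean across
#' thresholds (0 for an all-zero predictor, whose m(t) is 0 everywhere).
#' Ontology roots are excluded from the class universe when `ont` is given.
#'
#' @param truth propagated phenotype [annotation_set()] for the evaluated
#'   genes.
#' @param preds a [prediction_matrix()] over the same genes.
#' @param ont optional [ontology()] (root exclusion).
#' @param threshold_step threshold grid step (default 0.01).
#' @return List with `fmax`, `threshold`, `precision`, `recall` (at the
#'   maximising threshold) and the full `curve` data.frame.
#' @export
fmax_score <- function(truth, preds, ont = NULL, threshold_step = 0.01) {
  fr <- eval_frame(truth, preds, ont)
  curve <- pr_curve(fr$truth, fr$scores, threshold_step)
  f <- with(curve, ifelse(m > 0 & (avg_pr + avg_rc) > 0,
                          2 * avg_pr * avg_rc / (avg_pr + avg_rc), 0))
  if (all(f == 0)) {
    list(fmax = 0, threshold = NA_real_, precision = 0, recall = 0,
         curve = curve)
  } else {
    i <- which.max(f)
    list(fmax = f[i], threshold = curve$t[i], precision = curve$avg_pr[i],
         recall = curve$avg_rc[i], curve = curve)
  }
}

#' Semantic distance Smin
#'
#' For each threshold, remaining uncertainty ru(t) is the mean (over all
#' genes) summed information content of true classes missed by the
#' prediction set, and misinformation mi(t) the mean summed IC of wrongly
#' predicted classes; Smin is the minimum Euclidean combination
#' sqrt(ru^2 + mi^2). Uses the parent-conditional IC.
#'
#' @param truth,preds,ont,threshold_step as in [fmax_score()].
#' @param ic a conditional-mode `"ic_table"` covering the evaluated
#'   classes (an error lists any missing ones).
#' @return List with `smin`, `threshold` and a per-threshold `curve`
#'   (`t`, `ru`, `mi`).
#' @export
smin_score <- function(truth, preds, ic, ont = NULL, threshold_step = 0.01) {
  stopifnot(inherits(ic, "ic_table"))
  fr <- eval_frame(truth, preds, ont)
  truth_classes <- fr$classes[colSums(fr$truth) > 0]
  missing <- setdiff(truth_classes, names(ic$values))
  if (length(missing) > 0)
    stop("no information content for evaluated class(es): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ..." else "")
  icv <- ic_value(ic, fr$classes)
  ts <- seq(0, 1, by = threshold_step)
  n <- nrow(fr$truth)
  ru <- mi <- numeric(length(ts))
  for (j in seq_along(ts)) {
    Pm <- fr$scores > ts[j]
    ru[j] <- sum((fr$truth & !Pm) %*% icv) / n
    mi[j] <- sum((Pm & !fr$truth) %*% icv) / n
  }
  s <- sqrt(ru^2 + mi^2)
  i <- which.min(s)
  list(smin = s[i], threshold = ts[i],
       curve = data.frame(t = ts, ru = ru, mi = mi))
}

#' Area under the averaged precision-recall curve
#'
#' Trapezoidal area under the (recall, precision) points of the same
#' 101-threshold averaged curve used for Fmax, sorted by recall;
#' thresholds where no gene has a prediction are dropped, and the curve is
#' anchored at recall 0 with the precision of its lowest-recall point. A
#' micro-averaged variant (pooling all gene-class pairs) is available.
#'
#' @param truth,preds,ont,threshold_step as in [fmax_score()].
#' @param micro use micro-averaged precision/recall instead of the
#'   averaged curve.
#' @return Scalar area in \[0,1\].
#' @export
aupr_score <- function(truth, preds, ont = NULL, threshold_step = 0.01,
                       micro = FALSE) {
  fr <- eval_frame(truth, preds, ont)
  ts <- seq(0, 1, by = threshold_step)
  if (micro) {
    total_true <- sum(fr$truth)
    pts <- do.call(rbind, lapply(ts, function(t) {
      Pm <- fr$scores > t
      npred <- sum(Pm)
      if (npred == 0) return(NULL)
      tp <- sum(Pm & fr$truth)
      data.frame(rc = tp / total_true, pr = tp / npred)
    }))
  } else {
    curve <- pr_curve(fr$truth, fr$scores, threshold_step)
    curve <- curve[curve$m > 0, ]
    pts <- data.frame(rc = curve$avg_rc, pr = curve$avg_pr)
  }
  if (is.null(pts) || nrow(pts) == 0) return(0)
  pts <- pts[order(pts$rc, pts$pr), ]
  pts <- rbind(data.frame(rc = 0, pr = pts$pr[1]), pts)
  sum(diff(pts$rc) * (utils::head(pts$pr, -1) + utils::tail(pts$pr, -1)) / 2)
}

#' Term-centric mean AUROC
#'
#' For every class with at least one positive and one negative gene, the
#' AUROC is computed from the rank statistic with mid-rank tie handling
#' (tied gene scores contribute 0.5); classes failing the evaluability
#' condition are skipped and the unweighted mean over evaluable classes is
#' returned. A predictor giving every gene the same score yields exactly
#' 0.5 per class.
#'
#' @param truth,preds,ont as in [fmax_score()].
#' @return List with `mean_auroc`, and `per_class` named vector.
#' @export
term_auroc <- function(truth, preds, ont = NULL) {
  fr <- eval_frame(truth, preds, ont, drop_empty = FALSE)
  n <- nrow(fr$truth)
  aucs <- rep(NA_real_, ncol(fr$truth))
  names(aucs) <- fr$classes
  for (j in seq_len(ncol(fr$truth))) {
    y <- fr$truth[, j]
    np <- sum(y); nn <- n - np
    if (np == 0 || nn == 0) next
    r <- rank(fr$scores[, j], ties.method = "average")
    aucs[j] <- (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
  }
  keep <- !is.na(aucs)
  if (!any(keep)) stop("no class with both positive and negative genes")
  list(mean_auroc = mean(aucs[keep]), per_class = aucs[keep])
}

#' Full CAFA-style evaluation report
#'
#' Convenience wrapper computing Fmax (with precision/recall at the
#' maximising threshold), Smin (when an IC table is given), AUPR and
#' term-centric AUROC in one pass.
#'
#' @param truth,preds,ont,threshold_step as in [fmax_score()].
#' @param ic optional conditional `"ic_table"` for Smin.
#' @return An object of class `"eval_report"`.
#' @export
evaluate_predictions <- function(truth, preds, ont = NULL, ic = NULL,
                                 threshold_step = 0.01) {
  fm <- fmax_score(truth, preds, ont, threshold_step)
  sm <- if (!is.null(ic)) smin_score(truth, preds, ic, ont, threshold_step)
  au <- aupr_score(truth, preds, ont, threshold_step)
  ta <- term_auroc(truth, preds, ont)
  structure(list(fmax = fm$fmax, fmax_threshold = fm$threshold,
                 precision_at_fmax = fm$precision,
                 recall_at_fmax = fm$recall,
                 smin = if (is.null(sm)) NA_real_ else sm$smin,
                 aupr = au, term_auroc = ta$mean_auroc,
                 curve = fm$curve,
                 smin_curve = if (is.null(sm)) NULL else sm$curve),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Fmax %.3f (t=%.2f, pr %.3f, rc %.3f)  Smin %s  AUPR %.3f  AUROC %.3f\n",
              x$fmax, x$fmax_threshold, x$precision_at_fmax, x$recall_at_fmax,
              if (is.na(x$smin)) "NA" else sprintf("%.3f", x$smin),
              x$aupr, x$term_auroc))
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional TSV curve)
#'
#' @param report an `"eval_report"`.
#' @param path JSON output path.
#' @param curve_path optional TSV path for the threshold curve.
#' @export
write_report <- function(report, path, curve_path = NULL) {
  x <- unclass(report)
  curve <- x$curve; x$curve <- NULL; x$smin_curve <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(curve_path))
    utils::write.table(curve, curve_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Three-column TSV (gene_a, gene_b, score). Scores on STRING's 0-999
#' scale are auto-detected (maximum > 1) and rescaled to 0-1 before the
#' cutoff is applied.
#'
#' @param path TSV path.
#' @param score_cutoff minimum combined score on a 0-1 scale (default
#'   0.7, the usual high-confidence filter).
#' @return De-duplicated undirected edge data.frame (gene_a, gene_b).
#' @export
read_interactions <- function(path, score_cutoff = 0.7) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  if (ncol(df) >= 3) {
    sc <- as.numeric(df[[3]])
    if (max(sc, na.rm = TRUE) > 1) sc <- sc / 1000
    df <- df[!is.na(sc) & sc >= score_cutoff, 1:2]
  } else df <- df[, 1:2]
  dedupe_edges(df)
}

dedupe_edges <- function(df) {
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  keep <- !duplicated(paste(a, b)) & a != b
  data.frame(gene_a = a[keep], gene_b = b[keep])
}

#' Permutation test for interaction-network overlap of predictions
#'
#' For each phenotype, the false-positive predicted genes (predicted but
#' not known) are checked for adjacency to at least one known
#' phenotype-associated gene in the interaction network; the statistic is
#' the mean, over phenotypes with at least one false positive, of that
#' adjacent fraction. The null replaces each phenotype's predicted set by
#' a uniform random gene set of the same size, repeated `n_perm` times;
#' the p-value uses the add-one (permutation-inclusive) rule
#' (1 + #\{null >= observed\}) / (1 + n_perm), so it is never exactly 0.
#'
#' @param pred_sets named list: phenotype -> predicted gene ids.
#' @param known_sets named list: phenotype -> known associated gene ids.
#' @param edges undirected edge data.frame (gene_a, gene_b), e.g. from
#'   [read_interactions()] or [gen_interaction_graph()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param gene_universe genes to sample random sets from; defaults to the
#'   union of edge endpoints and all set members.
#' @return An object of class `"overlap_test"`: `observed_mean_overlap`,
#'   `null_mean`, `p_value`, `n_permutations`.
#' @export
ppi_overlap_test <- function(pred_sets, known_sets, edges, n_perm = 1000,
                             seed = 1, gene_universe = NULL) {
  phenos <- intersect(names(pred_sets), names(known_sets))
  if (length(phenos) == 0 ||
      all(vapply(known_sets[phenos], length, 1L) == 0))
    stop("no phenotype has a non-empty known gene set")
  if (ncol(edges) >= 2) edges <- dedupe_edges(
    data.frame(gene_a = as.character(edges[[1]]),
               gene_b = as.character(edges[[2]])))
  nb <- split(c(edges$gene_b, edges$gene_a), c(edges$gene_a, edges$gene_b))
  if (is.null(gene_universe))
    gene_universe <- unique(c(edges$gene_a, edges$gene_b,
                              unlist(pred_sets[phenos], use.names = FALSE),
                              unlist(known_sets[phenos], use.names = FALSE)))
  stat <- function(sets) {
    fr <- vapply(phenos, function(ph) {
      fp <- setdiff(sets[[ph]], known_sets[[ph]])
      if (length(fp) == 0) return(NA_real_)
      known <- known_sets[[ph]]
      mean(vapply(fp, function(g) any(nb[[g]] %in% known), TRUE))
    }, 1)
    if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
  }
  observed <- stat(pred_sets)
  if (is.na(observed))
    stop("every phenotype's predicted set is a subset of its known set; ",
         "no false positives to evaluate")
  sizes <- vapply(pred_sets[phenos], length, 1L)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    rand <- lapply(sizes, function(s)
      sample(gene_universe, min(s, length(gene_universe))))
    names(rand) <- phenos
    stat(rand)
  }, 1))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  structure(list(observed_mean_overlap = observed,
                 null_mean = if (length(null)) mean(null) else NA_real_,
                 p_value = p, n_permutations = length(null)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Network overlap: observed %.3f vs null mean %.3f (p = %.4g, %d permutations)\n",
              x$observed_mean_overlap, x$null_mean, x$p_value,
              x$n_permutations))
  invisible(x)
}
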