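# Independent oracles coded against definitions, not against the package
# implementation: naive reachability by repeated edge relaxation, exhaustive
# threshold enumeration for the protein-centric metrics, pairwise-comparison
# AUROC, and brute-force common-ancestor similarity.

# reflexive transitive closure by repeated relaxation over an edge list
oracle_reachable <- function(edges, from, direction = "ancestors") {
  set <- from
  repeat {
    if (direction == "ancestors")
      new <- edges$parent[edges$child %in% set]
    else
      new <- edges$child[edges$parent %in% set]
    grown <- union(set, new)
    if (setequal(grown, set)) return(sort(set))
    set <- grown
  }
}

# edge list of an ontology object (child, parent) for oracle use
edges_of <- function(ont) {
  do.call(rbind, lapply(ont$classes, function(c) {
    ps <- ont$parents[[c]]
    if (length(ps) == 0) return(NULL)
    data.frame(child = c, parent = ps)
  })) %||% data.frame(child = character(), parent = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive 101-threshold protein-centric evaluation on plain sets.
# truth_sets: named list gene -> class set; scores: named list gene ->
# named numeric vector; classes: the evaluation class universe.
oracle_curve <- function(truth_sets, scores, classes, step = 0.01) {
  genes <- names(truth_sets)
  ts <- seq(0, 1, by = step)
  res <- data.frame(t = ts, avg_pr = 0, avg_rc = 0, m = 0L)
  for (row in seq_along(ts)) {
    t <- ts[row]
    prs <- c(); rcs <- c()
    for (g in genes) {
      sc <- scores[[g]]
      pred <- intersect(names(sc)[sc > t], classes)
      truth <- intersect(truth_sets[[g]], classes)
      tp <- length(intersect(pred, truth))
      if (length(pred) > 0) prs <- c(prs, tp / length(pred))
      rcs <- c(rcs, tp / length(truth))
    }
    res$m[row] <- length(prs)
    res$avg_pr[row] <- if (length(prs) > 0) mean(prs) else 0
    res$avg_rc[row] <- mean(rcs)
  }
  res
}

oracle_fmax <- function(truth_sets, scores, classes, step = 0.01) {
  cv <- oracle_curve(truth_sets, scores, classes, step)
  f <- ifelse(cv$m > 0 & cv$avg_pr + cv$avg_rc > 0,
              2 * cv$avg_pr * cv$avg_rc / (cv$avg_pr + cv$avg_rc), 0)
  max(f)
}

oracle_smin <- function(truth_sets, scores, classes, ic_values, step = 0.01) {
  genes <- names(truth_sets)
  ts <- seq(0, 1, by = step)
  best <- Inf
  for (t in ts) {
    ru <- 0; mi <- 0
    for (g in genes) {
      sc <- scores[[g]]
      pred <- intersect(names(sc)[sc > t], classes)
      truth <- intersect(truth_sets[[g]], classes)
      ru <- ru + sum(ic_values[setdiff(truth, pred)])
      mi <- mi + sum(ic_values[setdiff(pred, truth)])
    }
    ru <- ru / length(genes); mi <- mi / length(genes)
    best <- min(best, sqrt(ru^2 + mi^2))
  }
  best
}

oracle_aupr <- function(truth_sets, scores, classes, step = 0.01) {
  cv <- oracle_curve(truth_sets, scores, classes, step)
  cv <- cv[cv$m > 0, ]
  if (nrow(cv) == 0) return(0)
  pts <- cv[order(cv$avg_rc, cv$avg_pr), c("avg_rc", "avg_pr")]
  pts <- rbind(data.frame(avg_rc = 0, avg_pr = pts$avg_pr[1]), pts)
  sum(diff(pts$avg_rc) *
        (head(pts$avg_pr, -1) + tail(pts$avg_pr, -1)) / 2)
}

# pairwise-comparison (Mann-Whitney) AUROC with ties counting 0.5
oracle_auroc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force Resnik: max IC over the intersection of relaxation closures
oracle_resnik <- function(ont, c1, c2, ic_values) {
  e <- edges_of(ont)
  common <- intersect(oracle_reachable(e, c1), oracle_reachable(e, c2))
  if (length(common) == 0) return(0)
  max(ic_values[common])
}

# descendant-max oracle for the hierarchical layer
oracle_hier <- function(ont, class_order, x) {
  e <- edges_of(ont)
  sapply(class_order, function(c) {
    desc <- intersect(oracle_reachable(e, c, "descendants"), class_order)
    max(x[desc])
  })
}
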