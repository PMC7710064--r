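#' Construct an ontology from classes and is_a edges
#'
#' An ontology here is a directed acyclic graph of classes connected by
#' `is_a` (subclass) edges, as in the Gene Ontology or the Human Phenotype
#' Ontology. Only `is_a` edges define the hierarchy; other relation types
#' (e.g. `part_of`) are outside the model.
#'
#' @param classes character vector of class identifiers (e.g. "HP:0000118").
#' @param edges two-column data.frame (or matrix) of child/parent pairs;
#'   both endpoints must be members of `classes`.
#' @param alt_map named character vector mapping alternative ids to primary
#'   ids (may be empty).
#'
#' @return An object of class `"ontology"` with elements `classes`,
#'   `parents` (named list child -> parents), `children`, `roots`,
#'   `alt_map` and `topo` (a topological order from roots to leaves).
#' @export
ontology <- function(classes, edges = NULL, alt_map = character()) {
  classes <- unique(as.character(classes))
  if (anyNA(classes) || any(classes == ""))
    stop("class identifiers must be non-empty strings")
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character())
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
  }
  bad <- setdiff(unique(c(edges$child, edges$parent)), classes)
  if (length(bad) > 0)
    stop("edge endpoints not declared as classes: ", paste(bad, collapse = ", "))
  edges <- unique(edges[, c("child", "parent")])
  parents <- split(edges$parent, factor(edges$child, levels = classes))
  children <- split(edges$child, factor(edges$parent, levels = classes))
  names(parents) <- classes
  names(children) <- classes

  topo <- topo_sort(classes, parents)   # errors on cycles
  roots <- classes[vapply(parents, length, 1L) == 0L]

  structure(
    list(classes = classes, parents = parents, children = children,
         roots = roots, alt_map = alt_map, topo = topo),
    class = "ontology")
}

# Kahn's algorithm; parents[[c]] are prerequisites so the returned order
# goes from roots to leaves. Fails if the edge set has a directed cycle.
topo_sort <- function(classes, parents) {
  n <- length(classes)
  idx <- stats::setNames(seq_len(n), classes)
  indeg <- vapply(parents, length, 1L)
  kids <- vector("list", n)
  for (c in classes) {
    for (p in parents[[c]]) kids[[idx[[p]]]] <- c(kids[[idx[[p]]]], c)
  }
  queue <- classes[indeg == 0L]
  out <- character(n); k <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    k <- k + 1L; out[k] <- v
    for (w in kids[[idx[[v]]]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) stop("cycle detected in is_a graph; an ontology must be acyclic")
  out
}

#' @export
print.ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat(sprintf("Ontology: %d classes, %d is_a edges, %d root(s)\n",
              length(x$classes), n_edges, length(x$roots)))
  invisible(x)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 file. Obsolete terms are
#' dropped (their `replaced_by` target, followed once, and their id are
#' recorded in the alt map); `alt_id` values map to their primary id.
#' Only `is_a` lines define edges; `relationship: part_of` lines are
#' ignored with a warning.
#'
#' @param path path to an OBO text file.
#' @return An [ontology()] object.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  saw_part_of <- FALSE
  start_line <- 0L

  flush_term <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$id))
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   cur$start))
    cur
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "[Term]") {
      t <- flush_term(cur)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- list(start = i, is_a = character(), alt_id = character(),
                  obsolete = FALSE, replaced_by = NULL)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {            # [Typedef] etc.
      t <- flush_term(cur)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || ln == "" || startsWith(ln, "!")) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed line %d in OBO file: %s", i, ln))
    key <- m[[2]]; val <- sub("\\s*!.*$", "", m[[3]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "replaced_by" && is.null(cur$replaced_by)) cur$replaced_by <- val
    else if (key == "relationship" && grepl("^part_of\\b", val)) saw_part_of <- TRUE
  }
  t <- flush_term(cur)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  if (saw_part_of)
    warning("part_of relationships present in OBO file are ignored; ",
            "only is_a edges define the hierarchy")

  keep <- terms[!vapply(terms, `[[`, TRUE, "obsolete")]
  classes <- vapply(keep, `[[`, "", "id")
  alt_map <- character()
  for (t in keep) {
    if (length(t$alt_id) > 0)
      alt_map[t$alt_id] <- t$id
  }
  for (t in terms) {
    if (t$obsolete && !is.null(t$replaced_by))
      alt_map[t$id] <- t$replaced_by
  }
  edges <- do.call(rbind, lapply(keep, function(t) {
    if (length(t$is_a) == 0) return(NULL)
    data.frame(child = t$id, parent = t$is_a)
  }))
  if (!is.null(edges)) {
    # drop edges pointing at obsolete parents after following replaced_by
    edges$parent <- ifelse(edges$parent %in% names(alt_map) &
                             !(edges$parent %in% classes),
                           alt_map[edges$parent], edges$parent)
    edges <- edges[edges$parent %in% classes & edges$child %in% classes, ]
  }
  ontology(classes, edges, alt_map)
}

#' Reflexive transitive closure of a class along is_a edges
#'
#' @param ont an [ontology()].
#' @param class a class identifier in `ont`.
#' @param direction `"ancestors"` (towards roots) or `"descendants"`.
#' @return Character vector of class ids; always contains `class` itself.
#' @export
closure <- function(ont, class, direction = c("ancestors", "descendants")) {
  direction <- match.arg(direction)
  if (!(class %in% ont$classes))
    stop("unknown class: ", class)
  step <- if (direction == "ancestors") ont$parents else ont$children
  seen <- stats::setNames(logical(length(ont$classes)), ont$classes)
  queue <- class
  seen[class] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in step[[v]]) {
      if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
    }
  }
  names(seen)[seen]
}

# Ancestor closures for every class at once, walking the topological order
# once (each class = itself plus the union of its parents' closures).
ancestor_sets <- function(ont) {
  anc <- stats::setNames(vector("list", length(ont$classes)), ont$classes)
  for (c in ont$topo) {
    ps <- ont$parents[[c]]
    if (length(ps) == 0) anc[[c]] <- c
    else anc[[c]] <- unique(c(c, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate an annotation set by the true path rule
#'
#' Replaces each gene's class set by the union of the ancestor closures of
#' its classes: an annotation to a class implies annotation to every
#' superclass up to the root. Idempotent. Alternative ids are first mapped
#' to their primary id.
#'
#' @param ont an [ontology()].
#' @param annots an [annotation_set()].
#' @param unknown what to do with annotated classes absent from the
#'   ontology: `"drop"` them with a warning (default) or `"error"`.
#' @return A propagated [annotation_set()].
#' @export
propagate <- function(ont, annots, unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(annots, "annotation_set"))
  anc <- ancestor_sets(ont)
  dropped <- character()
  assignments <- lapply(annots$assignments, function(cs) {
    if (length(names(ont$alt_map)) > 0) {
      hit <- cs %in% names(ont$alt_map)
      cs[hit] <- ont$alt_map[cs[hit]]
    }
    known <- cs %in% ont$classes
    if (any(!known)) {
      if (unknown == "error")
        stop("annotated class not in ontology: ",
             paste(cs[!known], collapse = ", "))
      dropped <<- union(dropped, cs[!known])
      cs <- cs[known]
    }
    unique(unlist(anc[cs], use.names = FALSE))
  })
  if (length(dropped) > 0)
    warning(length(dropped), " annotated class(es) absent from the ontology ",
            "were dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  annotation_set(annots$gene_ids, assignments, propagated = TRUE,
                 ontology_id = annots$ontology_id)
}

#' Reflexive subclass indicator matrix over an ordered class list
#'
#' Entry (i, j) is 1 iff `class_order[j]` is a (reflexive) subclass of
#' `class_order[i]`, restricted to the given classes. This is the binary
#' structure consumed by the hierarchical classification layer.
#'
#' @param ont an [ontology()].
#' @param class_order ordered character vector of classes (no duplicates).
#' @return A k x k binary matrix with `class_order` as both dimnames.
#' @export
subclass_matrix <- function(ont, class_order) {
  if (anyDuplicated(class_order))
    stop("duplicate class ids in class_order")
  missing <- setdiff(class_order, ont$classes)
  if (length(missing) > 0)
    stop("classes not in ontology: ", paste(missing, collapse = ", "))
  k <- length(class_order)
  S <- matrix(0L, k, k, dimnames = list(class_order, class_order))
  anc <- ancestor_sets(ont)
  pos <- stats::setNames(seq_len(k), class_order)
  for (j in seq_len(k)) {
    up <- intersect(anc[[class_order[j]]], class_order)
    S[pos[up], j] <- 1L
  }
  S
}

#' Information content tables
#'
#' `conditional_ic()` computes, for each class c annotated in a propagated
#' corpus, IC(c) = -log Pr(c | parents(c)) where the probability is the
#' number of genes annotated with c divided by the number of genes
#' annotated with *all* parents of c (for roots, the corpus size). This
#' parent-conditional variant feeds the Smin semantic-distance metric.
#'
#' `marginal_ic()` computes IC(c) = -log(n_c / n) from the marginal
#' annotation frequency; this variant feeds Resnik similarity. Classes
#' annotated to every gene (e.g. the root after propagation) get IC 0.
#'
#' Classes with a zero-probability denominator get IC 0 (conditional mode)
#' so downstream sums stay finite; lookups of classes absent from a
#' marginal table return the maximum observed IC (see [ic_value()]).
#'
#' @param annots a propagated [annotation_set()] (the IC corpus).
#' @param ont an [ontology()] (conditional mode only).
#' @param log_base base of the logarithm (default 2).
#' @return An object of class `"ic_table"` with fields `mode`, `values`
#'   (named numeric), `corpus_size`, `log_base`, `max_ic`.
#' @export
conditional_ic <- function(annots, ont, log_base = 2) {
  stopifnot(inherits(annots, "annotation_set"))
  if (!isTRUE(annots$propagated))
    stop("conditional_ic requires a propagated annotation set")
  if (length(annots$gene_ids) == 0) stop("empty annotation corpus")
  sets <- annots$assignments
  n <- length(annots$gene_ids)
  counts <- class_counts(annots)
  vals <- stats::setNames(numeric(length(counts)), names(counts))
  # genes annotated with ALL parents of c: count via per-gene membership
  for (c in names(counts)) {
    if (!(c %in% ont$classes)) { vals[[c]] <- 0; next }
    ps <- ont$parents[[c]]
    denom <- if (length(ps) == 0) n else
      sum(vapply(sets, function(s) all(ps %in% s), TRUE))
    vals[[c]] <- if (denom == 0) 0 else
      -log(counts[[c]] / denom) / log(log_base)
  }
  vals[vals < 0 & vals > -1e-12] <- 0
  new_ic_table("conditional", vals, n, log_base)
}

#' @rdname conditional_ic
#' @export
marginal_ic <- function(annots, log_base = 2) {
  stopifnot(inherits(annots, "annotation_set"))
  if (!isTRUE(annots$propagated))
    stop("marginal_ic requires a propagated annotation set")
  n <- length(annots$gene_ids)
  if (n == 0) stop("empty annotation corpus")
  counts <- class_counts(annots)
  vals <- -log(counts / n) / log(log_base)
  vals[vals < 0 & vals > -1e-12] <- 0
  new_ic_table("marginal", vals, n, log_base)
}

new_ic_table <- function(mode, values, corpus_size, log_base) {
  stopifnot(all(values >= 0))
  structure(list(mode = mode, values = values, corpus_size = corpus_size,
                 log_base = log_base,
                 max_ic = if (length(values)) max(values) else 0),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ICTable (%s, base %g): %d classes over %d genes, max IC %.3f\n",
              x$mode, x$log_base, length(x$values), x$corpus_size, x$max_ic))
  invisible(x)
}

#' Look up information content values
#'
#' Classes absent from the table get the maximum observed IC in marginal
#' mode (an unseen class is at least as specific as anything observed) and
#' 0 in conditional mode.
#'
#' @param ic an `"ic_table"`.
#' @param classes character vector of class ids.
#' @return Named numeric vector of IC values.
#' @export
ic_value <- function(ic, classes) {
  stopifnot(inherits(ic, "ic_table"))
  out <- ic$values[classes]
  miss <- is.na(out)
  out[miss] <- if (ic$mode == "marginal") ic$max_ic else 0
  stats::setNames(as.numeric(out), classes)
}
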