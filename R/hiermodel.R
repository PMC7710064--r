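#' Construct a prediction matrix
#'
#' Genes x phenotype-class scores in \[0,1\]. The `consistent` flag records
#' whether the scores respect the ontology: every ancestor scores at least
#' as high as each of its descendants.
#'
#' @param gene_ids ordered genes.
#' @param class_order ordered phenotype classes.
#' @param scores numeric matrix, genes x classes, values in \[0,1\].
#' @param consistent logical flag.
#' @return An object of class `"prediction_matrix"`.
#' @export
prediction_matrix <- function(gene_ids, class_order, scores,
                              consistent = FALSE) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(gene_ids),
            ncol(scores) == length(class_order))
  if (any(scores < -1e-9 | scores > 1 + 1e-9))
    stop("prediction scores must lie in [0, 1]")
  scores <- pmin(pmax(scores, 0), 1)
  dimnames(scores) <- list(gene_ids, class_order)
  structure(list(gene_ids = as.character(gene_ids),
                 class_order = as.character(class_order),
                 scores = scores, consistent = isTRUE(consistent)),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("PredictionMatrix: %d genes x %d classes%s\n",
              length(x$gene_ids), length(x$class_order),
              if (x$consistent) " (hierarchically consistent)" else ""))
  invisible(x)
}

# descendant index list from a subclass matrix: desc[[i]] = columns j with
# S[i, j] == 1 (always contains i itself)
descendant_index <- function(S) {
  if (nrow(S) != ncol(S)) stop("subclass matrix must be square")
  if (any(diag(S) != 1)) stop("subclass matrix diagonal must be all ones")
  lapply(seq_len(nrow(S)), function(i) which(S[i, ] == 1))
}

# forward pass of the hierarchical max layer on a score matrix;
# returns the pooled scores and, per output entry, the input column that
# achieved the max (used to route gradients during training)
hier_forward <- function(P, desc) {
  n <- nrow(P); k <- length(desc)
  out <- matrix(0, n, k, dimnames = dimnames(P))
  amax <- matrix(0L, n, k)
  for (i in seq_len(k)) {
    cols <- desc[[i]]
    sub <- P[, cols, drop = FALSE]
    w <- max.col(sub, ties.method = "first")
    out[, i] <- sub[cbind(seq_len(n), w)]
    amax[, i] <- cols[w]
  }
  list(out = out, amax = amax)
}

#' Hierarchical classification layer
#'
#' Replaces each class score by the maximum score among the class's
#' reflexive descendants, as encoded in a [subclass_matrix()]. The output
#' is ontology-consistent by construction: an ancestor can never score
#' below a descendant. The operator is idempotent, monotone, and never
#' decreases any score; it is the same max-reduction used inside the
#' neural model during training.
#'
#' @param x numeric score vector over the classes of `S`, or a genes x
#'   classes matrix.
#' @param S a [subclass_matrix()] over the same class order.
#' @return Object of the same shape as `x`.
#' @export
hierarchical_layer <- function(x, S) {
  vec <- is.null(dim(x))
  P <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(P) != nrow(S))
    stop(sprintf("score vector length %d does not match subclass matrix size %d",
                 ncol(P), nrow(S)))
  out <- hier_forward(P, descendant_index(S))$out
  if (vec) stats::setNames(as.numeric(out), colnames(S)) else out
}

#' Post-hoc true-path-rule fixing of predictions
#'
#' Makes a prediction matrix hierarchically consistent by setting each
#' class's score to the maximum over its reflexive descendants within the
#' prediction's class order — the score-level generalisation of adding all
#' superclasses of a positive prediction up to the root. Equal to applying
#' [hierarchical_layer()] after the fact; idempotent.
#'
#' @param preds a [prediction_matrix()].
#' @param ont the phenotype [ontology()].
#' @return A consistent [prediction_matrix()].
#' @export
true_path_fix <- function(preds, ont) {
  stopifnot(inherits(preds, "prediction_matrix"))
  S <- subclass_matrix(ont, preds$class_order)
  fixed <- hierarchical_layer(preds$scores, S)
  prediction_matrix(preds$gene_ids, preds$class_order, fixed,
                    consistent = TRUE)
}

#' Check hierarchical consistency of predictions
#'
#' @param preds a [prediction_matrix()].
#' @param S a [subclass_matrix()] over `preds$class_order`.
#' @param tol numeric tolerance.
#' @return TRUE iff no descendant outscores an ancestor anywhere.
#' @export
is_consistent <- function(preds, S, tol = 1e-9) {
  fixed <- hierarchical_layer(preds$scores, S)
  all(fixed - preds$scores <= tol)
}

#' Model hyperparameter configuration
#'
#' Defaults follow a desk-scale configuration inside the search grid used
#' for tuning: one reduction layer of 1024 units, dropout 0.5 after it,
#' Adam with learning rate 0.001, mini-batches of 32, early stopping on
#' validation loss with patience 5.
#'
#' @param hidden_layers integer vector of reduction-layer unit counts.
#' @param dropout_rate dropout probability after the last reduction layer.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch budget.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialisation, batch order,
#'   dropout and the validation split.
#' @param search_trials number of random-search trials ([random_search()]).
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(hidden_layers = 1024, dropout_rate = 0.5,
                         learning_rate = 0.001, batch_size = 32,
                         max_epochs = 100, patience = 5, seed = 1,
                         search_trials = 0) {
  stopifnot(all(hidden_layers >= 1), dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 search_trials = as.integer(search_trials)),
            class = "model_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# binary cross-entropy, mean over all entries; scores clamped away from 0/1
bce_loss <- function(O, Y, eps = 1e-7) {
  O <- pmin(pmax(O, eps), 1 - eps)
  -mean(Y * log(O) + (1 - Y) * log(1 - O))
}

#' Train the phenotype prediction network
#'
#' A fully connected network: one or more reduction layers (ReLU) over the
#' sparse binary GO block, dropout after the last reduction layer, the
#' normalised expression block concatenated to the reduced representation,
#' and a sigmoid multi-label output with one unit per phenotype class. In
#' `"hierarchical"` mode the hierarchical classification layer (descendant
#' max-pooling through the subclass matrix) is applied on top of the
#' sigmoid output both during training — the loss is computed on the
#' pooled scores, with gradients routed through the max — and during
#' prediction, so outputs are ontology-consistent by construction. In
#' `"flat"` mode the layer is omitted and predictions can be repaired
#' afterwards with [true_path_fix()].
#'
#' Training minimises binary cross-entropy with Adam, mini-batches, and
#' early stopping on validation loss (best weights restored).
#'
#' @param features a [build_features()] matrix for the training genes.
#' @param labels propagated phenotype [annotation_set()] for the same
#'   genes (classes outside the subclass matrix's order are ignored).
#' @param S [subclass_matrix()] over the predictable classes.
#' @param config a [model_config()].
#' @param mode `"hierarchical"` (default) or `"flat"`.
#' @param valid_genes optional validation gene ids; by default 10% of the
#'   genes are held out (seeded).
#' @param verbose print per-epoch losses.
#' @return An object of class `"pheno_model"`.
#' @export
train_model <- function(features, labels, S, config = model_config(),
                        mode = c("hierarchical", "flat"),
                        valid_genes = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "feature_matrix"),
            inherits(labels, "annotation_set"),
            inherits(config, "model_config"))
  class_order <- rownames(S)
  genes <- features$gene_ids
  Y <- matrix(0, length(genes), length(class_order),
              dimnames = list(genes, class_order))
  pos <- stats::setNames(seq_along(class_order), class_order)
  for (g in intersect(genes, labels$gene_ids)) {
    cs <- intersect(labels$assignments[[g]], class_order)
    if (length(cs)) Y[g, pos[cs]] <- 1
  }
  if (all(colSums(Y) == 0))
    stop("no positive labels for any class; cannot train")

  X1 <- features$go_block * 1.0
  X2 <- features$expr_block              # may be NULL
  d1 <- ncol(X1); d2 <- if (is.null(X2)) 0L else ncol(X2)
  k <- length(class_order)
  desc <- if (mode == "hierarchical") descendant_index(S) else NULL

  if (is.null(valid_genes)) {
    n_valid <- max(1L, round(0.1 * length(genes)))
    valid_genes <- with_seed(config$seed, sample(genes, n_valid))
  }
  vi <- match(valid_genes, genes)
  ti <- setdiff(seq_along(genes), vi)
  if (length(ti) == 0) stop("no training genes left after validation split")

  params <- with_seed(config$seed, init_params(d1, d2, config$hidden_layers, k))
  opt <- adam_state(params, config$learning_rate)

  forward <- function(idx, masks = NULL) {
    A <- X1[idx, , drop = FALSE]
    acts <- list()
    for (l in seq_along(params$W)) {
      Zl <- sweep(A %*% params$W[[l]], 2, params$b[[l]], `+`)
      Al <- pmax(Zl, 0)
      acts[[l]] <- list(input = A, pre = Zl, post = Al)
      A <- Al
    }
    if (!is.null(masks)) A <- A * masks
    Zcat <- if (d2 > 0) cbind(A, X2[idx, , drop = FALSE]) else A
    logits <- sweep(Zcat %*% params$Wout, 2, params$bout, `+`)
    P <- sigmoid(logits)
    hier <- if (mode == "hierarchical") hier_forward(P, desc) else NULL
    O <- if (is.null(hier)) P else hier$out
    list(acts = acts, H = A, Zcat = Zcat, P = P, hier = hier, out = O)
  }

  eval_loss <- function(idx) bce_loss(forward(idx)$out, Y[idx, , drop = FALSE])

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_loss = numeric())
  n_train <- length(ti)
  eps <- 1e-7

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(ti)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        nb <- length(b)
        masks <- if (config$dropout_rate > 0)
          matrix(stats::rbinom(nb * utils::tail(config$hidden_layers, 1), 1,
                               1 - config$dropout_rate) /
                   (1 - config$dropout_rate),
                 nb, utils::tail(config$hidden_layers, 1))
        else NULL
        fw <- forward(b, masks)
        Yb <- Y[b, , drop = FALSE]
        loss <- bce_loss(fw$out, Yb)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate", epoch))
        ep_loss <- ep_loss + loss * nb

        # gradient of mean BCE wrt the (possibly pooled) output scores
        Ocl <- pmin(pmax(fw$out, eps), 1 - eps)
        dO <- (Ocl - Yb) / (Ocl * (1 - Ocl)) / (nb * k)
        if (mode == "hierarchical") {
          dP <- matrix(0, nb, k)
          am <- fw$hier$amax
          for (i in seq_len(k)) {
            tgt <- cbind(seq_len(nb), am[, i])
            dP[tgt] <- dP[tgt] + dO[, i]
          }
        } else dP <- dO
        dlogits <- dP * fw$P * (1 - fw$P)

        grads <- list()
        grads$Wout <- crossprod(fw$Zcat, dlogits)
        grads$bout <- colSums(dlogits)
        dZcat <- tcrossprod(dlogits, params$Wout)
        h_last <- utils::tail(config$hidden_layers, 1)
        dH <- dZcat[, seq_len(h_last), drop = FALSE]
        if (!is.null(masks)) dH <- dH * masks
        grads$W <- vector("list", length(params$W))
        grads$b <- vector("list", length(params$b))
        for (l in rev(seq_along(params$W))) {
          dH <- dH * (fw$acts[[l]]$pre > 0)
          grads$W[[l]] <- crossprod(fw$acts[[l]]$input, dH)
          grads$b[[l]] <- colSums(dH)
          if (l > 1) dH <- tcrossprod(dH, params$W[[l]])
        }
        upd <- adam_update(params, grads, opt)
        params <- upd$params; opt <- upd$opt
      }
      train_loss <- ep_loss / n_train
      valid_loss <- eval_loss(vi)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           valid_loss = valid_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  valid %.5f",
                        epoch, train_loss, valid_loss))
      if (valid_loss < best$loss - 1e-6) {
        best <- list(loss = valid_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  structure(list(params = best$params, config = config, mode = mode,
                 S = S, class_order = class_order,
                 go_vocab = features$go_vocab, n_tissues = features$n_tissues,
                 best_valid_loss = best$loss, best_epoch = best$epoch,
                 history = history),
            class = "pheno_model")
}

init_params <- function(d1, d2, hidden, k) {
  W <- list(); b <- list()
  din <- d1
  for (h in hidden) {
    W[[length(W) + 1]] <- matrix(stats::rnorm(din * h, 0, sqrt(2 / din)), din, h)
    b[[length(b) + 1]] <- numeric(h)
    din <- h
  }
  dcat <- din + d2
  list(W = W, b = b,
       Wout = matrix(stats::rnorm(dcat * k, 0, sqrt(1 / dcat)), dcat, k),
       bout = numeric(k))
}

adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_update <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    mhat <- m / (1 - opt$beta1^opt$t)
    vhat <- v / (1 - opt$beta2^opt$t)
    list(p = p - opt$lr * mhat / (sqrt(vhat) + opt$eps), m = m, v = v)
  }
  out <- Map(step, params, grads[names(params)], opt$m, opt$v)
  list(params = lapply(out, `[[`, "p"),
       opt = utils::modifyList(opt, list(m = lapply(out, `[[`, "m"),
                                         v = lapply(out, `[[`, "v"))))
}

#' Predict phenotype scores for new genes
#'
#' @param object a `"pheno_model"` from [train_model()].
#' @param features a [build_features()] matrix built with the model's GO
#'   vocabulary (an error otherwise).
#' @param ... unused.
#' @return A [prediction_matrix()]; consistent in hierarchical mode.
#' @export
predict.pheno_model <- function(object, features, ...) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!identical(features$go_vocab, object$go_vocab))
    stop("feature vocabulary does not match the model's training vocabulary")
  if (features$n_tissues != object$n_tissues)
    stop("expression feature count does not match the trained model")
  params <- object$params
  A <- features$go_block * 1.0
  for (l in seq_along(params$W))
    A <- pmax(sweep(A %*% params$W[[l]], 2, params$b[[l]], `+`), 0)
  Z <- if (object$n_tissues > 0) cbind(A, features$expr_block) else A
  P <- sigmoid(sweep(Z %*% params$Wout, 2, params$bout, `+`))
  if (object$mode == "hierarchical")
    P <- hier_forward(P, descendant_index(object$S))$out
  prediction_matrix(features$gene_ids, object$class_order, P,
                    consistent = object$mode == "hierarchical")
}

#' @export
print.pheno_model <- function(x, ...) {
  cat(sprintf(paste0("pheno_model (%s): %d GO features + %d expression -> ",
                     "%s hidden -> %d classes; best valid loss %.5f (epoch %d)\n"),
              x$mode, length(x$go_vocab), x$n_tissues,
              paste(x$config$hidden_layers, collapse = "/"),
              length(x$class_order), x$best_valid_loss, x$best_epoch))
  invisible(x)
}

#' Random hyperparameter search
#'
#' Samples configurations from the tuning grid — units in
#' {250, 500, ..., 4000}, dropout in {0.2, 0.5}, learning rate in
#' {0.01, 0.001, 0.0001} — trains each, and returns the model with the
#' lowest validation loss.
#'
#' @param features,labels,S,mode as in [train_model()].
#' @param trials number of random-search trials.
#' @param base a [model_config()] supplying batch size, epochs, patience
#'   and seed.
#' @return The best `"pheno_model"`; the per-trial table is attached as
#'   attribute `"trials"`.
#' @export
random_search <- function(features, labels, S, trials = 10,
                          base = model_config(),
                          mode = c("hierarchical", "flat")) {
  mode <- match.arg(mode)
  grid_units <- seq(250, 4000, by = 250)
  grid_dropout <- c(0.2, 0.5)
  grid_lr <- c(0.01, 0.001, 0.0001)
  draws <- with_seed(base$seed, data.frame(
    units = sample(grid_units, trials, replace = TRUE),
    dropout = sample(grid_dropout, trials, replace = TRUE),
    lr = sample(grid_lr, trials, replace = TRUE)))
  best <- NULL
  draws$valid_loss <- NA_real_
  for (i in seq_len(trials)) {
    cfg <- model_config(hidden_layers = draws$units[i],
                        dropout_rate = draws$dropout[i],
                        learning_rate = draws$lr[i],
                        batch_size = base$batch_size,
                        max_epochs = base$max_epochs,
                        patience = base$patience, seed = base$seed + i)
    m <- train_model(features, labels, S, cfg, mode)
    draws$valid_loss[i] <- m$best_valid_loss
    if (is.null(best) || m$best_valid_loss < best$best_valid_loss) best <- m
  }
  attr(best, "trials") <- draws
  best
}

#' Save / load a trained model
#'
#' The archive holds the weights, GO vocabulary, class order, subclass
#' matrix and configuration needed to reproduce predictions exactly.
#'
#' @param model a `"pheno_model"`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pheno_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pheno_model")) stop("not a saved pheno_model: ", path)
  model
}

#' Write predictions as a long TSV (gene, hpo_id, score)
#'
#' @param preds a [prediction_matrix()].
#' @param path output path.
#' @param min_score drop scores below this value (default keep all > 0).
#' @export
write_predictions <- function(preds, path, min_score = 0) {
  idx <- which(preds$scores > min_score, arr.ind = TRUE)
  df <- data.frame(gene_id = preds$gene_ids[idx[, 1]],
                   hpo_id = preds$class_order[idx[, 2]],
                   score = preds$scores[idx])
  df <- df[order(df$gene_id, -df$score), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
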