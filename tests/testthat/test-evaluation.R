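test_that("a perfect predictor scores Fmax 1, Smin 0, AUPR 1", {
  fx <- worked_fixture()
  perfect <- prediction_matrix(
    c("g1", "g2"), c("A", "B", "C", "D", "E"),
    rbind(g1 = c(1, 1, 1, 0, 0), g2 = c(1, 1, 1, 1, 1)))
  expect_equal(fmax_score(fx$truth, perfect, fx$ont)$fmax, 1)
  expect_equal(smin_score(fx$truth, perfect, fx$ic, fx$ont)$smin, 0)
  expect_equal(aupr_score(fx$truth, perfect, fx$ont), 1)
})

test_that("an all-zero predictor scores Fmax 0 and Smin equals mean truth IC", {
  fx <- worked_fixture()
  zero <- prediction_matrix(c("g1", "g2"), c("A", "B", "C", "D", "E"),
                            matrix(0, 2, 5))
  expect_equal(fmax_score(fx$truth, zero, fx$ont)$fmax, 0)
  expect_equal(aupr_score(fx$truth, zero, fx$ont), 0)
  icv <- ic_value(fx$ic, c("B", "C", "D", "E"))
  expected <- mean(c(sum(icv[c("B", "C")]), sum(icv)))
  expect_equal(smin_score(fx$truth, zero, fx$ic, fx$ont)$smin, expected)
})

test_that("Fmax, Smin and AUPR equal the exhaustive threshold oracle on the worked fixture", {
  fx <- worked_fixture()
  classes <- c("B", "C", "D", "E")         # root A excluded
  score_list <- list(g1 = fx$scores["g1", ], g2 = fx$scores["g2", ])
  expect_equal(fmax_score(fx$truth, fx$preds, fx$ont)$fmax,
               oracle_fmax(fx$truth_sets, score_list, classes))
  expect_equal(smin_score(fx$truth, fx$preds, fx$ic, fx$ont)$smin,
               oracle_smin(fx$truth_sets, score_list, classes,
                           ic_value(fx$ic, classes)))
  expect_equal(aupr_score(fx$truth, fx$preds, fx$ont),
               oracle_aupr(fx$truth_sets, score_list, classes))
})

test_that("evaluation rejects mismatched gene lists and missing IC", {
  fx <- worked_fixture()
  other <- prediction_matrix("gX", c("B"), matrix(0.5, 1, 1))
  expect_error(fmax_score(fx$truth, other, fx$ont), "gene lists differ")
  thin_ic <- marginal_ic(annotation_set("g1", list(g1 = "B"),
                                        propagated = TRUE))
  thin_ic$values <- thin_ic$values["B"]
  expect_error(smin_score(fx$truth, fx$preds, thin_ic, fx$ont),
               "information content")
})

test_that("Fmax is invariant under grid-preserving monotone rescaling; AUROC under any", {
  ont <- gen_ontology(25, 2, seed = 91)
  truth <- propagate(ont, random_annotations(ont, 15, seed = 92))
  ord <- setdiff(ont$classes, ont$roots)
  set.seed(93)
  # scores on the grid midpoints so that squaring-type maps keep crossings
  sc <- matrix(sample(seq(0.05, 0.95, 0.1), 15 * length(ord), TRUE),
               15, length(ord), dimnames = list(truth$gene_ids, ord))
  pm <- prediction_matrix(truth$gene_ids, ord, sc)
  ranks <- (rank(unique(sort(sc))) - 0.5) / length(unique(sc))
  remap <- setNames(ranks, sort(unique(as.numeric(sc))))
  pm2 <- prediction_matrix(truth$gene_ids, ord,
                           matrix(remap[as.character(sc)], 15,
                                  dimnames = dimnames(sc)))
  expect_equal(fmax_score(truth, pm, ont)$fmax,
               fmax_score(truth, pm2, ont)$fmax)
  expect_equal(term_auroc(truth, pm, ont)$mean_auroc,
               term_auroc(truth, pm2, ont)$mean_auroc)
})

test_that("term-centric AUROC matches the pairwise oracle and handles constants", {
  ont <- gen_ontology(20, 2, seed = 101)
  truth <- propagate(ont, random_annotations(ont, 20, seed = 102))
  ord <- setdiff(ont$classes, ont$roots)
  set.seed(103)
  sc <- matrix(runif(20 * length(ord)), 20,
               dimnames = list(truth$gene_ids, ord))
  pm <- prediction_matrix(truth$gene_ids, ord, sc)
  res <- term_auroc(truth, pm, ont)
  Tm <- sapply(ord, function(c)
    vapply(truth$gene_ids, function(g) c %in% truth$assignments[[g]], TRUE))
  for (c in names(res$per_class))
    expect_equal(unname(res$per_class[c]),
                 oracle_auroc(sc[, c], Tm[, c]))
  # identical score for every gene -> exactly 0.5 per class
  flat <- prediction_matrix(truth$gene_ids, ord,
                            matrix(0.4, 20, length(ord)))
  expect_true(all(term_auroc(truth, flat, ont)$per_class == 0.5))
  # perfectly separating scores -> 1
  one_class <- ord[[1]]
  y <- Tm[, one_class]
  if (any(y) && any(!y)) {
    sep <- matrix(ifelse(y, 0.9, 0.1), 20, 1,
                  dimnames = list(truth$gene_ids, one_class))
    pm1 <- prediction_matrix(truth$gene_ids, one_class, sep)
    tr1 <- annotation_set(truth$gene_ids,
                          lapply(truth$assignments, intersect, one_class),
                          propagated = TRUE)
    expect_equal(unname(term_auroc(tr1, pm1)$per_class[one_class]), 1)
  }
})

test_that("metrics are unchanged when the truth is propagated twice", {
  ont <- gen_ontology(25, 2, seed = 111)
  truth <- propagate(ont, random_annotations(ont, 12, seed = 112))
  ord <- setdiff(ont$classes, ont$roots)
  set.seed(113)
  sc <- matrix(runif(12 * length(ord)), 12,
               dimnames = list(truth$gene_ids, ord))
  pm <- prediction_matrix(truth$gene_ids, ord, sc)
  twice <- propagate(ont, truth)
  expect_equal(fmax_score(truth, pm, ont)$fmax,
               fmax_score(twice, pm, ont)$fmax)
  expect_equal(term_auroc(truth, pm, ont)$mean_auroc,
               term_auroc(twice, pm, ont)$mean_auroc)
})

test_that("overlap statistic and p-value behave on extreme graphs", {
  known <- list(ph1 = c("g1", "g2"), ph2 = c("g3", "g4"))
  preds <- list(ph1 = c("g1", "g5"), ph2 = c("g6", "g3"))
  # g5 adjacent to known g2; g6 adjacent to known g4 -> overlap 1
  edges <- data.frame(gene_a = c("g5", "g6"), gene_b = c("g2", "g4"))
  res <- ppi_overlap_test(preds, known, edges, n_perm = 200, seed = 5,
                          gene_universe = sprintf("g%d", 1:20))
  expect_equal(res$observed_mean_overlap, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  # edgeless graph: observed 0, p = 1 by the add-one rule
  none <- data.frame(gene_a = character(), gene_b = character())
  res0 <- ppi_overlap_test(preds, known, none, n_perm = 100, seed = 6,
                           gene_universe = sprintf("g%d", 1:20))
  expect_equal(res0$observed_mean_overlap, 0)
  expect_equal(res0$p_value, 1)

  expect_error(ppi_overlap_test(preds, list(ph1 = character(),
                                            ph2 = character()),
                                edges), "non-empty known")
})

test_that("evaluation reports serialise to JSON", {
  fx <- worked_fixture()
  rep <- evaluate_predictions(fx$truth, fx$preds, fx$ont, fx$ic)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$fmax, rep$fmax)
  expect_equal(back$smin, rep$smin)
})
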