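test_that("gene-phenotype reader deduplicates and validates columns", {
  p <- write_tsv_fixture(data.frame(gene_id = c("g1", "g1"),
                                    hpo_id = c("HP:1", "HP:1")))
  an <- read_gene_phenotypes(p)
  expect_equal(an$assignments$g1, "HP:1")
  expect_false(an$propagated)

  p <- write_tsv_fixture(data.frame(gene_id = character(),
                                    hpo_id = character()))
  expect_equal(length(read_gene_phenotypes(p)$gene_ids), 0)

  p <- write_tsv_fixture(data.frame(gene_id = c("g1", "g1", "g2", "g3", "g3"),
                                    hpo_id = c("HP:1", "HP:2", "HP:1",
                                               "HP:3", "HP:3")))
  an <- read_gene_phenotypes(p)
  expect_equal(length(an$gene_ids), 3)
  expect_equal(sum(lengths(an$assignments)), 4)

  p <- write_tsv_fixture(data.frame(foo = "g1", bar = "HP:1"))
  expect_error(read_gene_phenotypes(p), "gene_id")
})

test_that("GO annotation reader applies evidence filters and NOT qualifiers", {
  p <- write_tsv_fixture(data.frame(
    gene_id = c("g1", "g1", "g2"),
    go_id = c("GO:1", "GO:2", "GO:3"),
    evidence = c("IEA", "IDA", "TAS")))
  an <- read_go_annotations(p, evidence_filter = experimental_evidence_codes())
  expect_equal(an$assignments$g1, "GO:2")     # IEA dropped, IDA kept
  expect_equal(an$assignments$g2, "GO:3")     # TAS experimental
  an_all <- read_go_annotations(p)
  expect_equal(sum(lengths(an_all$assignments)), 3)

  gaf <- tempfile(fileext = ".gaf")
  row <- function(gene, qual, go, ev)
    paste(c("UniProt", gene, gene, qual, go, "REF", ev,
            "", "P", "", "", "protein", "taxon:9606", "20190101",
            "UniProt", "", ""), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("P1", "", "GO:0001", "IDA"),
               row("P1", "NOT", "GO:0002", "IDA"),
               row("P2", "", "GO:0003", "IEA")), gaf)
  an <- read_go_annotations(gaf, format = "gaf")
  expect_equal(an$assignments$P1, "GO:0001")  # NOT row dropped
  expect_equal(an$assignments$P2, "GO:0003")
  an <- read_go_annotations(gaf, format = "gaf",
                            evidence_filter = experimental_evidence_codes())
  expect_false("P2" %in% an$gene_ids)
})

test_that("expression reader handles NA cells, duplicates, ragged rows", {
  p <- write_tsv_fixture(data.frame(gene_id = c("g1", "g2"),
                                    t1 = c(1, 4), t2 = c(2, 5),
                                    t3 = c("NA", "6")))
  m <- read_expression(p)
  expect_equal(dim(m), c(2, 3))
  expect_true(is.na(m["g1", "t3"]))
  expect_equal(m["g2", "t3"], 6)

  p <- write_tsv_fixture(data.frame(gene_id = c("g1", "g1"),
                                    t1 = c(1, 9)))
  expect_warning(m <- read_expression(p), "last row wins")
  expect_equal(unname(m["g1", "t1"]), 9)

  ragged <- tempfile()
  writeLines(c("gene_id\tt1\tt2", "g1\t1\t2", "g2\t3"), ragged)
  expect_error(read_expression(ragged), "ragged")
})

test_that("class selection respects the minimum-gene rule and skips roots", {
  ont <- chain_ontology(c("A", "B", "C"))
  genes <- sprintf("g%02d", 1:12)
  sets <- c(lapply(1:10, function(i) c("A", "B")),
            lapply(11:12, function(i) c("A", "B", "C")))
  names(sets) <- genes
  an <- annotation_set(genes, sets, propagated = TRUE)
  expect_equal(select_classes(an, ont, min_genes = 10), "B")   # C has 2 < 10
  # class with exactly min_genes genes is included
  an2 <- annotation_set(genes[1:10],
                        setNames(lapply(1:10, function(i) c("A", "B", "C")),
                                 genes[1:10]),
                        propagated = TRUE)
  expect_setequal(select_classes(an2, ont, min_genes = 10), c("B", "C"))
  expect_setequal(select_classes(an, ont, min_genes = 1), c("B", "C"))
  expect_error(select_classes(annotation_set("g1", list(g1 = "A")), ont),
               "propagated")
})

test_that("feature building produces closed binary GO rows and z-scored expression", {
  ont <- chain_ontology(c("A", "B", "C"))
  an <- propagate(ont, annotation_set(c("g1", "g2"),
                                      list(g1 = "C", g2 = "B")))
  expr <- matrix(c(1, 2, 3, 10), 1, 4,
                 dimnames = list("g1", paste0("t", 1:4)))
  fm <- build_features(an, vocab = c("A", "B", "C"), expression = expr)
  expect_equal(unname(fm$go_block["g1", ]), c(1L, 1L, 1L))  # leaf + ancestors
  expect_equal(unname(fm$go_block["g2", ]), c(1L, 1L, 0L))
  # z-score: mean 0, sd 1 over observed tissues
  expect_equal(mean(fm$expr_block["g1", ]), 0, tolerance = 1e-12)
  expect_equal(sd(fm$expr_block["g1", ]), 1, tolerance = 1e-12)
  # gene with no expression record gets an all-zero row
  expect_equal(unname(fm$expr_block["g2", ]), rep(0, 4))
  expect_error(build_features(an, character()), "empty")
  # unseen GO classes are ignored
  an2 <- propagate(ont, annotation_set("g1", list(g1 = "C")))
  fm2 <- build_features(an2, vocab = c("B", "C"))
  expect_equal(dim(fm2$go_block), c(1, 2))
})

test_that("gene-level splits are disjoint, covering, and deterministic", {
  genes <- sprintf("g%03d", 1:100)
  sp <- split_by_gene(genes, seed = 7)
  f <- sp$folds[[1]]
  expect_equal(length(f$test), 20)
  expect_equal(length(f$valid), 8)
  expect_equal(length(f$train), 72)
  expect_equal(sort(c(f$train, f$valid, f$test)), genes)
  expect_length(intersect(f$train, f$test), 0)
  expect_length(intersect(f$valid, f$test), 0)
  expect_length(intersect(f$train, f$valid), 0)
  # same seed -> identical folds
  sp2 <- split_by_gene(genes, seed = 7)
  expect_identical(sp, sp2)
  # the five test sets partition the genes
  tests <- lapply(sp$folds, `[[`, "test")
  expect_setequal(unlist(tests), genes)
  expect_equal(sum(lengths(tests)), 100)
  expect_error(split_by_gene(genes, test_fraction = 1.5), "test_fraction")
  expect_error(split_by_gene(genes[1:3], folds = 5), "fewer genes")
})
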