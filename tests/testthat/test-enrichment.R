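test_that("ontology loading propagates annotations up the is_a chain", {
  obo <- write_tiny_obo(withr::local_tempfile(fileext = ".obo"))
  dag <- load_ontology(obo)
  expect_equal(nrow(dag$terms), 3)           # obsolete term excluded
  expect_identical(term_ancestors(dag, "GO:0000003"),
                   c("GO:0000001", "GO:0000002"))
  ann_f <- withr::local_tempfile()
  writeLines(c("g1\tGO:0000003", "g2\tGO:0000002", "g3\tGO:0000001",
               "g4\tGO:9999999"), ann_f)
  expect_warning(ann <- load_annotations(ann_f, dag), "unknown")
  expect_true(all(c("g1", "g2", "g3") %in% ann$propagated[["GO:0000001"]]))
  expect_identical(ann$direct[["GO:0000003"]], "g1")
  expect_false("g4" %in% ann$universe)
  # invariants: direct subset propagated; parent superset child
  for (t in names(ann$direct))
    expect_true(all(ann$direct[[t]] %in% ann$propagated[[t]]))
  expect_true(all(ann$propagated[["GO:0000002"]] %in%
                  ann$propagated[["GO:0000001"]]))
})

test_that("cyclic is_a is a format error and empty annotations give empty maps", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "is_a: B", "",
               "[Term]", "id: B", "name: b", "is_a: A", ""), obo)
  expect_error(load_ontology(obo), "cyclic")
  dag <- load_ontology(write_tiny_obo(withr::local_tempfile(fileext = ".obo")))
  ann_f <- withr::local_tempfile()
  writeLines(character(), ann_f)
  ann <- load_annotations(ann_f, dag)
  expect_length(ann$universe, 0)
  expect_length(ann$propagated, 0)
})

test_that("GAF rows are parsed with NOT-qualifier and evidence filtering", {
  dag <- load_ontology(write_tiny_obo(withr::local_tempfile(fileext = ".obo")))
  gaf <- withr::local_tempfile()
  row <- function(gene, term, ev, qual = "") {
    paste(c("DB", paste0("ID_", gene), gene, qual, term, "REF", ev,
            "", "P", "", "", "protein", "taxon:9606", "20260101", "DB",
            "", ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               row("g1", "GO:0000003", "EXP"),
               row("g2", "GO:0000002", "IEA"),
               row("g3", "GO:0000002", "EXP", qual = "NOT|involved_in")),
             gaf)
  ann <- load_annotations(gaf, dag)
  expect_setequal(ann$universe, c("g1", "g2"))   # NOT row skipped
  ann_exp <- load_annotations(gaf, dag, evidence_filter = "EXP")
  expect_identical(ann_exp$universe, "g1")
})

test_that("over-representation p-values match the exact tail", {
  # N=10, K=4, n=5, x=4 -> 6/252
  ann <- ann_fixture(N = 10, K = 4)
  res <- overrepresentation(sprintf("g%02d", 1:5), ann, adjust = "none")
  expect_equal(res$p_raw[res$term_id == "T1"],
               hyper_tail_oracle(10, 4, 5, 4), tolerance = 1e-12)
  expect_equal(res$p_raw[res$term_id == "T1"], 6 / 252, tolerance = 1e-12)
  # x = 0 -> p = 1; query = universe -> p = 1
  res0 <- overrepresentation(sprintf("g%02d", 5:10), ann, adjust = "none")
  expect_identical(res0$p_raw, 1)
  resU <- overrepresentation(ann$universe, ann, adjust = "none")
  expect_identical(resU$p_raw, 1)
})

test_that("query hygiene: out-of-universe genes drop, empty query errors", {
  ann <- ann_fixture(N = 8, K = 4)
  expect_warning(res <- overrepresentation(c("g01", "nope"), ann,
                                           adjust = "none"), "absent")
  expect_identical(res$n[1], 1L)
  expect_error(suppressWarnings(overrepresentation("nope", ann)), "universe")
  # min_term_size skips small terms
  expect_equal(nrow(overrepresentation("g01", ann, min_term_size = 5)), 0)
})

test_that("adding an annotated gene to the query never raises that term's p", {
  ann <- ann_fixture(N = 20, K = 8)
  q <- sprintf("g%02d", 9:12)  # start outside the term
  p_prev <- overrepresentation(q, ann, adjust = "none")$p_raw
  for (g in sprintf("g%02d", 1:4)) {
    q <- c(q, g)
    p_now <- overrepresentation(q, ann, adjust = "none")$p_raw
    expect_lte(p_now, p_prev)
    p_prev <- p_now
  }
})

test_that("BH adjustment matches the step-up definition", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  ann <- ann_fixture(N = 12, K = 5)
  res <- overrepresentation(sprintf("g%02d", 1:5), ann, adjust = "bh")
  expect_equal(res$p_adjusted, bh_oracle(res$p_raw), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_raw))
})

test_that("per-group enrichment stacks group results", {
  dag <- load_ontology(write_tiny_obo(withr::local_tempfile(fileext = ".obo")))
  ann_f <- withr::local_tempfile()
  writeLines(sprintf("g%d\tGO:000000%d", 1:9, rep(1:3, each = 3)), ann_f)
  ann <- load_annotations(ann_f, dag)
  net <- network(sprintf("g%d", 1:9))
  net <- add_group(net, c("g7", "g8", "g9"), "mod1")  # all on leaf term
  net <- add_group(net, c("g1", "g2"), "mod2")
  res <- enrich_groups(net, ann, adjust = "none", min_term_size = 2)
  expect_true(all(c("mod1", "mod2") %in% res$group))
  leaf <- res[res$group == "mod1" & res$term_id == "GO:0000003", ]
  expect_equal(leaf$x, 3)
  expect_equal(leaf$p_raw, hyper_tail_oracle(9, 3, 3, 3), tolerance = 1e-12)
})
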