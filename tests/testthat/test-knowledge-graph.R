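test_that("terms round-trip by provenance key and collisions are rejected", {
  g <- kb_graph()
  g <- kb_add_term(g, "ncit", "C1234", "Imatinib", "v1", termClass = "therapy")
  t <- kb_get_term(g, term_key("ncit", "C1234", "v1"))
  expect_equal(t$name, "Imatinib")
  expect_equal(t$sourceIdVersion, "v1")
  expect_error(kb_add_term(g, "ncit", "C1234", "Imatinib again", "v1"),
               class = "oncomatch_collision")
  # a different version is a different key
  g <- kb_add_term(g, "ncit", "C1234", "Imatinib", "v2", termClass = "therapy")
  expect_equal(nrow(g$terms), 2L)
  expect_error(kb_add_term(g, "ncit", "C9", "   "),
               class = "oncomatch_invariant")
})

test_that("batch-loading three sources gives per-source counts matching an independent scan", {
  records <- data.frame(
    source = rep(c("ncit", "drugbank", "chembl"), each = 100),
    sourceId = paste0("ID", 1:300),
    name = paste("compound", 1:300),
    stringsAsFactors = FALSE)
  g <- kb_graph()
  for (i in seq_len(nrow(records)))
    g <- kb_add_term(g, records$source[i], records$sourceId[i],
                     records$name[i], termClass = "therapy")
  # oracle: count input records per source directly
  expected <- table(records$source)
  got <- table(g$terms$source)
  expect_equal(as.integer(got[names(expected)]), as.integer(expected))
  expect_true(all(got == 100L))
})

test_that("name lookup is exact after normalization and returns the ambiguity set", {
  g <- kb_graph()
  g <- kb_add_term(g, "ncit", "C1", "imatinib", termClass = "therapy")
  g <- kb_add_term(g, "drugbank", "DB1", "Imatinib", termClass = "therapy")
  g <- kb_add_term(g, "ncit", "C2", "gefitinib", termClass = "therapy")
  hits <- kb_find_terms_by_name(g, "  Imatinib ")
  expect_setequal(hits$source, c("ncit", "drugbank"))
  expect_error(kb_find_terms_by_name(g, "absent-drug"),
               class = "oncomatch_no_match")
  # oracle: linear scan over normalized names
  scan <- g$terms$key[tolower(trimws(g$terms$name)) == "imatinib"]
  expect_setequal(hits$key, scan)
  expect_equal(nrow(kb_find_terms_by_name(g, "imatinib", termClass = "therapy")), 2L)
  expect_error(kb_find_terms_by_name(g, "imatinib", termClass = "disease"),
               class = "oncomatch_no_match")
})

make_stmt_graph <- function() {
  g <- kb_graph()
  g <- kb_add_term(g, "vocab", "R1", "sensitivity",
                   termClass = "relevance_term", category = "therapeutic")
  g <- kb_add_term(g, "ncit", "D1", "imatinib", termClass = "therapy")
  g <- kb_add_term(g, "ncit", "C1", "leukemia", termClass = "disease")
  g
}

test_that("statements enforce exactly one subject/relevance and >=1 condition/evidence", {
  g <- make_stmt_graph()
  conds <- list(
    kb_condition("variant", gene = "ABL1", variantClass = "fusion"),
    kb_condition("term", termKey = term_key("ncit", "C1")))
  g <- kb_add_statement(g, "S1", conds, term_key("ncit", "D1"),
                        term_key("vocab", "R1"),
                        list(list(citationId = "PMID:1")), "civic")
  expect_equal(length(g$statements), 1L)
  expect_equal(g$statements$S1$relevanceCategory, "therapeutic")

  expect_error(kb_add_statement(g, "S2", list(), term_key("ncit", "D1"),
                                term_key("vocab", "R1"),
                                list(list(citationId = "x")), "civic"),
               class = "oncomatch_invariant")
  expect_error(kb_add_statement(g, "S2", conds, term_key("ncit", "D1"),
                                term_key("vocab", "R1"), list(), "civic"),
               class = "oncomatch_invariant")
  expect_error(kb_add_statement(g, "S2", conds, term_key("ncit", "MISSING"),
                                term_key("vocab", "R1"),
                                list(list(citationId = "x")), "civic"),
               class = "oncomatch_referential")
  dangling <- list(kb_condition("term", termKey = term_key("ncit", "NOPE")))
  expect_error(kb_add_statement(g, "S2", dangling, term_key("ncit", "D1"),
                                term_key("vocab", "R1"),
                                list(list(citationId = "x")), "civic"),
               class = "oncomatch_referential")
  # relevance must be a relevance_term with a category
  expect_error(kb_add_statement(g, "S2", conds, term_key("ncit", "D1"),
                                term_key("ncit", "D1"),
                                list(list(citationId = "x")), "civic"),
               class = "oncomatch_invariant")
})

test_that("reverse index agrees with a brute-force scan on a random 50-statement graph", {
  rk <- random_kb(11, n_statements = 50)
  g <- rk$graph
  # term-condition index
  for (tk in unique(g$terms$key)) {
    scan <- names(Filter(function(stmt) any(vapply(stmt$conditions,
      function(cd) cd$kind == "term" && identical(cd$termKey, tk),
      logical(1))), g$statements))
    expect_setequal(kb_statements_for_term(g, termKey = tk), scan)
  }
  # gene index for variant conditions
  for (gene in sprintf("G%02d", 1:12)) {
    scan <- names(Filter(function(stmt) any(vapply(stmt$conditions,
      function(cd) cd$kind == "variant" && nrm(cd$gene) == nrm(gene),
      logical(1))), g$statements))
    expect_setequal(kb_statements_for_term(g, gene = gene), scan)
  }
})

test_that("validate_graph reports exactly the injected defects", {
  expect_equal(nrow(kb_validate(kb_graph())), 0L)

  rk <- random_kb(5, n_statements = 20)
  g <- rk$graph
  expect_equal(nrow(kb_validate(g)), 0L)

  # inject a known defect set, bypassing the API
  set.seed(42)
  g$edges <- rbind(g$edges, data.table::data.table(
    fromKey = "ghost|X|", toKey = g$terms$key[1],
    edgeType = "cross_reference", assertedBy = "x"))
  g$terms <- rbind(g$terms, g$terms[3])                   # duplicate key
  alias_row <- data.table::copy(g$terms[5])
  alias_row$key <- term_key("ncit", "ORPHAN")
  alias_row$source <- "ncit"; alias_row$sourceId <- "ORPHAN"
  alias_row$isAlias <- TRUE
  g$terms <- rbind(g$terms, alias_row)                    # alias, no edge
  report <- kb_validate(g)
  expect_setequal(report$kind,
                  c("dangling_edge", "duplicate_key", "alias_without_primary"))
  expect_equal(nrow(report), 3L)
})

test_that("graph serialization round-trips terms, edges and statements", {
  for (seed in c(2, 9)) {
    g <- random_kb(seed, n_statements = 25)$graph
    dir <- withr::local_tempdir()
    write_kb(g, dir)
    g2 <- read_kb(dir)
    expect_equal(data.table::setorder(data.table::copy(g$terms), key),
                 data.table::setorder(data.table::copy(g2$terms), key),
                 ignore_attr = TRUE)
    ekey <- function(e) sort(do.call(paste, as.list(e)))
    expect_equal(ekey(g$edges), ekey(g2$edges))
    expect_equal(g$statements[sort(names(g$statements))],
                 g2$statements[sort(names(g2$statements))])
  }
})
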