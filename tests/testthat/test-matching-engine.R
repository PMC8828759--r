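# Direct/second-pass matching and the five applicability filters.

kras_graph <- function() {
  g <- kb_graph()
  g <- kb_add_term(g, "vocab", "R1", "sensitivity",
                   termClass = "relevance_term", category = "therapeutic")
  g <- kb_add_term(g, "vocab", "R2", "resistance",
                   termClass = "relevance_term", category = "therapeutic")
  g <- kb_add_term(g, "vocab", "R3", "oncogenic",
                   termClass = "relevance_term", category = "biological")
  for (i in seq_along(c("mutation", "missense mutation", "oncogenic")))
    g <- kb_add_term(g, "vocab", paste0("V", i),
                     c("mutation", "missense mutation", "oncogenic")[i],
                     termClass = "variant_class")
  g <- kb_add_edge(g, term_key("vocab", "V2"), term_key("vocab", "V1"),
                   "generalizes")
  g <- kb_add_term(g, "hgnc", "H1", "KRAS", termClass = "gene")
  g <- kb_add_term(g, "ncit", "D1", "cetuximab", termClass = "therapy")
  g <- kb_add_term(g, "ncit", "D2", "trametinib", termClass = "therapy")
  g
}

kras_variants <- function()
  variant_set(small_mutations = data.table::data.table(
    sample = "S", gene = "KRAS", proteinChange = "p.G12D",
    classification = "Missense_Mutation"))

test_that("position-specific and gene-level small-mutation matching", {
  g <- kras_graph()
  g <- kb_add_statement(g, "SPEC",
    list(kb_condition("variant", gene = "KRAS",
                      variantClass = "missense mutation",
                      proteinChange = "p.G12D")),
    term_key("ncit", "D2"), term_key("vocab", "R1"),
    list(list(citationId = "PMID:1")), "civic")
  g <- kb_add_statement(g, "GENE",
    list(kb_condition("variant", gene = "KRAS", variantClass = "mutation")),
    term_key("ncit", "D2"), term_key("vocab", "R1"),
    list(list(citationId = "PMID:2")), "civic")
  m <- match_direct(g, kras_variants())
  expect_setequal(m$statementId, c("SPEC", "GENE"))
  expect_false(m$nonSpecific[m$statementId == "SPEC"])
  expect_true(m$nonSpecific[m$statementId == "GENE"])
  # protein comparison strips the optional p. prefix and case
  vs2 <- variant_set(small_mutations = data.table::data.table(
    sample = "S", gene = "kras", proteinChange = "G12D",
    classification = "Missense_Mutation"))
  m2 <- match_direct(g, vs2)
  expect_true("SPEC" %in% m2$statementId)
  # a different position matches only the gene-level statement
  vs3 <- variant_set(small_mutations = data.table::data.table(
    sample = "S", gene = "KRAS", proteinChange = "p.G13D",
    classification = "Missense_Mutation"))
  expect_equal(match_direct(g, vs3)$statementId, "GENE")
  expect_equal(nrow(match_direct(g, variant_set())), 0L)
})

second_pass_graph <- function() {
  g <- kras_graph()
  g <- kb_add_statement(g, "S1",
    list(kb_condition("variant", gene = "KRAS",
                      variantClass = "missense mutation",
                      proteinChange = "p.G12D")),
    term_key("hgnc", "H1"), term_key("vocab", "R3"),
    list(list(citationId = "PMID:1")), "civic")
  g <- kb_add_statement(g, "S2",
    list(kb_condition("variant", gene = "KRAS", variantClass = "oncogenic")),
    term_key("ncit", "D1"), term_key("vocab", "R2"),
    list(list(citationId = "PMID:2")), "oncokb")
  # S3 builds on S2's conclusion (resistance), not on a variant class: it can
  # never be reached by a single inference hop
  g <- kb_add_statement(g, "S3",
    list(kb_condition("variant", gene = "KRAS", variantClass = "resistance")),
    term_key("ncit", "D2"), term_key("vocab", "R1"),
    list(list(citationId = "PMID:3")), "civic")
  g
}

test_that("second-pass matching takes exactly one inference hop", {
  g <- second_pass_graph()
  direct <- match_direct(g, kras_variants())
  expect_equal(direct$statementId, "S1")  # S2/S3 have no directly observable class
  second <- match_second_pass(g, direct)
  expect_equal(second$statementId, "S2")
  expect_equal(second$viaStatement, "S1")
  expect_equal(second$pathKind, "second_pass")
  expect_true(second$nonSpecific)  # driven by a small mutation, no position in S2
  expect_false("S3" %in% second$statementId)  # no chaining
  expect_equal(nrow(match_second_pass(g, match_direct(g, variant_set()))), 0L)
  # a non-biological direct match seeds nothing
  g2 <- kras_graph()
  g2 <- kb_add_statement(g2, "T1",
    list(kb_condition("variant", gene = "KRAS", variantClass = "mutation")),
    term_key("ncit", "D1"), term_key("vocab", "R1"),
    list(list(citationId = "x")), "civic")
  expect_equal(nrow(match_second_pass(g2, match_direct(g2, kras_variants()))), 0L)
})

test_that("AMP tier map assigns tier I to exactly the enumerated pairs", {
  tier1 <- list(civic = "A",
                cgi = c("FDA guidelines", "NCCN guidelines", "CPIC guidelines",
                        "NCCN/CAP guidelines",
                        "European Leukemianet guidelines"),
                oncokb = c("1", "R1", "2A"))
  for (src in names(tier1)) for (lv in tier1[[src]])
    expect_equal(map_evidence_to_amp_tier(src, lv), "tier_I")
  # case-insensitive on both fields
  expect_equal(map_evidence_to_amp_tier("CIViC", "a"), "tier_I")
  expect_equal(map_evidence_to_amp_tier("OncoKB", "r1"), "tier_I")
  # near-misses and no-scheme sources are unassigned
  unassigned <- list(civic = c("B", "C"), oncokb = c("2B", "3A", "4"),
                     cgi = "Early trials", cosmic = c("A", "1", "anything"),
                     docm = "1", unknown_source = "A")
  for (src in names(unassigned)) for (lv in unassigned[[src]])
    expect_equal(map_evidence_to_amp_tier(src, lv), "unassigned")
})

test_that("engine equals the brute-force oracle on random fixtures", {
  for (seed in 1:6) {
    rk <- random_kb(seed, n_statements = 40, n_samples = 2, n_variants = 25)
    for (vs in rk$samples) {
      m <- match_sample(rk$graph, vs)
      expect_identical(engine_match_signatures(m),
                       oracle_match_sample(rk$graph, vs))
    }
  }
})

test_that("removing a variant never adds a match", {
  rk <- random_kb(3, n_statements = 40, n_samples = 1, n_variants = 30)
  vs <- rk$samples[[1]]
  full <- engine_match_signatures(match_sample(rk$graph, vs))
  reduced <- vs
  reduced$small_mutations <- reduced$small_mutations[-1]
  reduced$fusions <- reduced$fusions[-1]
  msub <- match_sample(rk$graph, reduced)
  # every reduced-set match statement also matched with the full set
  full_stmts <- unique(sub("\\|.*", "", full))
  expect_true(all(msub$statementId %in% full_stmts))
})

filters_fixture <- function() {
  g <- second_pass_graph()
  g <- kb_add_term(g, "ncit", "C1", "colorectal cancer", termClass = "disease")
  g <- kb_add_term(g, "ncit", "C2", "melanoma", termClass = "disease")
  # tier-I, disease-restricted, specific
  g <- kb_add_statement(g, "F1",
    list(kb_condition("variant", gene = "KRAS",
                      variantClass = "missense mutation",
                      proteinChange = "p.G12D"),
         kb_condition("term", termKey = term_key("ncit", "C1"))),
    term_key("ncit", "D1"), term_key("vocab", "R1"),
    list(list(citationId = "PMID:9", levelSource = "oncokb",
              levelLabel = "1")), "oncokb")
  # weak evidence, wrong disease, gene-level
  g <- kb_add_statement(g, "F2",
    list(kb_condition("variant", gene = "KRAS", variantClass = "mutation"),
         kb_condition("term", termKey = term_key("ncit", "C2"))),
    term_key("ncit", "D2"), term_key("vocab", "R2"),
    list(list(citationId = "PMID:10", levelSource = "civic",
              levelLabel = "C")), "civic")
  g
}

empty_matches_for_test <- function() {
  m <- match_direct(kras_graph(), variant_set())
  stopifnot(nrow(m) == 0L)
  m
}

test_that("filters are subset-preserving, idempotent and order-independent", {
  g <- filters_fixture()
  vs <- kras_variants()
  m <- match_sample(g, vs)
  expect_setequal(m$statementId, c("S1", "F1", "F2", "S2"))
  diag <- expand_diagnosis(g, "", "colorectal cancer", "")

  all_filters <- c("amp_tier_i", "diagnosis_match", "position_specific",
                   "direct_match", "non_synon")
  combos <- unlist(lapply(0:5, function(k)
    combn(all_filters, k, simplify = FALSE)), recursive = FALSE)
  expect_length(combos, 32L)
  for (sel in combos) {
    out <- apply_filters(g, m, sel, diag)
    # subset of the input
    expect_true(all(out$statementId %in% m$statementId))
    # idempotent
    expect_identical(engine_match_signatures(apply_filters(g, out, sel, diag)),
                     engine_match_signatures(out))
    # order-independent and equal to the intersection of single filters
    if (length(sel) > 1) {
      perm <- rev(sel)
      seq_out <- m
      for (f in perm) seq_out <- apply_filters(g, seq_out, f, diag)
      expect_identical(engine_match_signatures(out),
                       engine_match_signatures(seq_out))
      single <- lapply(sel, function(f)
        engine_match_signatures(apply_filters(g, m, f, diag)))
      expect_identical(engine_match_signatures(out),
                       sort(Reduce(intersect, single)))
    }
  }
  # the direct filter removes exactly the second-pass match
  direct_only <- apply_filters(g, m, "direct_match")
  expect_setequal(setdiff(m$statementId, direct_only$statementId), "S2")
  # tier filter keeps only F1
  expect_equal(apply_filters(g, m, "amp_tier_i")$statementId, "F1")
  # diagnosis: F2 is melanoma-only and drops; S1/S2 have no disease condition
  kept <- apply_filters(g, m, "diagnosis_match", diag)$statementId
  expect_setequal(kept, c("S1", "F1", "S2"))
  expect_error(apply_filters(g, m, "diagnosis_match"),
               class = "oncomatch_config")
  expect_error(apply_filters(g, m, "bogus"), class = "oncomatch_config")
  expect_equal(nrow(apply_filters(g, empty_matches_for_test(), "non_synon")), 0L)
})

test_that("non-synon filter inspects every small-mutation variant of a match", {
  g <- kras_graph()
  g <- kb_add_statement(g, "G1",
    list(kb_condition("variant", gene = "KRAS", variantClass = "mutation")),
    term_key("ncit", "D1"), term_key("vocab", "R1"),
    list(list(citationId = "x")), "civic")
  silent <- variant_set(small_mutations = data.table::data.table(
    sample = "S", gene = "KRAS", proteinChange = "p.R213R",
    classification = "Silent"))
  m <- match_direct(g, silent)
  expect_equal(nrow(apply_filters(g, m, "non_synon")), 0L)
  m2 <- match_direct(g, kras_variants())
  expect_equal(nrow(apply_filters(g, m2, "non_synon")), 1L)
})
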