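# Seeded synthetic fixtures: toy ontologies, a toy knowledge base, a variant
# cohort with planted matches, and registry-style trial records. The
# generator stands in for licensed external knowledge bases, TCGA-scale
# cohorts and registry dumps; every planted truth is recorded in a manifest
# so downstream modules can be checked against construction-time expectations
# rather than against their own output.

default_sizes <- function() {
  list(
    n_statements = 60,     # evidence statements in the toy knowledge base
    n_samples = 20,        # cohort size (>= 20 so a planted unique expression
                           # outlier clears the 97.5 / 2.5 percentile bounds)
    n_drugs = 30,          # drug concepts across the drug ontologies
    n_diseases = 8,        # oncotree/ncit disease pairs
    n_trials = 150,        # registry records
    n_noise_genes = 20,    # genes absent from the knowledge base
    n_second_pass = 5,     # functional/consequent statement pairs
    n_shared_pairs = 4,    # cross-source conclusion pairs merged by links
    p_plant = 0.12,        # per (statement, sample) planting probability
    p_drugbank = 0.6,      # drug concept also present in the second source
    alias_rate = 0.3,      # alias record per drug concept
    xref_rate = 0.5,       # cross-reference linking the concept's sources
    p_disease_cond = 0.5,  # therapeutic statements carrying a disease term
    p_tier1 = 0.4          # statements with Tier-I compatible evidence
  )
}

RELEVANCE_VOCAB <- data.table(
  name = c("sensitivity", "resistance", "diagnostic indicator",
           "favourable prognosis", "unfavourable prognosis", "oncogenic"),
  category = c("therapeutic", "therapeutic", "diagnostic", "prognostic",
               "prognostic", "biological"))

VARIANT_CLASS_VOCAB <- c("mutation", "missense mutation", "deep deletion",
                         "amplification", "increased expression",
                         "reduced expression", "fusion", "oncogenic")

#' Generate a seeded synthetic input bundle
#'
#' Builds, as a pure function of `(seed, sizes)`: multi-source toy drug and
#' disease ontologies with controlled alias/cross-reference overlap; a
#' knowledge base of statements spanning all four variant types, all
#' relevance categories, gene-level and position-specific mutation
#' conditions, and functional/consequent pairs enabling second-pass
#' inference; a cohort with planted variants; and registry records with a
#' controlled term-frequency spectrum. The manifest records every planted
#' truth: expected matches per sample, expected concordance counts, expected
#' variant-type breakdown and expected coverages.
#'
#' @param seed integer RNG seed.
#' @param sizes named list overriding [default_sizes()] entries.
#' @param dir optional output directory; when given, the full bundle (KB
#'   files, cohort files, registry, manifest.json) is written there.
#' @return list with `graph`, `variants`, `diagnoses`, `registry_records`
#'   and `manifest`, invisibly when `dir` is given.
#' @export
generate_fixture <- function(seed, sizes = list(), dir = NULL) {
  sz <- modifyList(default_sizes(), sizes)
  if (any(unlist(sz) < 0)) om_stop("sizes must be non-negative", "config")
  if (sz$n_statements < 1 || sz$n_samples < 1)
    om_stop("need at least one statement and one sample", "config")
  set.seed(seed)

  g <- kb_graph()

  # --- controlled vocabulary -------------------------------------------
  for (i in seq_len(nrow(RELEVANCE_VOCAB)))
    g <- kb_add_term(g, "vocab", paste0("R", i), RELEVANCE_VOCAB$name[i],
                     termClass = "relevance_term",
                     category = RELEVANCE_VOCAB$category[i])
  rel_key <- function(nm)
    g$terms$key[g$terms$termClass == "relevance_term" & g$terms$normName == nm]
  for (i in seq_along(VARIANT_CLASS_VOCAB))
    g <- kb_add_term(g, "vocab", paste0("V", i), VARIANT_CLASS_VOCAB[i],
                     termClass = "variant_class")
  vc_key <- function(nm)
    g$terms$key[g$terms$termClass == "variant_class" & g$terms$normName == nm]
  g <- kb_add_edge(g, vc_key("missense mutation"), vc_key("mutation"),
                   "generalizes", "vocab")

  # --- diseases: oncotree codes cross-referenced to an ncit chain ------
  disease_names <- sprintf("carcinoma type %02d", seq_len(sz$n_diseases))
  g <- kb_add_term(g, "ncit", "C0", "cancer", termClass = "disease")
  oncotree_codes <- sprintf("DX%02d", seq_len(sz$n_diseases))
  for (i in seq_len(sz$n_diseases)) {
    g <- kb_add_term(g, "ncit", paste0("C", i), disease_names[i],
                     termClass = "disease")
    g <- kb_add_edge(g, term_key("ncit", paste0("C", i)), term_key("ncit", "C0"),
                     "subclass_of", "ncit")
    g <- kb_add_term(g, "oncotree", oncotree_codes[i],
                     paste(disease_names[i], "(oncotree)"),
                     termClass = "disease")
    g <- kb_add_edge(g, term_key("oncotree", oncotree_codes[i]),
                     term_key("ncit", paste0("C", i)),
                     "cross_reference", "oncotree")
  }

  # --- drug concepts across two sources with planted overlap -----------
  drug_terms <- list()   # concept -> data.table(key, name, source, cluster)
  for (i in seq_len(sz$n_drugs)) {
    base <- sprintf("drug%02d", i)
    in_db <- runif(1) < sz$p_drugbank
    linked <- in_db && runif(1) < sz$xref_rate
    has_alias <- runif(1) < sz$alias_rate
    g <- kb_add_term(g, "ncit", sprintf("D%03d", i), base, termClass = "therapy")
    k_ncit <- attr(g, "key")
    rows <- as.data.table(list(
      key = k_ncit, name = base, source = "ncit",
      cluster = if (linked) base else paste0(base, "@ncit")))
    if (in_db) {
      g <- kb_add_term(g, "drugbank", sprintf("DB%03d", i),
                       paste(base, "mesylate"), termClass = "therapy")
      k_db <- attr(g, "key")
      if (linked) g <- kb_add_edge(g, k_ncit, k_db, "cross_reference", "ncit")
      rows <- rbind(rows, as.data.table(list(
        key = k_db, name = paste(base, "mesylate"), source = "drugbank",
        cluster = if (linked) base else paste0(base, "@drugbank"))))
    }
    if (has_alias) {
      g <- kb_add_term(g, "ncit", sprintf("D%03dA", i), paste(base, "alias"),
                       termClass = "therapy", isAlias = TRUE)
      k_al <- attr(g, "key")
      g <- kb_add_edge(g, k_al, k_ncit, "alias_of", "ncit")
      rows <- rbind(rows, as.data.table(list(
        key = k_al, name = paste(base, "alias"), source = "ncit",
        cluster = rows$cluster[1L])))
    }
    drug_terms[[i]] <- rows
  }
  drug_tab <- rbindlist(drug_terms)

  # --- statements with one unique gene per statement -------------------
  genes <- sprintf("G%03d", seq_len(sz$n_statements + 2L * sz$n_shared_pairs +
                                      sz$n_second_pass))
  for (i in seq_along(genes))
    g <- kb_add_term(g, "hgnc", sprintf("H%03d", i), genes[i],
                     termClass = "gene")
  gene_key <- function(nm) g$terms$key[g$terms$source == "hgnc" &
                                         g$terms$normName == normalize_label(nm)]

  stmt_truth <- list()  # planted per-statement facts
  kbs <- c("civic", "oncokb", "cosmic", "cgi", "docm")
  tier1_levels <- list(civic = "A", oncokb = sample(c("1", "R1", "2A")),
                       cgi = "FDA guidelines")
  weak_levels <- list(civic = "C", oncokb = "3A", cgi = "Early trials",
                      cosmic = NA, docm = NA)
  pick_drug <- function() {
    primaries <- drug_tab[!grepl("alias$", name)]
    primaries[sample(nrow(primaries), 1L)]
  }
  variant_kinds <- c("mut_specific", "mut_gene", "cnv", "exp", "fus")
  gi <- 0L
  stmt_rows <- list()

  make_cond <- function(kind, gene) {
    switch(kind,
      mut_specific = kb_condition("variant", gene = gene,
                                  variantClass = "missense mutation",
                                  proteinChange = sprintf("p.G%dD",
                                                          sample(10:900, 1))),
      mut_gene = kb_condition("variant", gene = gene,
                              variantClass = "mutation"),
      cnv = kb_condition("variant", gene = gene,
                         variantClass = sample(c("deep deletion",
                                                 "amplification"), 1L)),
      exp = kb_condition("variant", gene = gene,
                         variantClass = sample(c("increased expression",
                                                 "reduced expression"), 1L)),
      fus = kb_condition("variant", gene = gene, variantClass = "fusion"))
  }

  add_stmt <- function(id, kind, relevance_nm, subject_key, source_kb,
                       tier1, cond = NULL, extra_conds = list(), via = NA) {
    gi <<- gi + 1L
    gene <- genes[gi]
    if (is.null(cond)) cond <- make_cond(kind, gene)
    lv <- if (tier1) tier1_levels[[source_kb]][1L] else weak_levels[[source_kb]]
    ev_item <- list(citationId = sprintf("PMID:%06d", sample(1e5, 1L)))
    if (!is.na(lv)) {
      ev_item$levelSource <- source_kb
      ev_item$levelLabel <- lv
    }
    ev <- list(ev_item)
    g <<- kb_add_statement(g, id, c(list(cond), extra_conds),
                           subject_key, rel_key(relevance_nm), ev, source_kb)
    stmt_rows[[length(stmt_rows) + 1L]] <<- data.table(
      statementId = id, kind = kind, gene = gene,
      proteinChange = cond$proteinChange %||% NA_character_,
      variantClass = cond$variantClass,
      relevance = relevance_nm,
      category = RELEVANCE_VOCAB$category[RELEVANCE_VOCAB$name == relevance_nm],
      subjectKey = subject_key, sourceKb = source_kb, tier1 = tier1,
      hasDisease = length(extra_conds) > 0L,
      diseaseKey = if (length(extra_conds)) extra_conds[[1L]]$termKey
                   else NA_character_,
      consequentOf = via)
    invisible(NULL)
  }

  # ordinary statements
  n_ord <- sz$n_statements - 2L * sz$n_second_pass
  if (n_ord < 0) om_stop("n_statements too small for n_second_pass", "config")
  for (j in seq_len(n_ord)) {
    kind <- variant_kinds[1L + (j - 1L) %% length(variant_kinds)]
    relevance_nm <- sample(c("sensitivity", "resistance",
                             "diagnostic indicator", "favourable prognosis",
                             "unfavourable prognosis"), 1L,
                           prob = c(.35, .25, .15, .15, .10))
    category <- RELEVANCE_VOCAB$category[RELEVANCE_VOCAB$name == relevance_nm]
    d <- pick_drug()
    subject_key <- if (category == "therapeutic") d$key
                   else term_key("ncit", paste0("C", sample(sz$n_diseases, 1L)))
    source_kb <- sample(kbs, 1L)
    tier1 <- source_kb %in% names(tier1_levels) && runif(1) < sz$p_tier1
    extra <- list()
    if (category == "therapeutic" && runif(1) < sz$p_disease_cond)
      extra <- list(kb_condition(
        "term", termKey = term_key("ncit", paste0("C", sample(sz$n_diseases, 1L)))))
    add_stmt(sprintf("S%03d", j), kind, relevance_nm, subject_key, source_kb,
             tier1, extra_conds = extra)
  }

  # second-pass pairs: functional statement + consequent on its category
  for (p in seq_len(sz$n_second_pass)) {
    id1 <- sprintf("S%03d", n_ord + 2L * p - 1L)
    id2 <- sprintf("S%03d", n_ord + 2L * p)
    gene <- genes[gi + 1L]
    add_stmt(id1, "mut_specific", "oncogenic", gene_key(gene), "civic",
             tier1 = FALSE)
    d <- pick_drug()
    cond2 <- kb_condition("variant", gene = gene, variantClass = "oncogenic")
    source_kb2 <- sample(c("civic", "oncokb", "cgi"), 1L)
    tier12 <- runif(1) < sz$p_tier1
    # consequent uses its own slot in the gene list but matches via `gene`
    add_stmt(id2, "consequent", "resistance", d$key, source_kb2, tier12,
             cond = cond2)
    set(stmt_rows[[length(stmt_rows)]], j = "gene", value = gene)
    set(stmt_rows[[length(stmt_rows)]], j = "consequentOf", value = id1)
  }

  # deliberately shared cross-source conclusions (raw-distinct, link-merged)
  linked_concepts <- unique(drug_tab[!grepl("@", cluster) &
                                       !grepl("alias$", name)]$cluster)
  for (p in seq_len(sz$n_shared_pairs)) {
    concept <- linked_concepts[1L + (p - 1L) %% length(linked_concepts)]
    pair <- drug_tab[cluster == concept & !grepl("alias$", name)]
    k1 <- pair$key[pair$source == "ncit"][1L]
    k2 <- if (any(pair$source == "drugbank"))
      pair$key[pair$source == "drugbank"][1L] else k1
    add_stmt(sprintf("SH%02da", p), "mut_specific", "sensitivity", k1,
             "civic", tier1 = TRUE)
    add_stmt(sprintf("SH%02db", p), "cnv", "sensitivity", k2,
             "oncokb", tier1 = FALSE)
  }

  stmt_tab <- rbindlist(stmt_rows)

  # --- cohort with planted variants ------------------------------------
  samples <- sprintf("SAMP%03d", seq_len(sz$n_samples))
  diagnoses <- data.table(
    sample = samples,
    oncotreeCode = oncotree_codes[sample(sz$n_diseases, sz$n_samples,
                                         replace = TRUE)])
  diagnoses[, detailedType := disease_names[match(oncotreeCode, oncotree_codes)]]
  diagnoses[, cancerType := "cancer"]

  matchable <- stmt_tab[kind != "consequent"]
  plant <- list()
  for (i in seq_len(nrow(matchable))) {
    st <- matchable[i]
    planted_in <- if (st$kind == "exp") sample(samples, 1L)
                  else samples[runif(sz$n_samples) < sz$p_plant]
    for (s in planted_in)
      plant[[length(plant) + 1L]] <- data.table(sample = s, statementId =
                                                  st$statementId)
  }
  plant <- if (length(plant)) rbindlist(plant)
           else data.table(sample = character(), statementId = character())
  plant <- merge(plant, matchable, by = "statementId")

  noise_genes <- sprintf("N%03d", seq_len(sz$n_noise_genes))

  # MAF
  maf_rows <- list()
  for (i in seq_len(nrow(plant))) {
    p <- plant[i]
    if (!p$kind %in% c("mut_specific", "mut_gene")) next
    if (p$kind == "mut_specific") {
      maf_rows[[length(maf_rows) + 1L]] <- data.table(
        Hugo_Symbol = p$gene, HGVSp_Short = p$proteinChange,
        Variant_Classification = "Missense_Mutation",
        Tumor_Sample_Barcode = p$sample)
    } else {
      synon <- runif(1) < 0.25
      maf_rows[[length(maf_rows) + 1L]] <- data.table(
        Hugo_Symbol = p$gene,
        HGVSp_Short = sprintf("p.%s%d%s", sample(LETTERS, 1), sample(999, 1),
                              if (synon) "=" else sample(LETTERS, 1)),
        Variant_Classification = if (synon) "Silent" else "Missense_Mutation",
        Tumor_Sample_Barcode = p$sample)
    }
  }
  # noise rows on genes unknown to the knowledge base + intergenic rows
  for (j in seq_len(sz$n_noise_genes)) {
    maf_rows[[length(maf_rows) + 1L]] <- data.table(
      Hugo_Symbol = noise_genes[j],
      HGVSp_Short = sprintf("p.A%dV", sample(999, 1)),
      Variant_Classification = "Missense_Mutation",
      Tumor_Sample_Barcode = sample(samples, 1L))
  }
  maf_rows[[length(maf_rows) + 1L]] <- data.table(
    Hugo_Symbol = "", HGVSp_Short = "", Variant_Classification = "IGR",
    Tumor_Sample_Barcode = samples[1L])
  maf <- rbindlist(maf_rows)

  # copy-number matrix: planted calls on statement genes, noise elsewhere
  cnv_stmts <- matchable[kind == "cnv"]
  cna_genes <- c(cnv_stmts$gene, noise_genes)
  cna <- matrix(0L, nrow = length(cna_genes), ncol = sz$n_samples,
                dimnames = list(cna_genes, samples))
  for (i in which(plant$kind == "cnv")) {
    p <- plant[i]
    cna[p$gene, p$sample] <- if (p$variantClass == "deep deletion") -2L else 2L
  }
  for (ng in noise_genes)
    cna[ng, ] <- sample(c(-2L, -1L, 0L, 1L, 2L), sz$n_samples, replace = TRUE)

  # expression matrix: background inside (-1.5, 1.5), one planted outlier
  exp_stmts <- matchable[kind == "exp"]
  exp_genes <- c(exp_stmts$gene, noise_genes)
  zmat <- matrix(pmin(pmax(rnorm(length(exp_genes) * sz$n_samples, 0, 0.7),
                           -1.5), 1.5),
                 nrow = length(exp_genes), dimnames = list(exp_genes, samples))
  for (i in which(plant$kind == "exp")) {
    p <- plant[i]
    zmat[p$gene, p$sample] <- if (p$variantClass == "increased expression") 4
                              else -4
  }

  # fusions
  fus_rows <- list()
  for (i in which(plant$kind == "fus")) {
    p <- plant[i]
    fus_rows[[length(fus_rows) + 1L]] <- data.table(
      Hugo_Symbol = p$gene, Fusion = sample(noise_genes, 1L),
      Tumor_Sample_Barcode = p$sample)
  }
  fusions <- if (length(fus_rows)) rbindlist(fus_rows)
             else data.table(Hugo_Symbol = character(), Fusion = character(),
                             Tumor_Sample_Barcode = character())

  # --- registry records with a controlled frequency spectrum ------------
  therapy_pool <- data.table(
    term = unique(drug_tab$name), inset = TRUE)
  therapy_pool <- rbind(therapy_pool, data.table(
    term = sprintf("exoticdrug%02d", seq_len(10)), inset = FALSE))
  disease_pool <- data.table(term = disease_names, inset = TRUE)
  disease_pool <- rbind(disease_pool, data.table(
    term = sprintf("rarecondition%02d", seq_len(6)), inset = FALSE))
  freq_levels <- c(1L, 2L, 5L, 20L, 120L)
  therapy_pool[, freq := sample(freq_levels, .N, replace = TRUE,
                                prob = c(.35, .25, .2, .15, .05))]
  disease_pool[, freq := sample(freq_levels, .N, replace = TRUE,
                                prob = c(.35, .25, .2, .15, .05))]
  stopifnot(sz$n_trials >= max(freq_levels))
  trial_ids <- sprintf("NCT%07d", seq_len(sz$n_trials))
  trials <- setNames(lapply(trial_ids, function(id)
    list(trialId = id, conditions = list(), interventions = list())),
    trial_ids)
  assign_term <- function(tab, field) {
    for (i in seq_len(nrow(tab))) {
      use <- sample(trial_ids, tab$freq[i])
      for (id in use) {
        if (field == "conditions")
          trials[[id]]$conditions <<- c(trials[[id]]$conditions, tab$term[i])
        else
          trials[[id]]$interventions <<- c(
            trials[[id]]$interventions,
            list(list(name = tab$term[i], type = sample(
              c("Drug", "Radiation", "Combination Product",
                "Dietary Supplement"), 1L))))
      }
    }
  }
  assign_term(disease_pool, "conditions")
  assign_term(therapy_pool, "interventions")
  # excluded intervention types must not surface as therapy terms
  for (id in sample(trial_ids, min(10L, sz$n_trials)))
    trials[[id]]$interventions <- c(
      trials[[id]]$interventions,
      list(list(name = sprintf("behavioural%02d", sample(5L, 1L)),
                type = "Behavioral")))
  registry_records <- unname(trials)

  # --- planted truths ----------------------------------------------------
  direct_expected <- plant[, .(sample, statementId, pathKind = "direct",
                               viaStatement = NA_character_,
                               nonSpecific = kind == "mut_gene")]
  consequents <- stmt_tab[kind == "consequent",
                          .(viaStatement = consequentOf,
                            statementId = statementId)]
  second_expected <- merge(
    plant[statementId %in% consequents$viaStatement,
          .(sample, viaStatement = statementId)],
    consequents, by = "viaStatement")[
      , .(sample, statementId, pathKind = "second_pass", viaStatement,
          nonSpecific = TRUE)]
  expected_matches <- rbind(direct_expected, second_expected)

  # conclusion truth over clinically informative statements
  info <- stmt_tab[category %in% c("therapeutic", "diagnostic", "prognostic")]
  subj_name <- g$terms$normName[match(info$subjectKey, g$terms$key)]
  subj_cluster <- drug_tab$cluster[match(info$subjectKey, drug_tab$key)]
  subj_cluster[is.na(subj_cluster)] <- info$subjectKey[is.na(subj_cluster)]
  info[, rawKey := paste(relevance, subj_name, sep = " -> ")]
  info[, normCluster := paste(relevance, subj_cluster, sep = " -> ")]
  conc_truth <- list(
    raw_unique = uniqueN(info$rawKey),
    normalized_unique = uniqueN(info$normCluster),
    raw_shared_fraction =
      info[, .(n = uniqueN(sourceKb)), by = rawKey][, mean(n > 1L)],
    normalized_shared_fraction =
      info[, .(n = uniqueN(sourceKb)), by = normCluster][, mean(n > 1L)])

  # breakdown truth: therapeutic direct matches only
  ther_ids <- stmt_tab$statementId[stmt_tab$category == "therapeutic"]
  bk <- plant[statementId %in% ther_ids,
              .(types = list(sort(unique(c(
                mut_specific = "mut", mut_gene = "mut", cnv = "cnv",
                exp = "exp", fus = "fus")[kind])))), by = sample]
  group_truth <- bk[, .(group = vapply(types, paste, character(1),
                                       collapse = "+"))][
                         , .(count = .N), by = group][order(-count, group)]

  # coverage truth by direct membership counting
  coverage_truth <- list()
  cov_sets <- list(
    ncit_primary = normalize_label(
      g$terms[source == "ncit" & termClass == "therapy" & !isAlias]$name),
    ncit_full = normalize_label(
      g$terms[source == "ncit" & termClass == "therapy"]$name),
    drugbank_primary = normalize_label(
      g$terms[source == "drugbank" & termClass == "therapy" & !isAlias]$name))
  for (nm in names(cov_sets)) {
    for (mf in c(1L, 10L, 100L)) {
      sel <- therapy_pool[freq >= mf]
      coverage_truth[[paste(nm, mf, sep = "_")]] <-
        if (nrow(sel) == 0L) 0 else mean(normalize_label(sel$term) %in%
                                           cov_sets[[nm]])
    }
  }

  manifest <- list(
    seed = seed, sizes = sz,
    n_terms = nrow(g$terms), n_edges = nrow(g$edges),
    n_statements = length(g$statements),
    per_source_terms = as.list(table(g$terms$source)),
    expected_matches = expected_matches,
    concordance = conc_truth,
    breakdown = group_truth,
    coverage = coverage_truth,
    registry_freq = rbind(therapy_pool[, .(term = normalize_label(term),
                                           class = "therapy",
                                           frequency = freq)],
                          disease_pool[, .(term = normalize_label(term),
                                           class = "disease",
                                           frequency = freq)]),
    maf_intergenic_rows = 1L)

  vs <- variant_set(
    small_mutations = parse_small_mutations(maf),
    copy = parse_copy_matrix(data.table(Hugo_Symbol = rownames(cna), cna)),
    expression = parse_expression_matrix(data.table(Hugo_Symbol = rownames(zmat),
                                                    as.data.table(zmat))),
    fusions = parse_fusions(fusions))

  out <- list(graph = g, variants = vs, diagnoses = diagnoses,
              registry_records = registry_records, manifest = manifest,
              raw = list(maf = maf, cna = cna, zmat = zmat, fusions = fusions))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_kb(g, dir)
    fwrite(maf, file.path(dir, "maf.tsv"), sep = "\t")
    fwrite(data.table(Hugo_Symbol = rownames(cna), cna),
           file.path(dir, "cna.tsv"), sep = "\t")
    fwrite(data.table(Hugo_Symbol = rownames(zmat), as.data.table(zmat)),
           file.path(dir, "expression.tsv"), sep = "\t")
    fwrite(fusions, file.path(dir, "fusions.tsv"), sep = "\t")
    fwrite(diagnoses, file.path(dir, "diagnoses.tsv"), sep = "\t")
    writeLines(vapply(registry_records, function(r)
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)),
      character(1)), file.path(dir, "registry.jsonl"))
    writeLines(as.character(jsonlite::toJSON(
      manifest, auto_unbox = TRUE, digits = NA, dataframe = "rows")),
      file.path(dir, "manifest.json"))
    return(invisible(out))
  }
  out
}
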