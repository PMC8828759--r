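# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's traversal/matching code paths: plain loops, recursive
# DFS over name-level adjacency, and a classic union-find.

nrm <- function(x) tolower(trimws(x))
strip_p <- function(x) sub("^p\\.", "", nrm(x))

# -- recursive DFS: does condClass cover obsClass over variant-class
#    alias (undirected) / generalizes (specific -> general) links? ----------
oracle_class_covers <- function(graph, condClass, obsClass) {
  nc <- nrm(condClass)
  vc <- graph$terms[graph$terms$termClass == "variant_class"]
  name_of <- setNames(vc$normName, vc$key)
  e <- graph$edges
  up <- list()
  add <- function(a, b) up[[a]] <<- unique(c(up[[a]], b))
  for (i in seq_len(nrow(e))) {
    f <- e$fromKey[i]; t <- e$toKey[i]
    if (!f %in% vc$key || !t %in% vc$key) next
    if (e$edgeType[i] == "generalizes") add(name_of[[f]], name_of[[t]])
    if (e$edgeType[i] == "alias_of") { add(name_of[[f]], name_of[[t]])
                                       add(name_of[[t]], name_of[[f]]) }
  }
  seen <- character(0)
  reach <- function(nm) {
    if (nm %in% seen) return(FALSE)
    seen <<- c(seen, nm)
    if (nm == nc) return(TRUE)
    any(vapply(up[[nm]] %||% character(0), reach, logical(1)))
  }
  reach(nrm(obsClass))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- exhaustive (variant, condition) predicate evaluation ------------------
oracle_condition_hits <- function(graph, cond, vs) {
  out <- list()
  add <- function(id, type, nonspec, nonsyn)
    out[[length(out) + 1L]] <<- list(variantId = id, type = type,
                                     nonSpecific = nonspec, nonSynon = nonsyn)
  sm <- vs$small_mutations
  for (i in seq_len(nrow(sm))) {
    if (nrm(sm$gene[i]) != nrm(cond$gene)) next
    nonsyn <- !is.na(sm$proteinChange[i]) && nzchar(sm$proteinChange[i]) &&
      !nrm(sm$classification[i]) %in% c("silent", "synonymous")
    if (!is.null(cond$proteinChange)) {
      if (!is.na(sm$proteinChange[i]) &&
          strip_p(sm$proteinChange[i]) == strip_p(cond$proteinChange))
        add(paste0("mut:", sm$gene[i], ":", sm$proteinChange[i]),
            "mut", FALSE, nonsyn)
    } else if (oracle_class_covers(graph, cond$variantClass, "mutation")) {
      add(paste0("mut:", sm$gene[i], ":",
                 ifelse(is.na(sm$proteinChange[i]), "gene",
                        sm$proteinChange[i])), "mut", TRUE, nonsyn)
    }
  }
  if (is.null(cond$proteinChange)) {
    cn <- vs$copy
    cls <- c(deep_deletion = "deep deletion", amplification = "amplification")
    for (i in seq_len(nrow(cn))) {
      if (cn$category[i] == "neutral") next
      if (nrm(cn$gene[i]) == nrm(cond$gene) &&
          oracle_class_covers(graph, cond$variantClass, cls[[cn$category[i]]]))
        add(paste0("cnv:", cn$gene[i], ":", cn$category[i]), "cnv", FALSE, NA)
    }
    ex <- vs$expression
    ecl <- c(increased = "increased expression", reduced = "reduced expression")
    for (i in seq_len(nrow(ex))) {
      if (ex$direction[i] == "none") next
      if (nrm(ex$gene[i]) == nrm(cond$gene) &&
          oracle_class_covers(graph, cond$variantClass, ecl[[ex$direction[i]]]))
        add(paste0("exp:", ex$gene[i], ":", ex$direction[i]), "exp", FALSE, NA)
    }
    fu <- vs$fusions
    if (oracle_class_covers(graph, cond$variantClass, "fusion")) {
      for (i in seq_len(nrow(fu))) {
        hit <- if (!is.null(cond$gene2))
          (nrm(fu$gene5[i]) == nrm(cond$gene) &&
             nrm(fu$gene3[i]) == nrm(cond$gene2)) ||
          (nrm(fu$gene5[i]) == nrm(cond$gene2) &&
             nrm(fu$gene3[i]) == nrm(cond$gene))
        else nrm(fu$gene5[i]) == nrm(cond$gene) ||
             nrm(fu$gene3[i]) == nrm(cond$gene)
        if (hit) add(paste0("fus:", fu$gene5[i], "::", fu$gene3[i]),
                     "fus", FALSE, NA)
      }
    }
  }
  unique(data.table::rbindlist(lapply(out, data.table::as.data.table)))
}

# Comparable signature of one match: statement/path/via/nonSpecific plus the
# sorted set of contributing variant ids.
match_signature <- function(statementId, pathKind, viaStatement, nonSpecific,
                            variantIds) {
  paste(statementId, pathKind, viaStatement, nonSpecific,
        paste(sort(unique(variantIds)), collapse = ";"), sep = "|")
}

oracle_match_sample <- function(graph, vs) {
  sigs <- character(0)
  direct <- list()
  for (stmt in graph$statements) {
    vconds <- Filter(function(cd) cd$kind == "variant", stmt$conditions)
    if (length(vconds) == 0L) next
    per <- lapply(vconds, oracle_condition_hits, graph = graph, vs = vs)
    if (any(vapply(per, nrow, integer(1)) == 0L)) next
    all_hits <- unique(data.table::rbindlist(per))
    direct[[stmt$statementId]] <- all_hits
    sigs <- c(sigs, match_signature(stmt$statementId, "direct", NA,
                                    any(all_hits$nonSpecific),
                                    all_hits$variantId))
  }
  # second pass: one hop from biological direct matches with gene/class subject
  for (sid in names(direct)) {
    s1 <- graph$statements[[sid]]
    if (s1$relevanceCategory != "biological") next
    subj <- graph$terms[match(s1$subject, graph$terms$key)]
    if (!subj$termClass %in% c("gene", "variant_class")) next
    rel <- graph$terms[match(s1$relevance, graph$terms$key)]
    rel_comp <- graph$terms$normName[
      oracle_component(graph, rel$key, c("alias_of", "cross_reference")) ==
        oracle_component(graph, graph$terms$key,
                         c("alias_of", "cross_reference"))]
    for (s2 in graph$statements) {
      if (s2$statementId == sid) next
      hit <- any(vapply(s2$conditions, function(cd)
        cd$kind == "variant" && is.null(cd$proteinChange) &&
          nrm(cd$variantClass) %in% rel_comp &&
          nrm(cd$gene) == subj$normName, logical(1)))
      if (hit)
        sigs <- c(sigs, match_signature(
          s2$statementId, "second_pass", sid,
          any(direct[[sid]]$type == "mut"), direct[[sid]]$variantId))
    }
  }
  sort(unique(sigs))
}

engine_match_signatures <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(unique(vapply(seq_len(nrow(m)), function(i)
    match_signature(m$statementId[i], m$pathKind[i], m$viaStatement[i],
                    m$nonSpecific[i], m$variants[[i]]$variantId),
    character(1))))
}

# -- classic union-find over term keys -------------------------------------
oracle_component <- function(graph, keys, edgeTypes) {
  all_keys <- graph$terms$key
  parent <- setNames(seq_along(all_keys), all_keys)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
                                                 i <- parent[i] }; i }
  e <- graph$edges[graph$edges$edgeType %in% edgeTypes]
  for (i in seq_len(nrow(e))) {
    a <- find(match(e$fromKey[i], all_keys))
    b <- find(match(e$toKey[i], all_keys))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(match(keys, all_keys), find, numeric(1))
  unname(roots)
}

# -- random unplanted fixtures for stress equality tests -------------------
# Gene/protein pools are small on purpose so conditions collide across
# statements and variants, exercising ambiguity the planted fixtures avoid.
random_kb <- function(seed, n_statements = 60, n_genes = 12, n_samples = 3,
                      n_variants = 40) {
  set.seed(seed)
  g <- kb_graph()
  rel <- data.frame(
    name = c("sensitivity", "resistance", "oncogenic", "diagnostic indicator"),
    cat = c("therapeutic", "therapeutic", "biological", "diagnostic"))
  for (i in seq_len(nrow(rel)))
    g <- kb_add_term(g, "vocab", paste0("R", i), rel$name[i],
                     termClass = "relevance_term", category = rel$cat[i])
  classes <- c("mutation", "missense mutation", "deep deletion",
               "amplification", "increased expression", "reduced expression",
               "fusion", "oncogenic", "copy variant")
  for (i in seq_along(classes))
    g <- kb_add_term(g, "vocab", paste0("V", i), classes[i],
                     termClass = "variant_class")
  vk <- function(nm) term_key("vocab", paste0("V", match(nm, classes)))
  g <- kb_add_edge(g, vk("missense mutation"), vk("mutation"), "generalizes")
  g <- kb_add_edge(g, vk("deep deletion"), vk("copy variant"), "generalizes")
  g <- kb_add_edge(g, vk("amplification"), vk("copy variant"), "generalizes")
  genes <- sprintf("G%02d", seq_len(n_genes))
  for (i in seq_along(genes))
    g <- kb_add_term(g, "hgnc", paste0("H", i), genes[i], termClass = "gene")
  for (i in 1:5)
    g <- kb_add_term(g, "ncit", paste0("D", i), paste0("drug", i),
                     termClass = "therapy")
  proteins <- sprintf("p.G%dD", c(12, 13, 600, 858))
  rel_key <- function(nm) term_key("vocab", paste0("R", match(nm, rel$name)))
  for (s in seq_len(n_statements)) {
    n_cond <- sample(1:2, 1, prob = c(.8, .2))
    conds <- lapply(seq_len(n_cond), function(j) {
      kind <- sample(c("mut_spec", "mut_gene", "cnv", "exp", "fus", "cat"), 1,
                     prob = c(.25, .2, .2, .15, .1, .1))
      gene <- sample(genes, 1)
      switch(kind,
        mut_spec = kb_condition("variant", gene = gene,
                                variantClass = "missense mutation",
                                proteinChange = sample(proteins, 1)),
        mut_gene = kb_condition("variant", gene = gene,
                                variantClass = "mutation"),
        cnv = kb_condition("variant", gene = gene,
                           variantClass = sample(c("deep deletion",
                                                   "amplification",
                                                   "copy variant"), 1)),
        exp = kb_condition("variant", gene = gene,
                           variantClass = sample(c("increased expression",
                                                   "reduced expression"), 1)),
        fus = kb_condition("variant", gene = gene, variantClass = "fusion",
                           gene2 = if (runif(1) < .4) sample(genes, 1)),
        cat = kb_condition("variant", gene = gene,
                           variantClass = "oncogenic"))
    })
    relev <- sample(rel$name, 1)
    subject <- if (relev == "oncogenic") term_key("hgnc", paste0("H", sample(n_genes, 1)))
               else term_key("ncit", paste0("D", sample(5, 1)))
    g <- kb_add_statement(
      g, sprintf("RS%03d", s), conds, subject, rel_key(relev),
      list(list(citationId = paste0("PMID:", s))), sample(c("civic", "oncokb"), 1))
  }
  vs_by_sample <- lapply(seq_len(n_samples), function(si) {
    sm <- data.table::data.table(
      sample = paste0("X", si),
      gene = sample(genes, n_variants, replace = TRUE),
      proteinChange = ifelse(runif(n_variants) < .2, NA_character_,
                             sample(proteins, n_variants, replace = TRUE)),
      classification = sample(c("Missense_Mutation", "Silent"), n_variants,
                              replace = TRUE, prob = c(.8, .2)))
    sm <- unique(sm, by = c("sample", "gene", "proteinChange"))
    cp <- data.table::data.table(
      sample = paste0("X", si), gene = genes,
      rawValue = sample(-3:3, n_genes, replace = TRUE))
    cp[, category := classify_copy_number(rawValue)]
    z <- round(stats::rnorm(n_genes, 0, 2), 2)
    pc <- round(stats::runif(n_genes, 0, 100), 1)
    exq <- data.table::data.table(
      sample = paste0("X", si), gene = genes, zScore = z, percentile = pc,
      direction = classify_expression(z, pc))
    fu <- data.table::data.table(
      sample = paste0("X", si),
      gene5 = sample(genes, 5, replace = TRUE),
      gene3 = sample(genes, 5, replace = TRUE))
    variant_set(small_mutations = sm, copy = cp, expression = exq,
                fusions = fu)
  })
  list(graph = g, samples = vs_by_sample)
}

# Random multi-source term graph for partition/round-trip tests.
random_term_graph <- function(seed, n_nodes = 80, n_edges = 100) {
  set.seed(seed)
  g <- kb_graph()
  sources <- c("ncit", "drugbank", "chembl")
  for (i in seq_len(n_nodes))
    g <- kb_add_term(g, sample(sources, 1), sprintf("T%04d", i),
                     sprintf("term %03d", sample(n_nodes, 1)),
                     termClass = sample(c("therapy", "disease"), 1))
  keys <- g$terms$key
  for (j in seq_len(n_edges)) {
    ab <- sample(keys, 2)
    ty <- sample(c("alias_of", "cross_reference", "subclass_of"), 1,
                 prob = c(.4, .4, .2))
    g <- kb_add_edge(g, ab[1], ab[2], ty, "x")
  }
  g
}
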