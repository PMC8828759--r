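# On-disk dialects: terms/edges as TSV, statements as JSON Lines, plus the
# bundle reader used by the CLI and the end-to-end tests.

term_ref_to_list <- function(graph, key) {
  t <- kb_get_term(graph, key)
  list(source = t$source, sourceId = t$sourceId,
       sourceIdVersion = t$sourceIdVersion)
}

list_to_term_key <- function(ref) {
  term_key(ref$source, ref$sourceId, ref$sourceIdVersion %||% "")
}

#' Write a knowledge graph to a directory
#'
#' Produces `terms.tsv` (source, sourceId, name, sourceIdVersion, termClass,
#' isAlias, category), `edges.tsv` (fromSource, fromId, toSource, toId,
#' edgeType, assertedBy) and `statements.jsonl` (one statement record per
#' line). The bundle round-trips through [read_kb()].
#'
#' @param graph a `kb_graph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  terms <- graph$terms[, .(source, sourceId, name, sourceIdVersion, termClass,
                           isAlias,
                           category = if ("category" %in% names(graph$terms))
                             category else NA_character_)]
  fwrite(terms, file.path(dir, "terms.tsv"), sep = "\t")
  ek <- graph$edges
  src <- function(k) graph$terms[match(k, key), .(source, sourceId)]
  edges <- data.table(
    fromSource = src(ek$fromKey)$source, fromId = src(ek$fromKey)$sourceId,
    toSource = src(ek$toKey)$source, toId = src(ek$toKey)$sourceId,
    edgeType = ek$edgeType, assertedBy = ek$assertedBy)
  fwrite(edges, file.path(dir, "edges.tsv"), sep = "\t")
  lines <- vapply(graph$statements, function(stmt) {
    rec <- list(
      statementId = stmt$statementId,
      conditions = lapply(stmt$conditions, function(cd) {
        if (cd$kind == "term")
          c(list(kind = "term"), term_ref_to_list(graph, cd$termKey))
        else Filter(Negate(is.null),
                    list(kind = "variant", gene = cd$gene, gene2 = cd$gene2,
                         variantClass = cd$variantClass,
                         proteinChange = cd$proteinChange))
      }),
      subject = term_ref_to_list(graph, stmt$subject),
      relevance = term_ref_to_list(graph, stmt$relevance),
      evidence = stmt$evidence,
      sourceKb = stmt$sourceKb)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, file.path(dir, "statements.jsonl"))
  invisible(dir)
}

#' Read a knowledge graph written by [write_kb()]
#'
#' Terms are loaded first, then edges (endpoints resolved by (source,
#' sourceId)), then statements; every record passes the same invariant checks
#' as incremental insertion. Malformed statement lines are skipped with a
#' warning naming the line number.
#'
#' @param dir directory holding `terms.tsv`, `edges.tsv`, `statements.jsonl`.
#' @return a `kb_graph`.
#' @export
read_kb <- function(dir) {
  g <- kb_graph()
  terms <- fread(file.path(dir, "terms.tsv"), sep = "\t",
                 colClasses = list(character = c("source", "sourceId", "name",
                                                 "sourceIdVersion", "termClass",
                                                 "category")),
                 na.strings = "")
  for (i in seq_len(nrow(terms))) {
    r <- terms[i]
    g <- kb_add_term(g, r$source, r$sourceId, r$name,
                     ifelse(is.na(r$sourceIdVersion), "", r$sourceIdVersion),
                     r$termClass, isTRUE(r$isAlias),
                     category = r$category)
  }
  key_of <- function(source, id) {
    hit <- g$terms$key[g$terms$source == source & g$terms$sourceId == id]
    if (length(hit) != 1L)
      om_stop(sprintf("edge endpoint (%s, %s) resolves to %d terms",
                      source, id, length(hit)), "referential")
    hit
  }
  edges <- fread(file.path(dir, "edges.tsv"), sep = "\t",
                 colClasses = "character", na.strings = NULL)
  for (i in seq_len(nrow(edges))) {
    r <- edges[i]
    g <- kb_add_edge(g, key_of(r$fromSource, r$fromId),
                     key_of(r$toSource, r$toId), r$edgeType,
                     ifelse(is.na(r$assertedBy), "", r$assertedBy))
  }
  lines <- readLines(file.path(dir, "statements.jsonl"), warn = FALSE)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) {
      warning(sprintf("statements.jsonl line %d: unparseable record skipped", i))
      next
    }
    conds <- lapply(rec$conditions, function(cd) {
      if (cd$kind == "term")
        kb_condition("term", termKey = list_to_term_key(cd))
      else kb_condition("variant", gene = cd$gene, gene2 = cd$gene2,
                        variantClass = cd$variantClass,
                        proteinChange = cd$proteinChange)
    })
    g <- kb_add_statement(g, rec$statementId, conds,
                          list_to_term_key(rec$subject),
                          list_to_term_key(rec$relevance),
                          rec$evidence, rec$sourceKb)
  }
  g
}

#' Read a diagnosis metadata table
#'
#' Tab-separated columns `sample`, `oncotreeCode`, `detailedType`,
#' `cancerType`.
#'
#' @param path file path.
#' @return data.table.
#' @export
read_diagnoses <- function(path) {
  tab <- fread(path, sep = "\t", colClasses = "character")
  req <- c("sample", "oncotreeCode", "detailedType", "cancerType")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    om_stop(sprintf("missing required column(s): %s",
                    paste(miss, collapse = ", ")), "format")
  tab
}

#' Load a full input bundle
#'
#' Reads the knowledge-base files plus whichever variant, diagnosis and
#' registry files are present, returning typed objects and per-stage counts.
#'
#' @param dir bundle directory (layout as produced by [generate_fixture()]).
#' @return list with `graph`, `variants` (a `variant_set`), `diagnoses`,
#'   `registry` (term-frequency table or `NULL`) and `counts`.
#' @export
read_inputs <- function(dir) {
  graph <- read_kb(dir)
  p <- function(f) file.path(dir, f)
  vs <- variant_set(
    small_mutations = if (file.exists(p("maf.tsv")))
      parse_small_mutations(p("maf.tsv")),
    copy = if (file.exists(p("cna.tsv"))) parse_copy_matrix(p("cna.tsv")),
    expression = if (file.exists(p("expression.tsv")))
      parse_expression_matrix(p("expression.tsv")),
    fusions = if (file.exists(p("fusions.tsv"))) parse_fusions(p("fusions.tsv")))
  diagnoses <- if (file.exists(p("diagnoses.tsv"))) read_diagnoses(p("diagnoses.tsv"))
  registry <- if (file.exists(p("registry.jsonl")))
    parse_trial_terms(p("registry.jsonl"))
  list(graph = graph, variants = vs, diagnoses = diagnoses,
       registry = registry,
       counts = list(
         terms = nrow(graph$terms), edges = nrow(graph$edges),
         statements = length(graph$statements),
         samples = length(variant_samples(vs)),
         maf_dropped = attr(vs$small_mutations, "dropped") %||% 0L))
}
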