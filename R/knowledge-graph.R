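# Graph knowledge base: ontology terms, inter-term edges, evidence statements.

#' @import data.table
#' @importFrom stats median setNames
#' @importFrom utils head modifyList
NULL

TERM_CLASSES <- c("disease", "therapy", "gene", "variant_class",
                  "evidence_level", "relevance_term", "signature")

EDGE_TYPES <- c("cross_reference", "subclass_of", "alias_of",
                "element_of", "generalizes")

RELEVANCE_CATEGORIES <- c("therapeutic", "diagnostic", "prognostic", "biological")

om_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("oncomatch_", class), "oncomatch_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Build the composite provenance key of a term
#'
#' Terms are uniquely identified by (source, sourceId, sourceIdVersion); the
#' version defaults to the empty string when absent and always participates in
#' key comparison.
#'
#' @param source character, originating ontology identifier.
#' @param sourceId character, identifier unique within the source.
#' @param sourceIdVersion character, optional identifier version ("" when absent).
#' @return character key.
#' @export
term_key <- function(source, sourceId, sourceIdVersion = "") {
  sourceIdVersion[is.na(sourceIdVersion)] <- ""
  paste(source, sourceId, sourceIdVersion, sep = "|")
}

#' Create an empty knowledge graph
#'
#' The graph stores provenance-stamped ontology terms, typed inter-term edges
#' and evidence statements, together with a normalized-name index and a
#' reverse index from condition terms to statements.
#'
#' @return an object of class `kb_graph`.
#' @export
kb_graph <- function() {
  structure(list(
    terms = as.data.table(list(
      source = character(), sourceId = character(), sourceIdVersion = character(),
      name = character(), normName = character(), termClass = character(),
      isAlias = logical(), key = character()
    )),
    edges = data.table(
      fromKey = character(), toKey = character(),
      edgeType = character(), assertedBy = character()
    ),
    statements = list(),     # statementId -> statement record
    cond_index = list()      # condition signature -> character vector of statementIds
  ), class = "kb_graph")
}

#' @export
print.kb_graph <- function(x, ...) {
  cat(sprintf("<kb_graph> %d terms (%d aliases), %d edges, %d statements\n",
              nrow(x$terms), sum(x$terms$isAlias), nrow(x$edges),
              length(x$statements)))
  invisible(x)
}

#' Add one ontology term to the graph
#'
#' @param graph a `kb_graph`.
#' @param source,sourceId,name,sourceIdVersion provenance fields; the
#'   (source, sourceId, sourceIdVersion) triple must be unique in the graph.
#' @param termClass one of `disease`, `therapy`, `gene`, `variant_class`,
#'   `evidence_level`, `relevance_term`, `signature`.
#' @param isAlias logical; `TRUE` marks a synonym/product-name record that must
#'   be tied to a primary term by an `alias_of` edge.
#' @param category for `relevance_term` records, the clinical category
#'   (`therapeutic`, `diagnostic`, `prognostic` or `biological`), assigned at
#'   load time.
#' @return the updated graph, invisibly carrying the new term's key as
#'   attribute `"key"`.
#' @export
kb_add_term <- function(graph, source, sourceId, name, sourceIdVersion = "",
                        termClass = "disease", isAlias = FALSE, category = NA_character_) {
  stopifnot(inherits(graph, "kb_graph"))
  if (is.na(sourceIdVersion)) sourceIdVersion <- ""
  if (!termClass %in% TERM_CLASSES)
    om_stop(sprintf("unknown term class '%s'", termClass), "invariant")
  nm <- normalize_label(name)
  if (!nzchar(nm))
    om_stop("term name is empty after whitespace trimming", "invariant")
  if (termClass == "relevance_term" && !is.na(category) &&
      !category %in% RELEVANCE_CATEGORIES)
    om_stop(sprintf("unknown relevance category '%s'", category), "invariant")
  key <- term_key(source, sourceId, sourceIdVersion)
  if (key %in% graph$terms$key)
    om_stop(sprintf("provenance collision: term (%s, %s, '%s') already present",
                    source, sourceId, sourceIdVersion), "collision")
  row <- as.data.table(list(source = source, sourceId = sourceId,
                            sourceIdVersion = sourceIdVersion, name = name,
                            normName = nm, termClass = termClass,
                            isAlias = isAlias, key = key))
  if (termClass == "relevance_term") row[, category := category]
  if (!"category" %in% names(graph$terms) && "category" %in% names(row))
    graph$terms[, category := NA_character_]
  if ("category" %in% names(graph$terms) && !"category" %in% names(row))
    row[, category := NA_character_]
  graph$terms <- rbind(graph$terms, row, fill = TRUE)
  attr(graph, "key") <- key
  invisible(graph)
}

#' Retrieve a term by provenance key
#'
#' @param graph a `kb_graph`.
#' @param key a key from [term_key()].
#' @return a one-row data.table.
#' @export
kb_get_term <- function(graph, key) {
  i <- match(key, graph$terms$key)
  if (is.na(i)) om_stop(sprintf("unknown term key '%s'", key), "referential")
  graph$terms[i]
}

#' Find terms by exact normalized name
#'
#' Matching is exact after [normalize_label()] (trim + lowercase); the full
#' ambiguity set is returned rather than an arbitrary member. An empty result
#' is an error condition (class `oncomatch_no_match`), mirroring strict
#' name-based import.
#'
#' @param graph a `kb_graph`.
#' @param query character, the name to look up.
#' @param termClass optional class restriction.
#' @return data.table of matching terms (>= 1 rows).
#' @export
kb_find_terms_by_name <- function(graph, query, termClass = NULL) {
  nm <- normalize_label(query)
  cls <- termClass
  hits <- graph$terms[graph$terms$normName == nm]
  if (!is.null(cls)) hits <- hits[which(hits$termClass %in% cls)]
  if (nrow(hits) == 0L)
    om_stop(sprintf("no exact match for name '%s'", query), "no_match")
  hits
}

#' Add a typed edge between two existing terms
#'
#' `alias_of` and `subclass_of` point child -> parent (alias -> primary);
#' `cross_reference` is stored directed but traversed as undirected.
#'
#' @param graph a `kb_graph`.
#' @param fromKey,toKey endpoint term keys; both must exist.
#' @param edgeType one of `cross_reference`, `subclass_of`, `alias_of`,
#'   `element_of`, `generalizes`.
#' @param assertedBy source identifier of the ontology defining the link.
#' @return the updated graph, invisibly.
#' @export
kb_add_edge <- function(graph, fromKey, toKey, edgeType, assertedBy = "") {
  stopifnot(inherits(graph, "kb_graph"))
  if (!edgeType %in% EDGE_TYPES)
    om_stop(sprintf("unknown edge type '%s'", edgeType), "invariant")
  if (!fromKey %in% graph$terms$key || !toKey %in% graph$terms$key)
    om_stop("edge endpoint does not exist in the graph", "referential")
  if (edgeType == "alias_of" && fromKey == toKey)
    om_stop("self-loop of type alias_of", "invariant")
  graph$edges <- rbind(graph$edges, data.table(
    fromKey = fromKey, toKey = toKey, edgeType = edgeType,
    assertedBy = assertedBy))
  invisible(graph)
}

# ---- statement conditions -----------------------------------------------

#' Construct a statement condition
#'
#' Conditions come in two shapes: a plain term condition (`kind = "term"`,
#' e.g. a disease restriction) referencing an existing graph term, and a
#' variant condition (`kind = "variant"`) describing the observation a sample
#' must carry: a gene plus a variant-class label, optionally a protein change
#' (position-specific small mutation) or a second gene (fusion partner).
#'
#' @param kind `"term"` or `"variant"`.
#' @param termKey for term conditions, the referenced term key.
#' @param gene,gene2 gene symbols for variant conditions.
#' @param variantClass variant-class label (e.g. `"mutation"`,
#'   `"amplification"`, or a functional category such as `"oncogenic"`).
#' @param proteinChange optional HGVS-style protein notation; absence means a
#'   gene-level (non-specific) condition.
#' @return a `kb_condition` list.
#' @export
kb_condition <- function(kind = c("term", "variant"), termKey = NULL,
                         gene = NULL, gene2 = NULL, variantClass = NULL,
                         proteinChange = NULL) {
  kind <- match.arg(kind)
  if (kind == "term" && is.null(termKey))
    om_stop("term condition requires termKey", "invariant")
  if (kind == "variant" && (is.null(gene) || is.null(variantClass)))
    om_stop("variant condition requires gene and variantClass", "invariant")
  structure(list(kind = kind, termKey = termKey, gene = gene, gene2 = gene2,
                 variantClass = variantClass, proteinChange = proteinChange),
            class = "kb_condition")
}

#' Add an evidence statement
#'
#' A statement links one or more conditions to exactly one subject and exactly
#' one relevance, backed by at least one evidence item. The reverse index from
#' condition terms to statements is maintained incrementally.
#'
#' @param graph a `kb_graph`.
#' @param statementId unique text identifier.
#' @param conditions list of [kb_condition()] objects, length >= 1.
#' @param subject term key of the single subject (e.g. a drug or disease).
#' @param relevance term key of the single relevance term; its category
#'   attribute fixes the statement's `relevanceCategory`.
#' @param evidence list of evidence items, each
#'   `list(citationId =, levelSource =, levelLabel =)`; length >= 1.
#' @param sourceKb identifier of the contributing knowledge base.
#' @return the updated graph, invisibly.
#' @export
kb_add_statement <- function(graph, statementId, conditions, subject,
                             relevance, evidence, sourceKb) {
  stopifnot(inherits(graph, "kb_graph"))
  if (statementId %in% names(graph$statements))
    om_stop(sprintf("duplicate statement id '%s'", statementId), "collision")
  if (length(conditions) < 1L)
    om_stop("statement must have at least one condition", "invariant")
  if (length(evidence) < 1L)
    om_stop("statement must have at least one evidence item", "invariant")
  for (ev in evidence)
    if (is.null(ev$citationId) || !nzchar(ev$citationId))
      om_stop("evidence item with empty citationId", "invariant")
  for (k in c(subject, relevance))
    if (!k %in% graph$terms$key)
      om_stop(sprintf("dangling term reference '%s'", k), "referential")
  rel <- kb_get_term(graph, relevance)
  if (rel$termClass != "relevance_term")
    om_stop("relevance must reference a relevance_term", "invariant")
  relevanceCategory <- rel$category
  if (is.null(relevanceCategory) || is.na(relevanceCategory))
    om_stop(sprintf("relevance term '%s' has no category attribute", rel$name),
            "invariant")
  conditions <- lapply(conditions, function(cond) {
    if (!inherits(cond, "kb_condition"))
      om_stop("conditions must be kb_condition objects", "invariant")
    if (cond$kind == "term" && !cond$termKey %in% graph$terms$key)
      om_stop(sprintf("dangling condition term '%s'", cond$termKey), "referential")
    cond
  })
  stmt <- list(statementId = statementId, conditions = conditions,
               subject = subject, relevance = relevance, evidence = evidence,
               sourceKb = sourceKb, relevanceCategory = relevanceCategory)
  graph$statements[[statementId]] <- stmt
  for (sig in vapply(conditions, condition_signature, character(1))) {
    graph$cond_index[[sig]] <- unique(c(graph$cond_index[[sig]], statementId))
  }
  invisible(graph)
}

condition_signature <- function(cond) {
  if (cond$kind == "term") paste0("term:", cond$termKey)
  else paste0("gene:", normalize_label(cond$gene))
}

#' Statements indexed under a condition term or gene
#'
#' Looks up the incrementally maintained reverse index: term conditions are
#' indexed by term key, variant conditions by gene symbol.
#'
#' @param graph a `kb_graph`.
#' @param termKey a term key, or `NULL` when querying by gene.
#' @param gene a gene symbol, or `NULL`.
#' @return character vector of statement ids (possibly empty).
#' @export
kb_statements_for_term <- function(graph, termKey = NULL, gene = NULL) {
  sig <- if (!is.null(termKey)) paste0("term:", termKey)
         else paste0("gene:", normalize_label(gene))
  out <- graph$cond_index[[sig]]
  if (is.null(out)) character(0) else out
}

#' Validate graph invariants
#'
#' Checks every structural invariant and returns violations as data (an empty
#' data.table iff the graph is consistent): duplicate provenance keys, empty
#' names, dangling edge endpoints, alias_of self-loops, alias terms not
#' connected to exactly one primary term, statements with dangling references,
#' and unknown edge types.
#'
#' @param graph a `kb_graph`.
#' @return data.table with columns `kind` and `detail`.
#' @export
kb_validate <- function(graph) {
  bad <- list()
  note <- function(kind, detail)
    bad[[length(bad) + 1L]] <<- data.table(kind = kind, detail = detail)

  dup <- graph$terms$key[duplicated(graph$terms$key)]
  for (k in unique(dup)) note("duplicate_key", k)
  for (k in graph$terms$key[!nzchar(graph$terms$normName)]) note("empty_name", k)

  known <- graph$terms$key
  if (nrow(graph$edges)) {
    e <- graph$edges
    for (i in which(!e$fromKey %in% known)) note("dangling_edge", e$fromKey[i])
    for (i in which(!e$toKey %in% known)) note("dangling_edge", e$toKey[i])
    for (i in which(!e$edgeType %in% EDGE_TYPES))
      note("bad_edge_type", e$edgeType[i])
    for (i in which(e$edgeType == "alias_of" & e$fromKey == e$toKey))
      note("alias_self_loop", e$fromKey[i])
  }
  alias_terms <- graph$terms$key[graph$terms$isAlias]
  if (length(alias_terms)) {
    ae <- graph$edges[graph$edges$edgeType == "alias_of"]
    n_out <- table(factor(ae$fromKey, levels = alias_terms))
    for (k in alias_terms[n_out[alias_terms] != 1L])
      note("alias_without_primary", k)
  }
  for (stmt in graph$statements) {
    refs <- c(stmt$subject, stmt$relevance,
              unlist(lapply(stmt$conditions,
                            function(cd) if (cd$kind == "term") cd$termKey)))
    for (k in refs[!refs %in% known])
      note(if (identical(k, stmt$subject) || identical(k, stmt$relevance))
             "dangling_statement_ref" else "dangling_condition_ref",
           paste(stmt$statementId, k, sep = ":"))
    if (length(stmt$conditions) < 1L) note("empty_conditions", stmt$statementId)
    if (length(stmt$evidence) < 1L) note("empty_evidence", stmt$statementId)
  }
  if (length(bad)) rbindlist(bad) else data.table(kind = character(),
                                                  detail = character())
}
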