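# Label normalization and reachability across semi-redundant ontologies.

#' Normalize a free-text label
#'
#' Strips leading/trailing whitespace and lowercases; deliberately nothing
#' else (no punctuation stripping, no stemming), so that coverage and name
#' matching remain exact-match comparisons.
#'
#' @param raw character vector.
#' @return character vector of the same length.
#' @export
normalize_label <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  tolower(trimws(raw))
}

# Adjacency rows for a traversal: undirected for cross_reference/alias_of,
# directional for the hierarchy-like types (subclass_of, generalizes,
# element_of), where "up" follows child -> parent only.
traversal_edges <- function(graph, edgeTypes, direction = "up") {
  e <- graph$edges[graph$edges$edgeType %in% edgeTypes]
  if (nrow(e) == 0L)
    return(data.table(fromKey = character(), toKey = character()))
  undirected_types <- c("cross_reference", "alias_of")
  hier <- e[!e$edgeType %in% undirected_types]
  undir <- e[e$edgeType %in% undirected_types]
  out <- list(undir[, .(fromKey, toKey)],
              undir[, .(fromKey = toKey, toKey = fromKey)])
  if (nrow(hier)) {
    if (direction %in% c("up", "both"))
      out <- c(out, list(hier[, .(fromKey, toKey)]))
    if (direction %in% c("down", "both"))
      out <- c(out, list(hier[, .(fromKey = toKey, toKey = fromKey)]))
  }
  unique(rbindlist(out))
}

#' Expand a seed set of terms over selected edge types
#'
#' Breadth-first reachability closure of the seeds. `cross_reference` and
#' `alias_of` edges are traversed as undirected; `subclass_of`, `generalizes`
#' and `element_of` are traversed child -> parent by default (`direction =
#' "up"`), or both ways. Cycles are tolerated (visited-set traversal). The
#' result is always a superset of the seeds.
#'
#' @param graph a `kb_graph`.
#' @param seeds character vector of term keys (may be empty).
#' @param edgeTypes subset of the edge-type vocabulary.
#' @param maxDepth optional non-negative integer truncation; `Inf` (default)
#'   means full closure.
#' @param direction `"up"`, `"down"` or `"both"` for the hierarchical types.
#' @return character vector of term keys.
#' @export
expand_terms <- function(graph, seeds, edgeTypes = EDGE_TYPES, maxDepth = Inf,
                         direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (length(seeds) == 0L) return(character(0))
  missing <- setdiff(seeds, graph$terms$key)
  if (length(missing))
    om_stop(sprintf("unknown seed term(s): %s", paste(missing, collapse = ", ")),
            "referential")
  adj <- traversal_edges(graph, edgeTypes, direction)
  visited <- unique(seeds)
  frontier <- visited
  depth <- 0L
  while (length(frontier) && depth < maxDepth) {
    nxt <- setdiff(adj$toKey[adj$fromKey %in% frontier], visited)
    visited <- c(visited, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }
  visited
}

#' Canonical representative of a term's connected component
#'
#' Terms connected by the selected edge types (treated as undirected for this
#' purpose) form one component; its representative is the member with the
#' lexicographically smallest (normalized name, source, sourceId) triple, a
#' deterministic tie-break stable across runs and platforms. All members of a
#' component map to the same representative.
#'
#' @param graph a `kb_graph`.
#' @param key term key.
#' @param edgeTypes edge types defining connectivity (default: alias and
#'   cross-reference links).
#' @return the representative's term key.
#' @export
canonical_representative <- function(graph, key,
                                     edgeTypes = c("alias_of", "cross_reference")) {
  comp <- expand_terms(graph, key, edgeTypes = edgeTypes, direction = "both")
  members <- graph$terms[graph$terms$key %in% comp]
  members <- members[order(normName, source, sourceId)]
  members$key[1L]
}

#' Expand a sample diagnosis into its disease-term closure
#'
#' Each non-empty input (OncoTree code, detailed cancer type, cancer type) is
#' resolved against disease terms by exact normalized match on either the term
#' name or its source identifier (OncoTree codes are identifiers, not display
#' names). Every resolved term is expanded over disease cross-reference,
#' alias and subclass links — ancestors and descendants both, so a biomarker
#' stated for a broader disease matches a subtype and vice versa — and the
#' union is returned.
#'
#' @param graph a `kb_graph`.
#' @param oncotreeCode,detailedType,cancerType diagnosis metadata strings
#'   (empty string or `NA` to skip).
#' @param direction subclass traversal direction; default `"both"`.
#' @return character vector of disease term keys.
#' @export
expand_diagnosis <- function(graph, oncotreeCode = "", detailedType = "",
                             cancerType = "", direction = "both") {
  inputs <- c(oncotreeCode, detailedType, cancerType)
  inputs <- inputs[!is.na(inputs) & nzchar(trimws(inputs))]
  if (length(inputs) == 0L)
    om_stop("at least one diagnosis input must be non-empty", "invariant")
  disease <- graph$terms[graph$terms$termClass == "disease"]
  seeds <- character(0)
  for (q in inputs) {
    nq <- normalize_label(q)
    hit <- disease$key[disease$normName == nq |
                         normalize_label(disease$sourceId) == nq]
    seeds <- c(seeds, hit)
  }
  seeds <- unique(seeds)
  if (length(seeds) == 0L)
    om_stop(sprintf("no exact match for diagnosis inputs: %s",
                    paste(inputs, collapse = " / ")), "no_match")
  expand_terms(graph, seeds,
               edgeTypes = c("cross_reference", "alias_of", "subclass_of"),
               direction = direction)
}
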