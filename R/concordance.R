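# Cross-source concordance of clinically informative conclusions, raw and
# after ontology normalization.

#' Extract per-source conclusions from statements
#'
#' A conclusion is the (relevance, subject) projection of a statement. Raw
#' keys compare normalized display names; normalized keys compare canonical
#' representatives of the relevance and subject terms, computed independently
#' over alias and cross-reference links ([canonical_representative()]).
#' `element_of` links (a drug inside a drug class) do not merge conclusions
#' unless requested — a drug and its class are distinct subjects.
#'
#' @param graph a `kb_graph`.
#' @param categories relevance categories retained; the default keeps the
#'   clinically informative three and drops `biological`.
#' @param mergeElementOf logical; also merge over `element_of` links.
#' @return data.table `sourceKb`, `statementId`, `rawKey`, `normKey`.
#' @export
extract_conclusions <- function(graph,
                                categories = c("therapeutic", "diagnostic",
                                               "prognostic"),
                                mergeElementOf = FALSE) {
  edgeTypes <- c("alias_of", "cross_reference")
  if (mergeElementOf) edgeTypes <- c(edgeTypes, "element_of")
  rows <- lapply(graph$statements, function(stmt) {
    if (!stmt$relevanceCategory %in% categories) return(NULL)
    rel <- kb_get_term(graph, stmt$relevance)
    sub <- kb_get_term(graph, stmt$subject)
    data.table(
      sourceKb = stmt$sourceKb, statementId = stmt$statementId,
      rawKey = paste(rel$normName, sub$normName, sep = " -> "),
      normKey = paste(
        canonical_representative(graph, stmt$relevance, edgeTypes),
        canonical_representative(graph, stmt$subject, edgeTypes),
        sep = " -> "))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) rbindlist(rows)
  else data.table(sourceKb = character(), statementId = character(),
                  rawKey = character(), normKey = character())
}

#' Summarize cross-source conclusion concordance
#'
#' For raw and normalized keys: the total number of unique conclusions, the
#' per-source unique contribution, and the fraction of unique conclusions
#' present in more than one source.
#'
#' @param conclusions output of [extract_conclusions()].
#' @return list with elements `raw` and `normalized`, each holding
#'   `total_unique`, `per_source` (named integer vector) and
#'   `shared_fraction`; plus `table`, a tidy per-source summary.
#' @export
concordance_summary <- function(conclusions) {
  one <- function(keycol) {
    per_src <- conclusions[, .(n_unique = uniqueN(get(keycol))), by = sourceKb]
    key_src <- unique(conclusions[, .(k = get(keycol), sourceKb)])
    n_sources <- key_src[, .(n = uniqueN(sourceKb)), by = k]
    total <- nrow(n_sources)
    shared <- if (total == 0L) 0 else sum(n_sources$n > 1L) / total
    list(total_unique = total,
         per_source = setNames(per_src$n_unique, per_src$sourceKb),
         shared_fraction = shared)
  }
  raw <- one("rawKey"); norm <- one("normKey")
  sources <- sort(unique(conclusions$sourceKb))
  tab <- data.table(
    source = c(sources, "all"),
    raw_unique = c(as.integer(raw$per_source[sources]), raw$total_unique),
    normalized_unique = c(as.integer(norm$per_source[sources]),
                          norm$total_unique),
    raw_shared_fraction = c(rep(NA_real_, length(sources)),
                            raw$shared_fraction),
    normalized_shared_fraction = c(rep(NA_real_, length(sources)),
                                   norm$shared_fraction))
  list(raw = raw, normalized = norm, table = tab)
}
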