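# Per-sample structured reports: knowledge-base match summary, conclusion
# counts, variant-type attribution.

VARIANT_TYPES <- c("mut", "cnv", "exp", "fus")

#' Summarize one sample's matches into a report
#'
#' `uniqueConclusions` counts distinct normalized (relevance, subject) pairs
#' among the matched statements; `therapeuticConclusions` restricts the count
#' to relevance category `therapeutic`. `variantTypeGroup` is the exact
#' subset of `{mut, cnv, exp, fus}` contributing at least one therapeutic
#' match; second-pass matches, which may bundle several variant types, are
#' excluded from that attribution by default. Per-match filter flags record
#' each match's pass/fail under every applicability filter.
#'
#' @param graph a `kb_graph`.
#' @param sampleId sample barcode.
#' @param vs the cohort (or single-sample) `variant_set`.
#' @param matches the sample's match table ([match_sample()]); computed from
#'   `vs` when `NULL`.
#' @param diagnosis list with `oncotreeCode`, `detailedType`, `cancerType`.
#' @param diagnosisTerms optional pre-expanded diagnosis closure for the
#'   diagnosis filter flag.
#' @param excludeSecondPassFromGroups logical, default `TRUE`.
#' @return a `sample_report` list.
#' @export
summarize_sample <- function(graph, sampleId, vs, matches = NULL,
                             diagnosis = list(oncotreeCode = "",
                                              detailedType = "",
                                              cancerType = ""),
                             diagnosisTerms = NULL,
                             excludeSecondPassFromGroups = TRUE) {
  svs <- subset_sample(vs, sampleId)
  if (is.null(matches)) matches <- match_sample(graph, svs)
  flags <- filter_flags(graph, matches, diagnosisTerms)

  stmt_ids <- unique(matches$statementId)
  conc <- if (length(stmt_ids)) {
    rbindlist(lapply(stmt_ids, function(sid) {
      stmt <- graph$statements[[sid]]
      as.data.table(list(
        key = paste(
          canonical_representative(graph, stmt$relevance),
          canonical_representative(graph, stmt$subject), sep = " -> "),
        category = stmt$relevanceCategory))
    }))
  } else as.data.table(list(key = character(), category = character()))

  therapeutic_ids <- stmt_ids[vapply(stmt_ids, function(sid)
    graph$statements[[sid]]$relevanceCategory == "therapeutic", logical(1))]
  attribution <- matches[matches$statementId %in% therapeutic_ids]
  if (excludeSecondPassFromGroups)
    attribution <- attribution[attribution$pathKind == "direct"]
  group <- as.character(sort(unique(unlist(attribution$variantTypes))))

  match_records <- lapply(seq_len(nrow(matches)), function(i) {
    stmt <- graph$statements[[matches$statementId[i]]]
    list(
      statementId = matches$statementId[i],
      pathKind = matches$pathKind[i],
      viaStatement = if (is.na(matches$viaStatement[i])) NULL
                     else matches$viaStatement[i],
      nonSpecific = matches$nonSpecific[i],
      variantIds = as.character(matches$variants[[i]]$variantId),
      variantTypes = as.character(matches$variantTypes[[i]]),
      relevance = kb_get_term(graph, stmt$relevance)$name,
      subject = kb_get_term(graph, stmt$subject)$name,
      relevanceCategory = stmt$relevanceCategory,
      sourceKb = stmt$sourceKb,
      filterFlags = as.list(flags[i])
    )
  })

  structure(list(
    sampleId = sampleId,
    diagnosis = list(
      oncotreeCode = diagnosis$oncotreeCode %||% "",
      detailedType = diagnosis$detailedType %||% "",
      cancerType = diagnosis$cancerType %||% ""),
    variantCounts = list(
      mut = nrow(svs$small_mutations),
      cnv = sum(svs$copy$category != "neutral"),
      exp = sum(svs$expression$direction != "none"),
      fus = nrow(svs$fusions)),
    uniqueConclusions = uniqueN(conc$key),
    therapeuticConclusions = uniqueN(conc$key[conc$category == "therapeutic"]),
    variantTypeGroup = group,
    matches = match_records
  ), class = "sample_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s: %d matches, %d unique conclusions (%d therapeutic), group {%s}\n",
              x$sampleId, length(x$matches), x$uniqueConclusions,
              x$therapeuticConclusions, paste(x$variantTypeGroup, collapse = ",")))
  invisible(x)
}

#' Cohort breakdown by contributing variant-type combination
#'
#' Each sample with at least one therapeutic match belongs to exactly one
#' group — the exact set of variant types contributing therapeutic matches —
#' so groups are mutually exclusive and their counts sum to the number of
#' samples with any therapeutic match. Marginal per-type totals (samples
#' where the type contributes, alone or in combination) are also reported.
#'
#' @param reports list of `sample_report` objects.
#' @return list with `groups` (data.table `group`, `count`) and `marginals`
#'   (named integer vector over `mut`, `cnv`, `exp`, `fus`).
#' @export
variant_type_breakdown <- function(reports) {
  if (length(reports) == 0L) om_stop("empty cohort", "input")
  groups <- vapply(reports, function(r)
    paste(r$variantTypeGroup, collapse = "+"), character(1))
  groups <- groups[nzchar(groups)]
  tab <- if (length(groups))
    as.data.table(table(group = groups))[, .(group, count = as.integer(N))]
  else data.table(group = character(), count = integer())
  marg <- vapply(VARIANT_TYPES, function(tp)
    sum(vapply(reports, function(r) tp %in% r$variantTypeGroup, logical(1))),
    integer(1))
  list(groups = tab[order(-count, group)], marginals = marg)
}

#' Serialize a sample report to JSON
#'
#' Field ordering is fixed by construction; the document round-trips
#' losslessly through [parse_report()].
#'
#' @param report a `sample_report`.
#' @return a JSON string (UTF-8).
#' @export
serialize_report <- function(report) {
  if (!inherits(report, "sample_report"))
    om_stop("not a sample_report", "serialization")
  req <- c("sampleId", "diagnosis", "variantCounts", "uniqueConclusions",
           "therapeuticConclusions", "variantTypeGroup", "matches")
  if (!identical(names(unclass(report)), req))
    om_stop("sample_report fields out of schema", "serialization")
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                null = "null", digits = NA))
}

#' Parse a serialized sample report
#'
#' @param json JSON string from [serialize_report()].
#' @return a `sample_report` equal to the original.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  chr <- function(v) if (length(v))
    vapply(v, as.character, character(1), USE.NAMES = FALSE) else character(0)
  x$uniqueConclusions <- as.integer(x$uniqueConclusions)
  x$therapeuticConclusions <- as.integer(x$therapeuticConclusions)
  x$variantCounts <- lapply(x$variantCounts, as.integer)
  x$variantTypeGroup <- chr(x$variantTypeGroup)
  x$matches <- lapply(x$matches, function(m) {
    m$variantIds <- chr(m$variantIds)
    m$variantTypes <- chr(m$variantTypes)
    m$filterFlags <- lapply(m$filterFlags, function(f)
      if (is.null(f)) NA else as.logical(f))
    m
  })
  structure(x, class = "sample_report")
}
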