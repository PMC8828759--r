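# Variant-to-statement matching (direct and second-pass) and the five
# therapeutic-applicability filters.

FILTER_NAMES <- c("amp_tier_i", "diagnosis_match", "position_specific",
                  "direct_match", "non_synon")

# Canonical empty match table.
empty_matches <- function() {
  data.table(statementId = character(), pathKind = character(),
             viaStatement = character(), nonSpecific = logical(),
             variants = list(), variantTypes = list())
}

# Protein-change comparison is normalized text equality after stripping an
# optional "p." prefix; no HGVS semantic parsing.
norm_protein <- function(x) sub("^p\\.", "", normalize_label(x))

# Does a condition's variant-class label cover an observed base class?
# TRUE on normalized name equality, or when the condition class is reachable
# from the observed class over variant-class alias/generalizes links
# (specific -> general).
class_covers <- function(graph, condClass, obsClass) {
  nc <- normalize_label(condClass)
  no <- normalize_label(obsClass)
  if (nc == no) return(TRUE)
  vc <- graph$terms[graph$terms$termClass == "variant_class"]
  obs_keys <- vc$key[vc$normName == no]
  if (length(obs_keys) == 0L) return(FALSE)
  closure <- expand_terms(graph, obs_keys,
                          edgeTypes = c("alias_of", "generalizes"),
                          direction = "up")
  nc %in% graph$terms$normName[match(closure, graph$terms$key)]
}

# Copy/expression categories -> observed variant-class names.
copy_class_name <- function(category)
  c(deep_deletion = "deep deletion", amplification = "amplification")[category]
expr_class_name <- function(direction)
  c(increased = "increased expression", reduced = "reduced expression")[direction]

# All sample variants satisfying one variant condition. Returns a data.table
# (variantId, type, nonSpecific, nonSynon) with zero rows when unsatisfied.
condition_hits <- function(graph, cond, vs) {
  hits <- list()
  sm <- vs$small_mutations
  if (nrow(sm)) {
    if (!is.null(cond$proteinChange)) {
      sel <- sm[normalize_label(gene) == normalize_label(cond$gene) &
                  !is.na(proteinChange) &
                  norm_protein(proteinChange) == norm_protein(cond$proteinChange)]
      if (nrow(sel))
        hits[[length(hits) + 1L]] <- data.table(
          variantId = paste0("mut:", sel$gene, ":", sel$proteinChange),
          type = "mut", nonSpecific = FALSE,
          nonSynon = is_nonsynonymous(sel$proteinChange, sel$classification))
    } else if (class_covers(graph, cond$variantClass, "mutation")) {
      sel <- sm[normalize_label(gene) == normalize_label(cond$gene)]
      if (nrow(sel))
        hits[[length(hits) + 1L]] <- data.table(
          variantId = paste0("mut:", sel$gene, ":",
                             ifelse(is.na(sel$proteinChange), "gene",
                                    sel$proteinChange)),
          type = "mut", nonSpecific = TRUE,
          nonSynon = is_nonsynonymous(sel$proteinChange, sel$classification))
    }
  }
  cn <- vs$copy[vs$copy$category != "neutral"]
  if (nrow(cn) && is.null(cond$proteinChange)) {
    keep <- normalize_label(cn$gene) == normalize_label(cond$gene) &
      vapply(copy_class_name(cn$category), function(oc)
        class_covers(graph, cond$variantClass, oc), logical(1))
    sel <- cn[keep]
    if (nrow(sel))
      hits[[length(hits) + 1L]] <- data.table(
        variantId = paste0("cnv:", sel$gene, ":", sel$category),
        type = "cnv", nonSpecific = FALSE, nonSynon = NA)
  }
  ex <- vs$expression[vs$expression$direction != "none"]
  if (nrow(ex) && is.null(cond$proteinChange)) {
    keep <- normalize_label(ex$gene) == normalize_label(cond$gene) &
      vapply(expr_class_name(ex$direction), function(oc)
        class_covers(graph, cond$variantClass, oc), logical(1))
    sel <- ex[keep]
    if (nrow(sel))
      hits[[length(hits) + 1L]] <- data.table(
        variantId = paste0("exp:", sel$gene, ":", sel$direction),
        type = "exp", nonSpecific = FALSE, nonSynon = NA)
  }
  fu <- vs$fusions
  if (nrow(fu) && is.null(cond$proteinChange) &&
      class_covers(graph, cond$variantClass, "fusion")) {
    g1 <- normalize_label(cond$gene)
    if (!is.null(cond$gene2)) {
      g2 <- normalize_label(cond$gene2)
      keep <- (normalize_label(fu$gene5) == g1 & normalize_label(fu$gene3) == g2) |
        (normalize_label(fu$gene5) == g2 & normalize_label(fu$gene3) == g1)
    } else {
      keep <- normalize_label(fu$gene5) == g1 | normalize_label(fu$gene3) == g1
    }
    sel <- fu[keep]
    if (nrow(sel))
      hits[[length(hits) + 1L]] <- data.table(
        variantId = paste0("fus:", sel$gene5, "::", sel$gene3),
        type = "fus", nonSpecific = FALSE, nonSynon = NA)
  }
  if (length(hits)) unique(rbindlist(hits))
  else data.table(variantId = character(), type = character(),
                  nonSpecific = logical(), nonSynon = logical())
}

#' Match one sample's variants directly against all statements
#'
#' A statement matches when every one of its variant-type conditions is
#' satisfied by at least one sample variant (co-occurrence within the
#' sample). Small mutations satisfy position-specific conditions by
#' (gene, normalized protein change) equality and gene-level conditions by
#' gene equality alone — the latter flags the match non-specific. Copy,
#' expression and fusion variants satisfy conditions on the matching gene
#' whose variant-class label covers the observed class (expanded over
#' variant-class alias/generalizes links). Non-variant conditions (e.g. a
#' disease restriction) do not block matching; they are evaluated by
#' [apply_filters()].
#'
#' @param graph a validated `kb_graph`.
#' @param vs a single-sample `variant_set`.
#' @return a match table: `statementId`, `pathKind` (`"direct"`),
#'   `viaStatement` (`NA`), `nonSpecific`, and list-columns `variants`
#'   (per-variant detail) and `variantTypes`.
#' @export
match_direct <- function(graph, vs) {
  out <- list()
  for (stmt in graph$statements) {
    vconds <- Filter(function(cd) cd$kind == "variant", stmt$conditions)
    if (length(vconds) == 0L) next
    per_cond <- lapply(vconds, condition_hits, graph = graph, vs = vs)
    if (any(vapply(per_cond, nrow, integer(1)) == 0L)) next
    all_hits <- unique(rbindlist(per_cond))
    out[[length(out) + 1L]] <- data.table(
      statementId = stmt$statementId, pathKind = "direct",
      viaStatement = NA_character_,
      nonSpecific = any(all_hits$nonSpecific),
      variants = list(all_hits[, .(variantId, type, nonSynon)]),
      variantTypes = list(sort(unique(all_hits$type))))
  }
  if (length(out)) rbindlist(out) else empty_matches()
}

#' Second-pass (inferred) matching
#'
#' For each direct match whose statement is a functional characterization
#' (relevance category `biological`) with a gene or variant-class subject,
#' statements conditioned on that (relevance, subject) characterization — a
#' variant condition whose class label names the relevance and whose gene is
#' the subject — are matched indirectly. Exactly one inference hop is taken;
#' second-pass matches never seed further passes.
#'
#' @param graph a `kb_graph`.
#' @param directMatches output of [match_direct()].
#' @return a match table with `pathKind = "second_pass"` and `viaStatement`
#'   set to the functional statement.
#' @export
match_second_pass <- function(graph, directMatches) {
  out <- list()
  if (nrow(directMatches) == 0L) return(empty_matches())
  for (i in seq_len(nrow(directMatches))) {
    s1 <- graph$statements[[directMatches$statementId[i]]]
    if (s1$relevanceCategory != "biological") next
    subj <- kb_get_term(graph, s1$subject)
    if (!subj$termClass %in% c("gene", "variant_class")) next
    rel <- kb_get_term(graph, s1$relevance)
    rel_names <- graph$terms$normName[match(
      expand_terms(graph, rel$key, edgeTypes = c("alias_of", "cross_reference"),
                   direction = "both"), graph$terms$key)]
    for (s2 in graph$statements) {
      if (s2$statementId == s1$statementId) next
      covers <- any(vapply(s2$conditions, function(cd) {
        cd$kind == "variant" && is.null(cd$proteinChange) &&
          normalize_label(cd$variantClass) %in% rel_names &&
          normalize_label(cd$gene) == subj$normName
      }, logical(1)))
      if (!covers) next
      vars <- directMatches$variants[[i]]
      out[[length(out) + 1L]] <- data.table(
        statementId = s2$statementId, pathKind = "second_pass",
        viaStatement = s1$statementId,
        nonSpecific = any(vars$type == "mut"),
        variants = list(vars),
        variantTypes = list(sort(unique(vars$type))))
    }
  }
  if (length(out) == 0L) return(empty_matches())
  res <- rbindlist(out)
  unique(res, by = c("statementId", "viaStatement"))
}

#' Match a sample and combine direct and second-pass results
#'
#' @param graph a `kb_graph`.
#' @param vs a single-sample `variant_set`.
#' @return combined match table.
#' @export
match_sample <- function(graph, vs) {
  direct <- match_direct(graph, vs)
  rbind(direct, match_second_pass(graph, direct))
}

AMP_TIER_I_MAP <- list(
  civic = "a",
  cgi = c("fda guidelines", "nccn guidelines", "cpic guidelines",
          "nccn/cap guidelines", "european leukemianet guidelines"),
  oncokb = c("1", "r1", "2a")
)

#' Map a source-specific evidence level to an AMP tier
#'
#' Tier I is assigned to exactly the enumerated (source, level) pairs:
#' CIViC level A; CGI FDA/NCCN/CPIC/NCCN-CAP/European LeukemiaNet guideline
#' levels; OncoKB 1, R1 and 2A. Sources without an evidence scheme (e.g.
#' COSMIC) are never Tier I.
#'
#' @param source knowledge-base source identifier (case-insensitive).
#' @param level evidence level label (case-insensitive).
#' @return `"tier_I"` or `"unassigned"` (vectorized).
#' @export
map_evidence_to_amp_tier <- function(source, level) {
  mapply(function(s, l) {
    lv <- AMP_TIER_I_MAP[[normalize_label(s)]]
    if (!is.null(lv) && normalize_label(l) %in% lv) "tier_I" else "unassigned"
  }, source, level, USE.NAMES = FALSE)
}

statement_is_tier1 <- function(stmt) {
  any(vapply(stmt$evidence, function(ev) {
    !is.null(ev$levelSource) && !is.null(ev$levelLabel) &&
      !is.na(ev$levelSource) && !is.na(ev$levelLabel) &&
      map_evidence_to_amp_tier(ev$levelSource, ev$levelLabel) == "tier_I"
  }, logical(1)))
}

# Per-match filter predicate; diagnosisTerms only needed for diagnosis_match.
match_passes_filter <- function(graph, match_row, filter, diagnosisTerms = NULL) {
  stmt <- graph$statements[[match_row$statementId]]
  switch(filter,
    amp_tier_i = statement_is_tier1(stmt),
    diagnosis_match = {
      disease_conds <- Filter(function(cd) {
        cd$kind == "term" &&
          kb_get_term(graph, cd$termKey)$termClass == "disease"
      }, stmt$conditions)
      if (length(disease_conds) == 0L) TRUE  # pan-cancer statements pass
      else any(vapply(disease_conds, function(cd) {
        closure <- expand_terms(
          graph, cd$termKey,
          edgeTypes = c("cross_reference", "alias_of", "subclass_of"),
          direction = "both")
        length(intersect(closure, diagnosisTerms)) > 0L
      }, logical(1)))
    },
    position_specific = !match_row$nonSpecific,
    direct_match = match_row$pathKind == "direct",
    non_synon = {
      v <- match_row$variants[[1L]]
      muts <- v[v$type == "mut"]
      nrow(muts) == 0L || all(muts$nonSynon)
    },
    om_stop(sprintf("unknown filter '%s'", filter), "config")
  )
}

#' Apply the five therapeutic-applicability filters
#'
#' Each filter is a subset-preserving predicate on matches; any selection is
#' applied as the intersection of the individual predicates, so composition
#' is idempotent and order-independent. Filters: `amp_tier_i` (at least one
#' Tier-I evidence item), `diagnosis_match` (a stated disease condition,
#' expanded over disease links, intersects the sample's diagnosis closure;
#' statements with no disease condition pass), `position_specific` (drop
#' matches driven by a non-specific small mutation), `direct_match` (drop
#' second-pass matches), `non_synon` (every small-mutation variant in the
#' match is non-synonymous at the protein level).
#'
#' @param graph a `kb_graph`.
#' @param matches a match table.
#' @param filters character vector of filter names (any subset of
#'   `amp_tier_i`, `diagnosis_match`, `position_specific`, `direct_match`,
#'   `non_synon`; case- and separator-insensitive).
#' @param diagnosisTerms disease-term closure from [expand_diagnosis()];
#'   required when `diagnosis_match` is selected.
#' @return the subset of `matches` passing every selected filter.
#' @export
apply_filters <- function(graph, matches, filters, diagnosisTerms = NULL) {
  filters <- gsub("[ -]", "_", tolower(filters))
  bad <- setdiff(filters, FILTER_NAMES)
  if (length(bad))
    om_stop(sprintf("unknown filter(s): %s", paste(bad, collapse = ", ")),
            "config")
  if ("diagnosis_match" %in% filters && is.null(diagnosisTerms))
    om_stop("diagnosis_match filter requires diagnosisTerms", "config")
  if (nrow(matches) == 0L || length(filters) == 0L) return(matches)
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    all(vapply(filters, function(f)
      match_passes_filter(graph, matches[i], f, diagnosisTerms), logical(1)))
  }, logical(1))
  matches[keep]
}

#' Per-match pass/fail flags for every filter
#'
#' @param graph a `kb_graph`.
#' @param matches a match table.
#' @param diagnosisTerms diagnosis closure (or `NULL` to skip the diagnosis
#'   flag, reported as `NA`).
#' @return data.table with one logical column per filter, rows parallel to
#'   `matches`.
#' @export
filter_flags <- function(graph, matches, diagnosisTerms = NULL) {
  flags <- lapply(FILTER_NAMES, function(f) {
    if (f == "diagnosis_match" && is.null(diagnosisTerms))
      return(rep(NA, nrow(matches)))
    vapply(seq_len(nrow(matches)), function(i)
      match_passes_filter(graph, matches[i], f, diagnosisTerms), logical(1))
  })
  setDT(setNames(flags, FILTER_NAMES))[]
}
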