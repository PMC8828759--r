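# Coverage of a frequency-weighted external terminology list (clinical-trial
# style) by ontology term sets.

#' Build a resource's term set
#'
#' The primary set contains the normalized names of the resource's non-alias
#' (preferred) terms; the full ("+") set additionally includes alias, synonym
#' and product names.
#'
#' @param graph a `kb_graph`.
#' @param resource source identifier of the ontology.
#' @param includeAliases logical; `TRUE` gives the full set.
#' @param termClass optional restriction (e.g. `"therapy"` or `"disease"`).
#' @return character vector of distinct normalized names.
#' @export
build_term_sets <- function(graph, resource, includeAliases = FALSE,
                            termClass = NULL) {
  t <- graph$terms[graph$terms$source == resource]
  if (nrow(t) == 0L)
    om_stop(sprintf("unknown resource '%s'", resource), "no_match")
  if (!is.null(termClass)) t <- t[t$termClass %in% termClass]
  if (!includeAliases) t <- t[!t$isAlias]
  unique(t$normName)
}

#' Parse registry-style trial records into term-frequency tables
#'
#' Records are consumed from a simplified structured format (JSON Lines, one
#' record per line with `trialId`, `conditions` and
#' `interventions[{name,type}]`). Therapy terms are normalized intervention
#' names whose type is in the drug-like inclusion list (Drug, Radiation,
#' Combination Product, Dietary Supplement); disease terms are normalized
#' condition names. Frequency is the number of distinct trials using a term.
#' Malformed records are skipped with a warning and counted.
#'
#' @param records a file path to JSON Lines, or a list of record lists.
#' @param drugTypes intervention types counted as therapies.
#' @return data.table `term`, `class` (`therapy`/`disease`), `frequency`;
#'   attribute `"skipped"` counts malformed records.
#' @export
parse_trial_terms <- function(records,
                              drugTypes = c("Drug", "Radiation",
                                            "Combination Product",
                                            "Dietary Supplement")) {
  if (is.character(records) && length(records) == 1L)
    records <- lapply(readLines(records, warn = FALSE),
                      jsonlite::fromJSON, simplifyVector = FALSE)
  drugTypes <- normalize_label(drugTypes)
  skipped <- 0L
  rows <- list()
  for (rec in records) {
    if (is.null(rec$trialId) || !nzchar(rec$trialId)) {
      warning("skipping registry record without trialId")
      skipped <- skipped + 1L
      next
    }
    for (cond in rec$conditions)
      rows[[length(rows) + 1L]] <- data.table(
        trial = rec$trialId, term = normalize_label(cond), class = "disease")
    for (iv in rec$interventions) {
      if (is.null(iv$name) || is.null(iv$type)) next
      if (normalize_label(iv$type) %in% drugTypes)
        rows[[length(rows) + 1L]] <- data.table(
          trial = rec$trialId, term = normalize_label(iv$name),
          class = "therapy")
    }
  }
  if (length(rows) == 0L) {
    out <- data.table(term = character(), class = character(),
                      frequency = integer())
  } else {
    long <- unique(rbindlist(rows))
    out <- long[, .(frequency = uniqueN(trial)), by = .(term, class)]
  }
  setattr(out, "skipped", skipped)
  out[]
}

#' Coverage of a frequency-filtered term list by a term set
#'
#' The fraction of terms used in at least `minFreq` trials whose normalized
#' name has an exact match in `termSet`; an empty filtered list has coverage
#' 0 by convention.
#'
#' @param termSet character vector of normalized ontology names.
#' @param freqTable data.table with columns `term` and `frequency` (already
#'   restricted to one term class).
#' @param minFreq minimum trial frequency (>= 1).
#' @return numeric fraction in \[0, 1\].
#' @export
compute_coverage <- function(termSet, freqTable, minFreq = 1L) {
  if (minFreq < 1L) om_stop("minFreq must be >= 1", "config")
  sel <- unique(freqTable$term[freqTable$frequency >= minFreq])
  if (length(sel) == 0L) return(0)
  mean(sel %in% termSet)
}

#' Coverage table across resources, classes and thresholds
#'
#' @param graph a `kb_graph`.
#' @param freqTable output of [parse_trial_terms()].
#' @param resources source identifiers to evaluate.
#' @param minFreqs frequency thresholds (default 1, 10, 100).
#' @param includeAliases logical vector of variants to evaluate (default both
#'   primary and full sets).
#' @return data.table `resource`, `aliases`, `class`, `minFreq`, `coverage`.
#' @export
coverage_table <- function(graph, freqTable, resources,
                           minFreqs = c(1L, 10L, 100L),
                           includeAliases = c(FALSE, TRUE)) {
  grid <- CJ(resource = resources, aliases = includeAliases,
             class = c("therapy", "disease"), minFreq = minFreqs)
  grid[, coverage := mapply(function(r, a, cl, mf) {
    ts <- build_term_sets(graph, r, includeAliases = a,
                          termClass = if (cl == "therapy") "therapy" else "disease")
    compute_coverage(ts, freqTable[freqTable$class == cl], mf)
  }, resource, aliases, class, minFreq)]
  grid[]
}
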