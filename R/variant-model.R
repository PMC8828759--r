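# Per-sample variant parsing and classification into the four matched types:
# small mutations, copy variants, expression outliers, fusions.

SYNONYMOUS_CLASSES <- c("Silent", "Synonymous")

#' Classify a discrete copy-number call
#'
#' GISTIC-like integer calls: a value of -2 or lower is a deep deletion and a
#' value of 2 or greater an amplification; everything strictly inside the open
#' interval is neutral. Boundaries are inclusive.
#'
#' @param rawValue numeric vector of discrete copy calls.
#' @param deletion,amplification thresholds (defaults -2 / +2).
#' @return character vector in `{deep_deletion, amplification, neutral}`.
#' @export
classify_copy_number <- function(rawValue, deletion = -2, amplification = 2) {
  if (any(!is.finite(rawValue)))
    om_stop("copy-number value must be finite", "input")
  ifelse(rawValue <= deletion, "deep_deletion",
         ifelse(rawValue >= amplification, "amplification", "neutral"))
}

#' Classify an expression observation as an outlier
#'
#' A threshold combination of z-score (-2, +2) and percentile (2.5, 97.5),
#' combined with AND (both must be extreme on the same side), flags increased
#' or reduced expression; boundaries are inclusive.
#'
#' @param zScore numeric vector of expression z-scores.
#' @param percentile numeric vector in \[0, 100\].
#' @param z_hi,z_lo,pct_hi,pct_lo thresholds.
#' @return character vector in `{increased, reduced, none}`.
#' @export
classify_expression <- function(zScore, percentile, z_hi = 2, z_lo = -2,
                                pct_hi = 97.5, pct_lo = 2.5) {
  if (any(!is.finite(percentile)) || any(percentile < 0 | percentile > 100))
    om_stop("percentile must be in [0, 100]", "input")
  ifelse(zScore >= z_hi & percentile >= pct_hi, "increased",
         ifelse(zScore <= z_lo & percentile <= pct_lo, "reduced", "none"))
}

#' Parse a MAF-like small-mutation table
#'
#' Expects tab-separated columns `Hugo_Symbol`, `HGVSp_Short`,
#' `Variant_Classification`, `Tumor_Sample_Barcode`. Rows without a gene
#' symbol (intergenic) are dropped; duplicate (sample, gene, proteinChange)
#' rows are collapsed before matching, since matching counts unique variants.
#'
#' @param path file path, or a data.frame already in the MAF dialect.
#' @return data.table with columns `sample`, `gene`, `proteinChange`
#'   (`NA` when absent, i.e. gene-level only), `classification`, plus
#'   attribute `"dropped"` giving the intergenic row count.
#' @export
parse_small_mutations <- function(path) {
  tab <- if (is.data.frame(path)) as.data.table(path)
         else fread(path, sep = "\t", colClasses = "character")
  req <- c("Hugo_Symbol", "HGVSp_Short", "Variant_Classification",
           "Tumor_Sample_Barcode")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    om_stop(sprintf("missing required column(s): %s",
                    paste(miss, collapse = ", ")), "format")
  n_in <- nrow(tab)
  tab <- tab[!is.na(Hugo_Symbol) & nzchar(trimws(Hugo_Symbol))]
  out <- tab[, .(sample = Tumor_Sample_Barcode, gene = Hugo_Symbol,
                 proteinChange = ifelse(
                   is.na(HGVSp_Short) | !nzchar(trimws(HGVSp_Short)),
                   NA_character_, HGVSp_Short),
                 classification = Variant_Classification)]
  out <- unique(out, by = c("sample", "gene", "proteinChange"))
  setattr(out, "dropped", n_in - nrow(tab))
  out[]
}

# Gene x sample matrix reader shared by the copy-number and expression dialects.
read_gene_matrix <- function(path) {
  tab <- if (is.data.frame(path)) as.data.table(path) else fread(path, sep = "\t")
  if (names(tab)[1L] != "Hugo_Symbol")
    om_stop("missing required column(s): Hugo_Symbol", "format")
  samples <- names(tab)[-1L]
  for (s in samples)
    if (!is.numeric(tab[[s]]))
      om_stop(sprintf("non-numeric matrix cell(s) in column '%s'", s), "format")
  melt(tab, id.vars = "Hugo_Symbol", variable.name = "sample",
       value.name = "value", variable.factor = FALSE)
}

#' Parse a gene x sample copy-number matrix
#'
#' @param path tab-separated file (first column `Hugo_Symbol`, one column per
#'   sample, integer calls) or an equivalent data.frame.
#' @return data.table `sample`, `gene`, `rawValue`, `category`; all cells are
#'   returned, classified — matching uses only the non-neutral ones.
#' @export
parse_copy_matrix <- function(path) {
  long <- read_gene_matrix(path)
  long[, .(sample, gene = Hugo_Symbol, rawValue = value,
           category = classify_copy_number(value))]
}

#' Parse a gene x sample expression z-score matrix
#'
#' Percentiles, when not supplied externally, are computed per gene across the
#' cohort samples as empirical ranks scaled to \[0, 100\].
#'
#' @param path tab-separated z-score matrix or data.frame.
#' @param percentiles optional long data.table (`sample`, `gene`,
#'   `percentile`) from an external compendium.
#' @return data.table `sample`, `gene`, `zScore`, `percentile`, `direction`.
#' @export
parse_expression_matrix <- function(path, percentiles = NULL) {
  long <- read_gene_matrix(path)
  setnames(long, c("Hugo_Symbol", "value"), c("gene", "zScore"))
  if (is.null(percentiles)) {
    long[, percentile := 100 * (frank(zScore, ties.method = "average") - 0.5) /
           .N, by = gene]
  } else {
    long <- merge(long, as.data.table(percentiles), by = c("sample", "gene"))
  }
  long[, direction := classify_expression(zScore, percentile)]
  long[, .(sample, gene, zScore, percentile, direction)]
}

#' Parse a fusion pair list
#'
#' Tab-separated columns `Hugo_Symbol` (5' gene), `Fusion` (partner gene
#' symbol), `Tumor_Sample_Barcode`.
#'
#' @param path file path or data.frame.
#' @return data.table `sample`, `gene5`, `gene3`.
#' @export
parse_fusions <- function(path) {
  tab <- if (is.data.frame(path)) as.data.table(path)
         else fread(path, sep = "\t", colClasses = "character")
  req <- c("Hugo_Symbol", "Fusion", "Tumor_Sample_Barcode")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    om_stop(sprintf("missing required column(s): %s",
                    paste(miss, collapse = ", ")), "format")
  tab <- tab[nzchar(trimws(Hugo_Symbol)) & nzchar(trimws(Fusion))]
  unique(tab[, .(sample = Tumor_Sample_Barcode, gene5 = Hugo_Symbol,
                 gene3 = Fusion)])
}

#' Is a small mutation non-synonymous at the protein level?
#'
#' True iff a protein change is stated and the classification is not in the
#' synonymous set. Gene-level records without a protein change are not
#' protein-level mutations and return `FALSE`.
#'
#' @param proteinChange character (possibly `NA`).
#' @param classification character classification label.
#' @param synonymous configurable synonymous label set.
#' @return logical vector.
#' @export
is_nonsynonymous <- function(proteinChange, classification,
                             synonymous = SYNONYMOUS_CLASSES) {
  !is.na(proteinChange) & nzchar(proteinChange) &
    !normalize_label(classification) %in% normalize_label(synonymous)
}

#' Bundle per-cohort variant tables
#'
#' @param small_mutations,copy,expression,fusions the parsed tables (any may
#'   be `NULL` for an absent data type).
#' @return a `variant_set` list with empty tables filled in.
#' @export
variant_set <- function(small_mutations = NULL, copy = NULL,
                        expression = NULL, fusions = NULL) {
  structure(list(
    small_mutations = if (is.null(small_mutations))
      data.table(sample = character(), gene = character(),
                 proteinChange = character(), classification = character())
      else small_mutations,
    copy = if (is.null(copy))
      data.table(sample = character(), gene = character(),
                 rawValue = numeric(), category = character())
      else copy,
    expression = if (is.null(expression))
      data.table(sample = character(), gene = character(), zScore = numeric(),
                 percentile = numeric(), direction = character())
      else expression,
    fusions = if (is.null(fusions))
      data.table(sample = character(), gene5 = character(), gene3 = character())
      else fusions
  ), class = "variant_set")
}

#' Restrict a variant bundle to one sample
#'
#' @param vs a `variant_set`.
#' @param sampleId sample barcode.
#' @return a `variant_set` for the single sample.
#' @export
subset_sample <- function(vs, sampleId) {
  variant_set(
    small_mutations = vs$small_mutations[vs$small_mutations$sample == sampleId],
    copy = vs$copy[vs$copy$sample == sampleId],
    expression = vs$expression[vs$expression$sample == sampleId],
    fusions = vs$fusions[vs$fusions$sample == sampleId]
  )
}

#' Sample barcodes present in a variant bundle
#' @param vs a `variant_set`.
#' @return character vector.
#' @export
variant_samples <- function(vs) {
  sort(unique(c(vs$small_mutations$sample, vs$copy$sample,
                vs$expression$sample, vs$fusions$sample)))
}
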