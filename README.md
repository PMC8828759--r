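# oncomatch

Somatic variant interpretation for precision oncology is, at its core, a
matching problem: a tumour's observed variants — small mutations, copy-number
calls, expression outliers and gene fusions — have to be related to curated
evidence statements spread across several knowledge bases, each speaking its
own semi-redundant vocabulary of drugs, diseases and variant classes.
`oncomatch` implements that interpretive core as an R package:

* a **graph knowledge base** of provenance-stamped ontology terms
  (`source`, `sourceId`, `name`, `sourceIdVersion`), typed edges
  (`cross_reference`, `subclass_of`, `alias_of`, `element_of`,
  `generalizes`) and evidence **statements**, each linking one or more
  conditions to exactly one subject and one relevance;
* **ontology traversal**: exact-match name normalization (trim + lowercase),
  reachability closures over selected edge types, deterministic canonical
  representatives of connected components, and diagnosis expansion from an
  OncoTree code / detailed cancer type / cancer type triple;
* a **variant model** for cBioportal-style inputs: MAF-like mutation tables,
  gene×sample copy matrices (deep deletion ≤ −2, amplification ≥ +2),
  expression z-score matrices (outlier iff z ≥ +2 ∧ percentile ≥ 97.5, or
  z ≤ −2 ∧ percentile ≤ 2.5), and fusion pair lists;
* a **matching engine** with direct matching (position-specific by
  gene + protein change, gene-level with a `nonSpecific` flag, class-aware
  copy/expression/fusion matching) and one-hop **second-pass** inference
  through functional characterizations ("oncogenic mutations in KRAS ⇒
  resistance to EGFR inhibition");
* the five **therapeutic-applicability filters** — AMP Tier I evidence
  (CIViC A; CGI guideline levels; OncoKB 1/R1/2A; no-scheme sources never
  Tier I), diagnosis match, position-specific, direct-only, non-synonymous —
  as order-independent, idempotent set predicates;
* cross-source **conclusion concordance** (a conclusion is the
  (relevance, subject) pair of a statement), raw and after ontology
  normalization, which can only merge: normalized unique ≤ raw unique;
* **coverage analysis** of a frequency-weighted registry-style terminology
  list by primary vs full ("+", including aliases) ontology term sets at
  trial-frequency thresholds 1+/10+/100+;
* per-sample structured **reports** (JSON, lossless round-trip) and a cohort
  breakdown of samples by the exact, mutually exclusive combination of
  variant types contributing therapeutic matches;
* a seeded **fixture generator** that stands in for licensed knowledge-base,
  TCGA and registry downloads, recording every planted truth in a manifest.

Real OncoKB/COSMIC/CGI dumps, web rendering and the wet-lab pipeline are out
of scope; all inputs are plain text and all fixtures are generated in code.

## Worked example

```r
library(oncomatch)

fx <- generate_fixture(42)        # seeded toy ontologies + KB + 20-sample cohort
fx$graph
#> <kb_graph> 157 terms (8 aliases), 31 edges, 68 statements

m <- match_sample(fx$graph, subset_sample(fx$variants, "SAMP004"))
m[, .(statementId, pathKind, nonSpecific)]
#>    statementId    pathKind nonSpecific
#> 1:        S011      direct       FALSE
#> ...
#> 8:        S056 second_pass        TRUE
```

`SAMP004` carries variants satisfying seven statements directly (two only at
gene level, hence `nonSpecific = TRUE`) and one more by second-pass
inference. Filters are plain set predicates:

```r
d   <- fx$diagnoses[sample == "SAMP004"]
dt  <- expand_diagnosis(fx$graph, d$oncotreeCode, d$detailedType, d$cancerType)
nrow(apply_filters(fx$graph, m, c("diagnosis_match", "direct_match"), dt))
#> [1] 7     # the second-pass match is dropped; all disease conditions fit
```

Summaries mirror the reporting tool's sections:

```r
summarize_sample(fx$graph, "SAMP004", fx$variants)
#> <sample_report> SAMP004: 8 matches, 8 unique conclusions (5 therapeutic),
#>                 group {cnv,exp,fus,mut}
```

i.e. after projecting matched statements to normalized (relevance, subject)
pairs this sample has 8 distinct conclusions, 5 of them therapeutic, with all
four variant types contributing at least one therapeutic match.

```r
concordance_summary(extract_conclusions(fx$graph))$table
#>    source raw_unique normalized_unique raw_shared_fraction normalized_shared_fraction
#> ...
#> 6:    all         45                40           0.3333333                       0.35
```

Ontology normalization merged 45 raw conclusions into 40 and raised the
fraction shared by more than one knowledge base from 0.33 to 0.35 — the
qualitative behaviour expected when sources state the same biomarker under
alias names.

```r
ft <- parse_trial_terms(fx$registry_records)
coverage_table(fx$graph, ft, "ncit", minFreqs = c(1L, 10L, 100L))[class == "therapy"]
#>    resource aliases   class minFreq  coverage
#> 1:     ncit   FALSE therapy       1 0.4761905
#> 4:     ncit    TRUE therapy       1 0.6031746
#> ...
```

Including aliases ("+" sets) can only raise coverage of the registry's
therapy terms — here from 0.48 to 0.60 at the 1+ threshold.

A command-line surface wraps the same calls
(`simulate`, `match`, `report`, `concordance`, `coverage`, `expand`):

```sh
Rscript inst/cli/oncomatch simulate --seed 42 --out bundle
Rscript inst/cli/oncomatch report --kb-dir bundle --out-dir bundle/reports
```

(use `system.file("cli/oncomatch", package = "oncomatch")` after install).

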