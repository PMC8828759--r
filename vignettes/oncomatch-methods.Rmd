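---
title: "Matching somatic variants to a graph knowledge base: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching somatic variants to a graph knowledge base}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomatch)
```

## The problem

Clinical interpretation of a tumour genome asks, for each observed variant,
what curated evidence exists about its therapeutic, diagnostic, prognostic or
biological significance. The evidence lives in several knowledge bases that
overlap in content but not in vocabulary: the same drug appears as a
preferred name in one ontology, a salt-form name in another and a trade name
as an alias; diseases are coded in OncoTree, NCIt or free text. `oncomatch`
models this as a labelled graph — terms with full provenance, typed edges,
and evidence statements — and treats interpretation as two graph problems:
*matching* (which statements does a sample satisfy?) and *normalization*
(which statements say the same thing?).

## The statement model

A statement has ≥ 1 conditions, exactly one subject, exactly one relevance
and ≥ 1 evidence items. Conditions are either term references (typically a
disease restriction) or variant descriptions (gene + variant-class label,
optionally a protein change or a fusion partner). The **conclusion** of a
statement is the (relevance, subject) pair alone — deliberately ignoring
conditions — which makes conclusions comparable across sources with
different condition granularity.

We read "any number of conditions" as ≥ 1: a statement with no conditions
can never be matched and is rejected at load time. Relevance terms carry an
explicit category (`therapeutic`/`diagnostic`/`prognostic`/`biological`)
assigned when the vocabulary is loaded, because the category partition is
used throughout (concordance keeps the first three; second-pass inference
keys on `biological`) but no canonical label→category table exists.

## Matching

**Direct matching** requires *every* variant-type condition of a statement to
be satisfied by at least one variant of the sample (co-occurrence within one
sample). Small mutations satisfy a position-specific condition by
(gene, protein change) equality — text equality after trimming, lowercasing
and stripping an optional `p.` prefix; there is deliberately no HGVS
semantic parsing — and a gene-level condition by gene equality alone, which
flags the match `nonSpecific`. Copy, expression and fusion variants satisfy
conditions whose class label *covers* the observed class, where coverage
walks variant-class `alias_of`/`generalizes` links from specific to general
(a missense mutation is a mutation; a deep deletion is a copy variant if the
vocabulary says so). Disease conditions never block matching; they are the
business of the diagnosis filter, so that a match and its disease
applicability remain separately reportable.

**Second-pass matching** takes exactly one inference hop: when a direct match
hits a functional statement (biological relevance, gene or variant-class
subject), statements conditioned on that characterization — a positionless
variant condition whose class names the relevance and whose gene is the
subject — are matched indirectly, recording the functional statement as
`viaStatement`. Chains are not followed; a statement that is matched both
directly and indirectly yields two match records, one per path kind, so the
direct-only filter is well defined. One open point in the contract is
whether a consequent statement's *other* variant conditions must also be
satisfied; we require only the functional condition to be covered by the
hop, matching the reading that the hop itself is the satisfying evidence.
The test oracle encodes the same rule, so this is a documented semantics,
not an accident.

For second-pass matches driven by a small mutation we set
`nonSpecific = TRUE`: the consequent condition states no protein position,
so the position-specific filter treats such matches exactly like gene-level
mutation matches.

## The five applicability filters

Each filter is a pure predicate on a match; selections are intersections,
hence subset-preserving, idempotent and order-independent (verified
exhaustively over all 32 combinations):

* **AMP Tier I** — at least one evidence item whose (source, level) is in the
  fixed map: CIViC A; CGI FDA/NCCN/CPIC/NCCN-CAP/European LeukemiaNet
  guideline levels; OncoKB 1, R1, 2A. Sources without an evidence scheme
  (e.g. COSMIC) never reach Tier I. Comparison is case-insensitive.
* **Diagnosis match** — the statement's disease condition, expanded over
  disease cross-reference/alias/subclass links, intersects the sample's
  diagnosis closure. Statements with no disease condition pass: a
  pan-cancer biomarker should not be dropped by a filter about stated
  diseases.
* **Position-specific** — drop `nonSpecific` matches.
* **Direct match** — drop second-pass matches.
* **Non-synonymous** — every small-mutation variant in the match has a
  protein change and a classification outside the configurable synonymous
  set (default `{Silent, Synonymous}`); matches without small mutations pass
  vacuously.

## Thresholds and units

Copy calls are GISTIC-like integers: deep deletion at ≤ −2, amplification at
≥ +2, both inclusive ("−2 or lower", "2 or greater"). Expression outliers
combine a z-score threshold (±2, dimensionless) with a percentile threshold
(2.5/97.5, percent) — the combination operator is not stated in the source
analysis, and we use AND on the same side, the stricter reading consistent
with "outlier" intent; boundaries are inclusive by analogy with the copy
rule. When percentiles are not supplied they are computed per gene across
the cohort as mid-rank percentiles, `100·(rank − ½)/n`; an external
compendium can be supplied instead. Label normalization is exactly trim +
lowercase — no punctuation stripping or stemming — so that term coverage
remains an exact-match statistic.

## Diagnosis expansion

The OncoTree code, detailed cancer type and cancer type are each resolved by
exact normalized match against disease term *names or source identifiers*
(codes are identifiers, not display names), then expanded and unioned. The
source analysis does not state whether expansion ascends or descends the
subclass hierarchy; we collect **both** ancestors and descendants by
default (`direction` is a parameter) — a biomarker stated for a broader
disease should apply to a subtype, and one stated for a subtype is at least
reportable for the broader diagnosis.

## Normalization and concordance

The canonical representative of a term is the member of its connected
component (under a chosen edge set, default alias + cross-reference) with
the lexicographically smallest (normalized name, source, sourceId) triple —
a deterministic, platform-independent tie-break. Conclusions are compared
raw (normalized display names) and normalized (canonical representatives of
relevance and subject independently). Because normalization can only merge
keys, normalized unique counts are bounded above by raw counts — an
invariant the tests assert on every fixture. `element_of` links (drug ∈
drug class) do **not** merge by default: a drug and its class are distinct
subjects; a flag enables merging for sensitivity analyses.

## What the generator emulates — and what it does not

`generate_fixture(seed, sizes)` is a pure function of its arguments and
emulates: multi-source drug ontologies with controlled alias (default rate
0.3) and cross-reference (0.5) overlap; an OncoTree-like disease axis
cross-referenced to an NCIt-like hierarchy; a knowledge base (default 68
statements) spanning all four variant types, all relevance categories,
gene-level and position-specific conditions, functional/consequent pairs for
second-pass, and deliberately shared cross-source conclusions; a cohort
(default 20 samples, per-statement planting probability 0.12) with
matrix-shaped copy/expression inputs and MAF/fusion tables including
intergenic and noise rows; and registry records with a fixed frequency
spectrum (1/2/5/20/120 trials) spanning in-ontology and out-of-ontology
terms plus excluded intervention types. Each statement owns a unique gene so
every planted match is attributable, and every planted truth (matches,
concordance counts, breakdown groups, coverages) is recorded in a manifest
at construction time, independent of the engine.

Two deliberate idealizations: planted expression outliers are unique extremes
(±4 against a background truncated to ±1.5), so a cohort of ≥ 20 samples
guarantees the planted cell clears the inclusive 97.5/2.5 percentile bound;
and noise variants use genes absent from the knowledge base. Real data have
ambiguous gene usage, borderline outliers and conflicting records — a green
parameter-recovery test therefore establishes correctness of the machinery
on a stated world, not robustness to messy inputs. Ambiguity *is* separately
stressed by the unplanted random fixtures (small gene/protein pools with
collisions) used in the oracle-equivalence tests.

## Numerical and degenerate-input choices

Coverage of an empty filtered term list is 0 by convention (0/0). Cycles in
cross-reference graphs are tolerated by visited-set traversal. Duplicate
(sample, gene, protein change) MAF rows are collapsed before matching, since
matching counts unique variants. Reports serialize with fixed field order;
`parse(serialize(r))` is exact, asserted on > 100 randomized instances.
Statement JSON lines that fail to parse are skipped with a line-numbered
warning rather than aborting a load.

## Known limitations

No HGVS semantics (p.G12D and p.Gly12Asp are different strings); no
wild-type/absence conditions; no fuzzy name matching; second-pass is exactly
one hop; the registry dialect is a simplified JSON-Lines mapping of
(trialId, conditions, typed interventions), not the full public XML; the
published headline quantities of the reference analysis are not reproduced
because they require licensed, dated external snapshots — concordance and
coverage here are property-checked at fixture scale instead.
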