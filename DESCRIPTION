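Package: oncomatch
Title: Graph Knowledge Base Matching and Reporting for Somatic Variants
Version: 0.1.0
Authors@R: person("BC", "Genomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An interpretive core for precision-oncology reporting: a graph
    knowledge base of provenance-stamped ontology terms and evidence
    statements; normalization and traversal across semi-redundant
    ontologies; parsing and classification of per-sample somatic variants
    (small mutations, copy number, expression outliers, fusions);
    direct and second-pass matching of variants to evidence statements;
    AMP/ASCO/CAP tier-I evidence mapping and the five therapeutic
    applicability filters; cross-source conclusion concordance before and
    after ontology normalization; ontology coverage of clinical-trial
    terminology; and structured per-sample reports. A seeded fixture
    generator stands in for licensed external knowledge bases and
    registries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
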