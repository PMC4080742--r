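Package: isovuln
Title: Sample-Specific Collateral-Lethality Vulnerabilities from Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sample-specific therapeutic vulnerabilities created by
    homozygous passenger deletions of metabolic isoenzymes. When one member of
    an isoenzyme gene set is homozygously deleted, the remaining intact
    partners become candidate drug targets that are selectively lethal to the
    deleted cells. The package builds isoenzyme gene-set catalogs from BioPAX
    Level 3 pathway exports, EC-number tables and GMT files; loads drug-target
    catalogs with FDA-approval and cancer-use annotations; consumes discrete
    gene-by-sample copy-number matrices (GISTIC/RAE codes) and expression
    matrices (Z-scores or log2 probe levels); calls and scores vulnerabilities
    per sample with a four-criterion 0-4 score; and aggregates cohort-level
    summaries (distinct deletion events, tumor/cell-line matching,
    druggability fractions). A deterministic synthetic-cohort generator with
    planted ground truth makes the whole pipeline testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
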