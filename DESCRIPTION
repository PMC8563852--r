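Package: toxscreen
Title: Non-Targeted Toxin Screening of Assigned Molecular Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens molecular formulas assigned from non-targeted LC/MS
    experiments for potentially toxic compounds. Assigned-formula tables are
    matched by exact elemental composition against a local table of candidate
    toxic compounds (OpenFoodTox/TPPT style), matched candidates are resolved
    to hierarchical compound records (local JSON store or a rate-limited live
    provider), records are scanned for toxicity and food-safety fields, GHS
    hazard-statement codes are extracted and each compound is classified into
    one of five severity-ordered categories, and per-sample results for both
    electrospray-ionization modes are merged into cross-sample screening
    reports. Includes seeded generators for synthetic assigned-formula
    samples, toxic tables and compound-record stores so the whole pipeline
    runs without network access.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
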