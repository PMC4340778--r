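Package: eavrecord
Title: Entity-Attribute-Value Storage Engine for Hierarchical Clinical Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic storage engine for integrating heterogeneous,
    hierarchical healthcare documents (HL7-CDA-style XML reports) into an
    extended entity-attribute-value (EAV) relational schema. Documents are
    shredded losslessly into per-occurrence entity rows with parent and
    sibling-position links, a deduplicated attribute dictionary, and typed
    value tables carrying verbatim lexical forms and per-document provenance.
    The package provides path-reconstructing and attribute-centric queries,
    exact reconstruction of imported documents, a rule-based export pipeline
    with a completeness-check loop, view-based horizontal/vertical access
    fragments with per-role rights, and a seeded generator for synthetic
    CDA-like nursing-report corpora with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    xml2,
    jsonlite,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
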