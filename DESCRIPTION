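Package: leapr
Title: Linked Entity-Attribute-Pair Stores for Terminology Crosswalk Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A hybrid entity-attribute-value (EAV) store in which entities
    inherit attributes from linked entities, designed for managing and
    versioning term mappings between dynamic clinical classification systems
    (for example OncoTree codes mapped to the seven GDC diagnosis elements
    built on ICD-O-3 morphology and topography codes). Provides an append-only
    change history with as-of reconstruction, readers and a dynamic-pivot
    exporter for denormalized mapping sheets, data-dictionary validation with
    an error taxonomy (unknown terms, capitalization mismatches, dependent
    field mismatches, annotated inaccurate mappings), classification-version
    diffing with re-review flagging, and a deterministic synthetic fixture
    generator with seeded defects.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
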