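Package: odmsemantics
Title: Uniform Semantic Annotation of CDISC ODM Data Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for uniform semantic annotation of clinical data elements
    in CDISC ODM 1.3 study metadata. Curated concept-code annotations
    (UMLS-style CUIs, including postcoordinated code combinations) are re-used
    from a term index built over a corpus of data models, with fallback lookup
    in a pluggable vocabulary table, fuzzy item-name matching, incremental
    index updates, a batch annotation workflow, and an analyzer that summarizes
    coding uniformity (variants per data element) across a corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
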