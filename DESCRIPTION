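Package: instancemaps
Title: Instance Maps for Documenting Experimental Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Create, validate, serialise and compare instance maps: directed
    graph documents that describe an experimental study as a chain of material
    "instances" (a material in its medium at a moment in time) with side
    branches for protocols, measured properties and the data they produce.
    Provides the built-in twelve-kind node taxonomy with per-kind metadata
    requirement slots, completeness scoring against those slots, structural
    validation under configurable strict/lenient profiles, canonical JSON
    serialisation (YAML read support), export to DOT, Mermaid and GraphML,
    import of legacy five-category curation tables, map diffing and merging,
    cross-map link resolution, programmatic builders for a set of worked
    example maps, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    xml2,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
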