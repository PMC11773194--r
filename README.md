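# instancemaps

Instance maps are a graph-based format for describing experimental studies,
developed in nanosafety research, where a material's properties change with
its surroundings and over time. The central object is the **instance**: the
test material in its medium at a specific moment. A physical or chemical
change to the material creates a new instance, so a study becomes a directed,
usually tree-like graph whose main branches are consecutive instances, with
side branches describing the material and medium, the protocols applied, the
properties measured, and the data produced. Built at the study-design stage
and kept alive through execution, such a map doubles as a data-management
plan: every node can link to the protocol, SOP, ELN page or data file behind
it, and the map can be checked for completeness before any data is collected.

`instancemaps` implements this format for R, for experimentalists, data
shepherds and curation teams who need study descriptions that are versionable,
diffable and machine-checkable rather than hand-drawn:

* **Taxonomy** — the built-in registry of twelve node kinds in four
  colour-coded categories (instance family, protocols, properties, data),
  each with the metadata "requirement slots" a complete description should
  fill, plus the mapping from the original five-term curation vocabulary.
* **Model** — a pure construction API (`new_map()`, `add_node()`,
  `add_edge()`, `add_region()`, `attach_resource()`, `add_map_link()`) that
  cannot produce a structurally inconsistent map.
* **Validation** — acyclicity with cycle witnesses, instance-backbone
  extraction, rule-based structural validation under configurable
  strict/lenient profiles, and per-node completeness scoring.
* **I/O** — canonical, byte-stable JSON serialisation (YAML read support),
  export to DOT, Mermaid and GraphML, and import of legacy five-category
  curation tables (CSV).
* **Compose** — field-level diffs between map versions with a patch
  guarantee, cross-map link resolution across a workspace, and submap
  merging with id prefixing.
* **Examples** — deterministic builders for seven worked maps (nanoparticle
  sulfidation, a soil mesocosm, *Daphnia magna* culture maintenance, the
  OECD 202 and 211 toxicity tests, an immunotoxicity workflow, and a
  multi-partner planning map), plus a seeded random-map generator.
* **CLI** — an `instancemap` script (in `exec/`) with `validate`, `render`,
  `diff`, `convert`, `example` and `report` subcommands and CI-friendly exit
  codes (0 valid, 1 validation errors, 2 usage/schema errors).

## Worked example

The acute *Daphnia* immobilisation test (OECD test guideline 202) as an
instance map: neonates, test vessels with an exposure series, the 48 h
endpoint, and the measurement chain down to the fitted dose–response curve.

```r
library(instancemaps)

m <- build_fixture("oecd202")
m
#> <instance_map 'oecd202'> 10 nodes, 9 edges, 0 regions, 0 map links
#>   nodes: DataProcessingProtocol=1, Instance=3, Material=1, MeasurementProtocol=1,
#>          Medium=1, ProcessedData=1, RawData=1, SamplePreparationProtocol=1

extract_backbone(m)
#> [[1]]
#> [1] "inst_neonates" "inst_test"     "inst_48h"

validate_map(m, validation_profile("strict"))
#> Validation (strict profile): PASSED, 0 issue(s)

completeness(m)
#> Completeness: map score 0.75 over 10 node(s)
#>   dp_fit               1.00
#>   inst_48h             0.00  missing: component_listing, provenance
#>   inst_neonates        0.50  missing: provenance
#>   ...
```

The backbone is the study's time axis: the three consecutive instances. The
strict profile confirms every connection follows the standard arrangement
(material/medium into an instance; sample preparation → measurement → raw
data → data processing → processed data). The completeness report shows
which nodes still lack the metadata their kind calls for — here the endpoint
instance carries neither a component listing nor provenance yet, exactly the
kind of gap the format is meant to surface *before* the experiment runs.

Maps serialise canonically (`to_document()`, `write_map()`), render to
diagrams (`export_map(m, "mermaid")`), and diff across versions
(`map_diff(old, new)`). The chronic-test map links into the acute one —
its exposure concentration is derived from the acute dose–response curve —
and `resolve_links(workspace(...))` checks such cross-map references.

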