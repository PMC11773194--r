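---
title: "Instance maps: model, validation rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance maps: model, validation rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instancemaps)
```

## The model

An instance map describes an experimental study as a directed graph. Its
organising unit is the *instance* — the test material (a nanomaterial, an
organism culture, a product sample) in its medium at a specific moment in
time. Any physical or chemical change that could alter the material's
properties starts a new instance, so the main branches of the graph are
chains of consecutive instances and edge direction encodes the flow of time.
Side branches attach everything needed to interpret each instance: the
material and medium themselves, the protocols applied (transformation,
sample preparation, measurement, data processing), the properties recorded
(curated from literature, computed, or measured), and the data produced
(raw and processed).

Two modelling assumptions follow from this reading and shape the package:

* **Maps are DAG-like but not trees.** Multiple parents are allowed —
  convergent steps (two inputs meeting in one exposure instance,
  multi-partner workflows joining) are common — but directed cycles are
  always a structural error, because an edge points forward in time.
* **Node identity is caller-supplied.** Node ids are stable strings chosen
  by the author, not auto-generated, because identity across versions is
  what makes diffing meaningful.

The twelve node kinds and four categories are fixed
(`builtin_taxonomy()`); the five-term vocabulary of the original curation
workflow (instance, material, medium, property, supplementary) maps onto
them via `map_legacy()`. Legacy *property* rows default to
`CuratedProperty` because that workflow extracted data from publications;
the default is overridable for tables that recorded primary measurements.
Legacy *supplementary* entries carried visual information about a property,
which today is simply a resource link, so they import as links with role
`"supplementary"` on the preceding property node.

## Requirement slots and completeness

Each kind carries one or two *requirement slots*: the information a complete
study description should provide for a node of that kind (a medium's recipe
or identifier, a material's characterisation, a protocol's SOP or ELN link,
an instrument's metadata, ...). Slot ids are stable snake_case identifiers
introduced by this package; the descriptive prose is stored verbatim as the
slot label. A slot is satisfied when the node carries a metadata field whose
name — or an attached resource link whose role — appears in the slot's
`satisfied_by` set.

`completeness()` scores each node as satisfied/required slots and the map as
the mean of node scores. Satisfaction is assessed **per node**: several
nodes may legitimately point at the same data file (e.g. tabs of one
workbook), and each node's slot is then satisfied independently. Scores are
monotone by construction — attaching a satisfying link can never lower any
score — and invariant under relabelling, both of which are enforced by
property tests.

## Validation profiles

Connection practice varies legitimately between authors: the measurement
chain (sample preparation → measurement → raw data → data processing →
processed data) is sometimes placed before the measured property, sometimes
after it, and sometimes replaces it. The package therefore never hard-fails
on connection style. `validate_map()` applies six rules:

| rule | checks | strict | lenient |
|------|--------|--------|---------|
| R1 | dangling references | error | error |
| R2 | directed cycles | error | error |
| R3 | edge outside the adjacency whitelist | warning | info |
| R4 | misordered measurement chain | warning | info |
| R5 | unattached Material/Medium | info | info |
| R6 | empty map | warning | warning |

Only R1 and R2 can fail a map. The strict whitelist admits both observed
arrangements of the measurement chain (including the property-first
variant), material/medium → instance, instance chains directly or through a
transformation protocol, and properties hanging off instances, materials,
media, raw data or processed data. Whether a material or medium *must* be
attached to an instance is an open question in the format — they may stand
alone when first used in a synthesis or exposure — so R5 only notices them
at info level. Severities are overridable per rule, and whole profiles can
be loaded from a YAML/JSON config (`profile_from_config()`), so a community
that wants hard connection rules can have them without code changes.

R4's chain check is local and per edge: it flags a stage edge that runs
against the stage order (e.g. raw data feeding its own measurement
protocol) but tolerates missing optional stages, such as a chain that stops
at raw data.

The cycle test is an iterative source-removal (Kahn) pass; when a cycle
exists the witness is recovered by pruning leftover nodes without successors
in the leftover set and walking until a node repeats. The witness is itself
verified to be a cycle in the test suite, and acyclicity is checked against
an exhaustive DFS oracle on hundreds of small random digraphs.

`extract_backbone()` returns the maximal instance chains (instances
connected directly or through a single transformation protocol), each
ordered along edge direction; at branch points every maximal path is
reported, with ids sorted at each choice point so enumeration is
deterministic.

## Serialisation

The canonical format is JSON with `format_version` "1.0". Canonical means:
nodes sorted by id, edges by (source, target, label), regions by id,
cross-map links by their full tuple, fixed key order, no locale-dependent
formatting. The map container itself maintains this order at all times, so
serialising twice is byte-identical and
`from_document(to_document(m))` is an exact identity — tested over all
packaged examples and a hundred seeded random maps. YAML is accepted on
read only; a single write dialect avoids drift. Parsing re-validates every
structural invariant and reports violations with JSON-pointer-style
locations (`/edges/2/target`); a missing or unknown `format_version` is its
own error so old tooling fails loudly rather than misreading a newer
document.

Exports carry one node statement per node with the node's kind, label and
effective colour (the category default unless overridden), one edge
statement per edge, and regions as DOT clusters / Mermaid subgraphs
(GraphML, which has no native grouping, stores region membership as a node
attribute). Mermaid node shapes encode the category — rectangle for the
instance family, hexagon for protocols, rounded for properties,
parallelogram for data — a convention of this package, since the upstream
format specifies colour-coding only. Overlapping regions are supported in
the model; DOT renders overlapping clusters on a last-wins basis, which is
a known limitation of that format, not of the document.

Category colours are constants chosen here (light blue instance family,
light purple protocols, orange properties, red data) following the
colour-coding conventions the example maps describe; the exact hex values
are an implementation choice. Colour overrides are deliberately
presentational: re-colouring nodes — e.g. borrowing the data-red to flag
steps still under discussion in a planning map — never changes validation.

## Versioning and composition

`map_diff()` matches nodes by id and enumerates changed fields
deterministically (sorted by field name) with old and new values; edges,
regions and cross-map links are compared by identity, since an edge's only
payload (its label) participates in its identity. The diff satisfies a
patch property — an internal helper reconstructs the target version exactly
from the base plus the diff — which is what makes the diff trustworthy as a
record of "what changed between planning and execution". A free-text
annotation can ride on a diff to record *why* a deviation happened; the
reason is deliberately unstructured. Versioning is linear: no three-way
merge, because the use case is documented deviation from a plan, not
concurrent editing, and history lives in ordinary version control of the
serialised files.

`resolve_links()` treats unresolved cross-map links as warnings, never
errors: maps travel separately and a target map may simply not be loaded.
`merge_maps()` with id prefixing rewrites cross-map links between merged
maps into ordinary labelled edges, so a merged workspace has nothing left
to resolve; merging is associative up to prefixing for disjoint maps.

## The example maps and the random generator

The seven builders encode what the underlying study descriptions state:
the sulfidation map has the three synthesis instances, one transformation
protocol per stated PVP-AgNP concentration, and four tracked nanoparticle
variants (pristine plus three sulfidised); the culture map carries the
printed culture parameters (900 mL medium in 1 L vessels, 10–15 adults,
20 °C, 16:8 photoperiod) and attaches the packaged culture-log CSV to its
raw-data node; the chronic-test map cross-links to the acute map's
dose–response node; the immunotoxicity map defines regions A–E; the
planning map includes shipping transformation protocols and red-override
planning nodes. Where a published figure's full node roster is not
enumerated in text (the mesocosm and immunotoxicity workflows), the map is
a faithful skeleton of the named nodes and says so in its metadata.

`random_map(seed, n_instances, branch_prob)` generates a backbone chain
with probabilistic side branches (material, medium, property, measurement
chain), emitting only forward edges, so its output is acyclic and
lenient-clean by construction. It emulates the *structure* of real maps —
the branching shapes the validator and serialiser must handle — but not
their content: labels and fields are synthetic placeholders, resource links
point nowhere, and metadata is minimal. Passing property suites therefore
demonstrates structural correctness (round trips, acyclicity, diff/patch,
monotonicity), not that any particular real study is well described. The
generator saves and restores the caller's RNG state, so the same seed
always yields the identical map regardless of surrounding code. Test and
acceptance runs use modest sizes — up to eight backbone instances, digraphs
of at most eight nodes for oracle comparisons, tens of seeds per property —
chosen to exercise every branch shape the model admits while keeping the
suites quick.

## Known limitations

* No layout persistence: node coordinates are delegated to the target
  format's auto-layout.
* Linked resources are opaque: files are never fetched, parsed or
  converted, so completeness measures metadata presence, not content
  quality.
* No ontology annotation of kinds (e.g. eNanoMapper/OBO terms); the kind
  registry is plain identifiers, ontology mapping is future work.
* The legacy importer assumes the documented row grouping (material,
  medium and property rows follow their instance; supplementary rows follow
  their property); tables that interleave rows differently import without
  error but may attach branches to an earlier instance than intended.
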