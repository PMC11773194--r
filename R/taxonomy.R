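# Built-in node taxonomy: twelve node kinds in four colour-coded categories,
# each with the metadata "requirement slots" a complete study description is
# expected to fill (directly as node fields or via attached resource links).

IM_CATEGORIES <- list(
  `instance-family` = "#A7C7E7",  # light blue
  protocol          = "#C9A0DC",  # light purple
  property          = "#F4A259",  # orange
  data              = "#E05252"   # red
)

IM_KIND_CATEGORY <- c(
  Instance                  = "instance-family",
  Material                  = "instance-family",
  Medium                    = "instance-family",
  TransformationProtocol    = "protocol",
  SamplePreparationProtocol = "protocol",
  MeasurementProtocol       = "protocol",
  DataProcessingProtocol    = "protocol",
  CuratedProperty           = "property",
  ComputedProperty          = "property",
  ExperimentalProperty      = "property",
  RawData                   = "data",
  ProcessedData             = "data"
)

IM_PROPERTY_KINDS <- c("CuratedProperty", "ComputedProperty", "ExperimentalProperty")

IM_LEGACY_TERMS <- c("instance", "material", "medium", "property", "supplementary")

# One requirement slot: stable snake_case id, the prose label describing the
# information expected, and the set of node-field names / resource-link roles
# any one of which satisfies it.
req_slot <- function(slot_id, label, satisfied_by) {
  structure(list(slot_id = slot_id, label = label,
                 satisfied_by = satisfied_by),
            class = "im_req_slot")
}

im_requirement_slots <- function() {
  protocol_slot <- req_slot(
    "protocol_resource",
    "protocol document/video, SOP, and/or ELN workflow",
    c("protocol", "sop", "eln_page", "eln_workflow", "protocol_document"))
  list(
    Instance = list(
      req_slot("component_listing",
               paste("listing of all components (materials and media) defining",
                     "the current life cycle stage of the material/sample"),
               c("components", "component_listing")),
      req_slot("provenance",
               "bibliographic and provenance data defining the setup",
               c("provenance", "bibliography", "reference"))),
    Material = list(
      req_slot("characterisation",
               paste("full characterisation of material including, e.g., chemical",
                     "composition, size, shape/structure, and/or NanoInChI"),
               c("characterisation", "chemical_composition", "size",
                 "shape", "structure", "nanoinchi"))),
    Medium = list(
      req_slot("recipe_or_identifier",
               "recipe of medium and/or identifier of medium and its constituents",
               c("recipe", "medium_identifier", "constituents"))),
    TransformationProtocol = list(protocol_slot),
    SamplePreparationProtocol = list(protocol_slot),
    MeasurementProtocol = list(
      req_slot("instrument_metadata",
               paste("instrument metadata, software metadata, instrument",
                     "settings/input parameters"),
               c("instrument", "instrument_metadata", "software",
                 "settings", "input_parameters")),
      protocol_slot),
    DataProcessingProtocol = list(
      req_slot("processing_pipeline",
               paste("data processing pipeline, software details, statistical test",
                     "details, equations utilised, and blanks/controls"),
               c("pipeline", "software", "statistical_test", "equations",
                 "blanks_controls", "protocol", "sop"))),
    CuratedProperty = list(
      req_slot("bibliographic_source",
               "bibliographic information and/or link to numeric value/data",
               c("bibliography", "reference", "value", "data"))),
    ComputedProperty = list(
      req_slot("model_and_software",
               paste("model/algorithm name and software used to compute the",
                     "property, and/or link to numeric value/data"),
               c("model", "algorithm", "software", "value", "data"))),
    ExperimentalProperty = list(
      req_slot("assay_metadata",
               paste("assay name, instrument metadata (if relevant), organism",
                     "metadata (if relevant), metadata, and/or link to numeric",
                     "value/data"),
               c("assay", "instrument", "organism", "metadata", "value", "data"))),
    RawData = list(
      req_slot("first_dataset",
               "first set of data produced by a specific experiment",
               c("raw_data", "data", "dataset", "value"))),
    ProcessedData = list(
      req_slot("downstream_dataset",
               "second and any other downstream set of data generated from raw data",
               c("processed_data", "data", "dataset", "value")))
  )
}

IM_KIND_DESCRIPTIONS <- c(
  Instance = "test object (material or other) in its chemical, biological and/or product environment at a moment in time",
  Material = "compositional and structural information about the test object",
  Medium = "description of the surroundings of the test object (solvent, biological model, product matrix)",
  TransformationProtocol = "experimental details of changes to the object or its surroundings that drive a change in its physicochemical properties",
  SamplePreparationProtocol = "experimental details of sample preparation, e.g. dispersion, mixing or presentation to test organisms",
  MeasurementProtocol = "experimental details of the measurement performed",
  DataProcessingProtocol = "step-by-step description of the data processing",
  CuratedProperty = "property value extracted from a publication or database",
  ComputedProperty = "property value calculated/predicted with a model or algorithm",
  ExperimentalProperty = "property value measured experimentally",
  RawData = "data retrieved directly from observation/measurement/computation",
  ProcessedData = "data produced from raw data by background subtraction, normalisation, calculation, etc."
)

#' The built-in node-kind registry
#'
#' Returns the registry of the twelve node kinds an instance map may use,
#' grouped into four categories (\code{instance-family}, \code{protocol},
#' \code{property}, \code{data}), each with its default category colour and
#' the metadata requirement slots used by [completeness()].
#'
#' @return An object of class \code{im_taxonomy}: a named list mapping each
#'   kind name to a kind specification with elements \code{kind},
#'   \code{category}, \code{colour}, \code{description} and
#'   \code{requirement_slots}.
#' @examples
#' tax <- builtin_taxonomy()
#' names(tax)
#' tax$Material$category
#' @seealso [requirements_for()], [map_legacy()], [taxonomy_document()]
#' @export
builtin_taxonomy <- function() {
  slots <- im_requirement_slots()
  specs <- lapply(names(IM_KIND_CATEGORY), function(kind) {
    cat <- IM_KIND_CATEGORY[[kind]]
    structure(list(kind = kind,
                   category = cat,
                   colour = IM_CATEGORIES[[cat]],
                   description = unname(IM_KIND_DESCRIPTIONS[[kind]]),
                   requirement_slots = slots[[kind]]),
              class = "im_kind_spec")
  })
  names(specs) <- names(IM_KIND_CATEGORY)
  structure(specs, class = "im_taxonomy")
}

#' Requirement slots for a node kind
#'
#' @param kind A registered node-kind name, e.g. \code{"Medium"}.
#' @param taxonomy A taxonomy as returned by [builtin_taxonomy()].
#' @return A list of requirement slots (\code{slot_id}, \code{label},
#'   \code{satisfied_by}).
#' @export
requirements_for <- function(kind, taxonomy = builtin_taxonomy()) {
  if (length(kind) != 1L || !kind %in% names(taxonomy))
    im_stop("E_UNKNOWN_KIND", "unknown node kind: %s",
            paste(as.character(kind), collapse = ", "))
  taxonomy[[kind]]$requirement_slots
}

#' Map a legacy five-term category to the current taxonomy
#'
#' The original curation vocabulary had five categories: \code{instance},
#' \code{material}, \code{medium}, \code{property} and \code{supplementary}.
#' The first three map to their same-named kinds. \code{property} maps to a
#' configurable property kind (default \code{CuratedProperty}, since legacy
#' tables were curated from publications). \code{supplementary} carried visual
#' information about a property and is represented today as a resource link
#' with role \code{"supplementary"} on the preceding property node; for it
#' this function returns an attachment directive rather than a kind.
#'
#' @param term A legacy term.
#' @param property_default Kind used for legacy \code{property} rows; one of
#'   the three property kinds.
#' @return For the first four terms, a list with \code{type = "kind"} and the
#'   target \code{kind}; for \code{supplementary}, a list with
#'   \code{type = "attachment"} and \code{role = "supplementary"}.
#' @export
map_legacy <- function(term, property_default = "CuratedProperty") {
  if (!property_default %in% IM_PROPERTY_KINDS)
    im_stop("E_UNKNOWN_KIND", "property_default must be a property kind, got %s",
            property_default)
  if (length(term) != 1L || !term %in% IM_LEGACY_TERMS)
    im_stop("E_UNKNOWN_LEGACY_TERM", "unknown legacy term: %s",
            paste(as.character(term), collapse = ", "))
  switch(term,
         instance = list(type = "kind", kind = "Instance"),
         material = list(type = "kind", kind = "Material"),
         medium   = list(type = "kind", kind = "Medium"),
         property = list(type = "kind", kind = property_default),
         supplementary = list(type = "attachment", role = "supplementary"))
}

#' Export the taxonomy as a JSON reference document
#'
#' Serialises the kind registry (kind, category, colour, description,
#' requirement slots) as pretty-printed JSON, for documentation and for
#' authors of validation-profile config files.
#'
#' @param taxonomy A taxonomy as returned by [builtin_taxonomy()].
#' @return A JSON string.
#' @export
taxonomy_document <- function(taxonomy = builtin_taxonomy()) {
  doc <- lapply(unclass(taxonomy), function(spec) {
    list(kind = spec$kind, category = spec$category, colour = spec$colour,
         description = spec$description,
         requirement_slots = lapply(spec$requirement_slots, function(s)
           list(slot_id = s$slot_id, label = s$label,
                satisfied_by = as.list(s$satisfied_by))))
  })
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
}

#' @export
print.im_taxonomy <- function(x, ...) {
  cat("Instance-map node taxonomy:", length(x), "kinds in",
      length(unique(vapply(x, `[[`, "", "category"))), "categories\n")
  for (cat_name in names(IM_CATEGORIES)) {
    members <- names(x)[vapply(x, `[[`, "", "category") == cat_name]
    cat(sprintf("  %-16s [%s] %s\n", cat_name, IM_CATEGORIES[[cat_name]],
                paste(members, collapse = ", ")))
  }
  invisible(x)
}
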