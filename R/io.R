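# Canonical serialisation, legacy-table import, and export to DOT, Mermaid
# and GraphML.
#
# The canonical document is JSON (format_version "1.0") with a fixed key
# order, nodes sorted by id, edges by (source, target, label): serialising the
# same map twice is byte-identical, and from_document(to_document(m)) == m.
# YAML is accepted on read only, so there is a single write dialect.

IM_FORMAT_VERSION <- "1.0"

empty_obj <- function() structure(list(), names = character(0))

im_node_to_list <- function(n) {
  out <- list(id = n$id, kind = n$kind, label = n$label,
              meta = if (length(n$meta)) n$meta else empty_obj(),
              fields = if (length(n$fields)) n$fields else empty_obj(),
              links = lapply(n$links, function(l) {
                ll <- list(target = l$target, role = l$role)
                if (!is.null(l$media_hint)) ll$media_hint <- l$media_hint
                ll
              }))
  if (!is.null(n$colour_override)) out$colour_override <- n$colour_override
  out
}

#' Serialise a map to its canonical JSON document
#'
#' @param map An instance map.
#' @return A single JSON string. Output is byte-stable: canonical element
#'   ordering, fixed key order, no locale-dependent formatting.
#' @seealso [from_document()], [write_map()]
#' @export
to_document <- function(map) {
  stopifnot(inherits(map, "instance_map"))
  doc <- list(
    format_version = IM_FORMAT_VERSION,
    map = list(id = map$id,
               meta = if (length(map$meta)) map$meta else empty_obj()),
    nodes = lapply(unname(map$nodes), im_node_to_list),
    edges = lapply(map$edges, function(e) {
      out <- list(source = e$source, target = e$target)
      if (!is.null(e$label)) out$label <- e$label
      out
    }),
    regions = lapply(map$regions, function(r) {
      out <- list(id = r$id, label = r$label, members = as.list(r$members))
      if (!is.null(r$colour)) out$colour <- r$colour
      out
    }),
    map_links = lapply(map$map_links, function(l)
      list(source_node = l$source_node, target_map = l$target_map,
           target_node = l$target_node, relation = l$relation))
  )
  paste0(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                       digits = NA, null = "null")), "\n")
}

im_schema_fail <- function(where, msg, ...) {
  im_stop("E_SCHEMA", "schema violation at %s: %s", where, sprintf(msg, ...))
}

chr1 <- function(x, where) {
  if (is.null(x) || length(x) != 1L || !is.character(x) && !is.numeric(x))
    im_schema_fail(where, "expected a string")
  as.character(x)
}

#' Parse a canonical document into an instance map
#'
#' Accepts the canonical JSON and, for convenience, YAML with the same
#' structure. The document must declare a supported \code{format_version}.
#' All structural invariants are re-checked during reconstruction; violations
#' are reported with a JSON-pointer-style location.
#'
#' @param text A single string holding the document (or a character vector of
#'   lines, which are joined with newlines).
#' @return An instance map.
#' @export
from_document <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(doc))
    doc <- tryCatch(yaml::yaml.load(text),
                    error = function(e)
                      im_stop("E_SCHEMA",
                              "input is neither well-formed JSON nor YAML"))
  if (!is.list(doc) || is.null(names(doc)))
    im_stop("E_SCHEMA", "schema violation at /: document must be an object")
  fv <- doc$format_version
  if (is.null(fv))
    im_stop("E_FORMAT_VERSION", "document has no format_version")
  if (!identical(as.character(fv), IM_FORMAT_VERSION))
    im_stop("E_FORMAT_VERSION", "unsupported format_version: %s",
            as.character(fv))
  if (is.null(doc$map) || is.null(doc$map$id))
    im_schema_fail("/map/id", "missing map id")

  wrap <- function(where, expr) {
    tryCatch(expr, im_error = function(e) {
      if (inherits(e, "E_SCHEMA") || inherits(e, "E_FORMAT_VERSION")) stop(e)
      im_schema_fail(where, "%s", conditionMessage(e))
    })
  }

  m <- wrap("/map", new_map(chr1(doc$map$id, "/map/id"),
                            meta = doc$map$meta %||% list()))
  for (i in seq_along(doc$nodes)) {
    nd <- doc$nodes[[i]]
    where <- sprintf("/nodes/%d", i - 1L)
    m <- wrap(where, add_node(m, im_node(
      id = chr1(nd$id, paste0(where, "/id")),
      kind = chr1(nd$kind, paste0(where, "/kind")),
      label = if (is.null(nd$label)) chr1(nd$id, where) else
        chr1(nd$label, paste0(where, "/label")),
      meta = nd$meta %||% list(),
      fields = nd$fields %||% list(),
      links = lapply(nd$links %||% list(), function(l)
        resource_link(l$target, l$role, l$media_hint)),
      colour_override = nd$colour_override)))
  }
  for (i in seq_along(doc$edges)) {
    ed <- doc$edges[[i]]
    where <- sprintf("/edges/%d", i - 1L)
    m <- wrap(where, add_edge(m, im_edge(
      chr1(ed$source, paste0(where, "/source")),
      chr1(ed$target, paste0(where, "/target")),
      ed$label)))
  }
  for (i in seq_along(doc$regions)) {
    rg <- doc$regions[[i]]
    where <- sprintf("/regions/%d", i - 1L)
    m <- wrap(where, add_region(m, im_region(
      chr1(rg$id, paste0(where, "/id")),
      label = if (is.null(rg$label)) chr1(rg$id, where) else rg$label,
      members = as.character(unlist(rg$members %||% list())),
      colour = rg$colour)))
  }
  for (i in seq_along(doc$map_links)) {
    ml <- doc$map_links[[i]]
    where <- sprintf("/map_links/%d", i - 1L)
    m <- wrap(where, add_map_link(m, im_map_link(
      chr1(ml$source_node, paste0(where, "/source_node")),
      chr1(ml$target_map, paste0(where, "/target_map")),
      chr1(ml$target_node, paste0(where, "/target_node")),
      ml$relation %||% "")))
  }
  m
}

#' Write / read a map file
#'
#' \code{write_map()} writes the canonical JSON document; \code{read_map()}
#' reads a JSON or YAML document.
#'
#' @param map An instance map.
#' @param path File path.
#' @return \code{write_map()} returns \code{path} invisibly; \code{read_map()}
#'   returns an instance map.
#' @export
write_map <- function(map, path) {
  writeLines(sub("\n$", "", to_document(map)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path))
    im_stop("E_SCHEMA", "no such file: %s", path)
  from_document(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# --- graph/diagram exports ---------------------------------------------------

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

im_export_dot <- function(map, taxonomy) {
  out <- c(sprintf("digraph %s {", dot_quote(map$id)),
           "  rankdir=TB;",
           '  node [style=filled];')
  for (n in map$nodes)
    out <- c(out, sprintf('  %s [label=%s, fillcolor="%s", kind="%s", category="%s"];',
                          dot_quote(n$id), dot_quote(n$label),
                          effective_colour(n, taxonomy), n$kind,
                          IM_KIND_CATEGORY[[n$kind]]))
  for (e in map$edges) {
    attr <- if (!is.null(e$label)) sprintf(" [label=%s]", dot_quote(e$label)) else ""
    out <- c(out, sprintf("  %s -> %s%s;", dot_quote(e$source),
                          dot_quote(e$target), attr))
  }
  for (i in seq_along(map$regions)) {
    r <- map$regions[[i]]
    out <- c(out, sprintf("  subgraph cluster_%d {", i - 1L),
             sprintf("    label=%s;", dot_quote(r$label)),
             sprintf("    %s;", paste(dot_quote(r$members), collapse = "; ")),
             "  }")
  }
  paste0(paste(c(out, "}"), collapse = "\n"), "\n")
}

mermaid_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

im_export_mermaid <- function(map, taxonomy) {
  # node shape encodes the category: rectangle instance-family, hexagon
  # protocol, rounded property, parallelogram data (colour alone does not
  # survive every mermaid theme)
  shape <- function(id, label, category) {
    lab <- gsub('"', "#quot;", label)
    switch(category,
           `instance-family` = sprintf('%s["%s"]', id, lab),
           protocol = sprintf('%s{{"%s"}}', id, lab),
           property = sprintf('%s("%s")', id, lab),
           data = sprintf('%s[/"%s"/]', id, lab))
  }
  out <- "flowchart TD"
  for (n in map$nodes) {
    mid <- mermaid_id(n$id)
    out <- c(out, paste0("  ", shape(mid, n$label, IM_KIND_CATEGORY[[n$kind]])),
             sprintf("  style %s fill:%s", mid, effective_colour(n, taxonomy)))
  }
  for (e in map$edges) {
    arrow <- if (!is.null(e$label))
      sprintf("-->|%s|", gsub("\\|", "/", e$label)) else "-->"
    out <- c(out, sprintf("  %s %s %s", mermaid_id(e$source), arrow,
                          mermaid_id(e$target)))
  }
  for (r in map$regions)
    out <- c(out,
             sprintf('  subgraph %s ["%s"]', mermaid_id(r$id), r$label),
             sprintf("    %s", vapply(r$members, mermaid_id, "")),
             "  end")
  paste0(paste(out, collapse = "\n"), "\n")
}

im_export_graphml <- function(map, taxonomy) {
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    list(id = "kind", `for` = "node", attr.name = "kind", attr.type = "string"),
    list(id = "category", `for` = "node", attr.name = "category", attr.type = "string"),
    list(id = "label", `for` = "node", attr.name = "label", attr.type = "string"),
    list(id = "colour", `for` = "node", attr.name = "colour", attr.type = "string"),
    list(id = "regions", `for` = "node", attr.name = "regions", attr.type = "string"),
    list(id = "elabel", `for` = "edge", attr.name = "label", attr.type = "string"))
  for (k in keydefs)
    xml2::xml_add_child(doc, "key", id = k$id, "for" = k$`for`,
                        "attr.name" = k$attr.name, "attr.type" = k$attr.type)
  g <- xml2::xml_add_child(doc, "graph", id = map$id, edgedefault = "directed")
  region_of <- lapply(map$regions, `[[`, "members")
  names(region_of) <- vapply(map$regions, `[[`, "", "id")
  for (n in map$nodes) {
    nd <- xml2::xml_add_child(g, "node", id = n$id)
    add <- function(key, value) {
      d <- xml2::xml_add_child(nd, "data", key = key)
      xml2::xml_text(d) <- value
    }
    add("kind", n$kind)
    add("category", IM_KIND_CATEGORY[[n$kind]])
    add("label", n$label)
    add("colour", effective_colour(n, taxonomy))
    in_regions <- names(region_of)[vapply(region_of, function(m) n$id %in% m, TRUE)]
    if (length(in_regions)) add("regions", paste(in_regions, collapse = ";"))
  }
  for (i in seq_along(map$edges)) {
    e <- map$edges[[i]]
    ed <- xml2::xml_add_child(g, "edge", id = sprintf("e%d", i - 1L),
                              source = e$source, target = e$target)
    if (!is.null(e$label)) {
      d <- xml2::xml_add_child(ed, "data", key = "elabel")
      xml2::xml_text(d) <- e$label
    }
  }
  as.character(doc)
}

#' Export a map to a diagram/graph format
#'
#' Emits one node statement per node (carrying kind, label and
#' [effective_colour()]), one edge statement per edge, and regions as
#' clusters/subgraphs where the format allows (DOT clusters, Mermaid
#' subgraphs; GraphML stores region membership as a node attribute).
#'
#' @param map An instance map.
#' @param format One of \code{"dot"}, \code{"mermaid"}, \code{"graphml"}.
#' @param taxonomy Taxonomy providing category colours.
#' @return The exported document as a single string.
#' @export
export_map <- function(map, format = c("dot", "mermaid", "graphml"),
                       taxonomy = builtin_taxonomy()) {
  stopifnot(inherits(map, "instance_map"))
  if (length(format) != 1L || !format %in% c("dot", "mermaid", "graphml"))
    im_stop("E_FORMAT", "unknown export format: %s",
            paste(as.character(format), collapse = ", "))
  switch(format,
         dot = im_export_dot(map, taxonomy),
         mermaid = im_export_mermaid(map, taxonomy),
         graphml = im_export_graphml(map, taxonomy))
}

# --- legacy five-category table import --------------------------------------

legacy_id <- function(name, taken) {
  base <- gsub("[^A-Za-z0-9_.-]", "_", name)
  if (!nzchar(base)) base <- "node"
  id <- base
  k <- 1L
  while (id %in% taken) {
    k <- k + 1L
    id <- sprintf("%s_%d", base, k)
  }
  id
}

#' Import a legacy five-category curation table
#'
#' The original curation workflow recorded studies as flat tables whose rows
#' are categorised with the five-term vocabulary (\code{instance},
#' \code{material}, \code{medium}, \code{property}, \code{supplementary}).
#' This rebuilds an instance map from such a table: consecutive instance rows
#' are chained with Instance-to-Instance edges; material, medium and property
#' rows become nodes attached to the most recent instance; supplementary rows
#' become resource links (role \code{"supplementary"}) on the nearest
#' preceding property node.
#'
#' @param rows A data frame with columns \code{category}, \code{name},
#'   \code{value}, \code{link} (RFC 4180 CSV read with
#'   \code{utils::read.csv} works directly), or a path to such a CSV file.
#' @param property_default Node kind used for \code{property} rows; legacy
#'   tables were curated from publications, so the default is
#'   \code{CuratedProperty}.
#' @param map_id Id for the resulting map.
#' @return An instance map. The result always passes lenient validation with
#'   zero errors.
#' @export
import_legacy_table <- function(rows, property_default = "CuratedProperty",
                                map_id = "legacy_import") {
  if (is.character(rows) && length(rows) == 1L) {
    if (!file.exists(rows))
      im_stop("E_SCHEMA", "no such file: %s", rows)
    rows <- utils::read.csv(rows, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  stopifnot(is.data.frame(rows))
  need <- c("category", "name")
  if (!all(need %in% names(rows)))
    im_stop("E_SCHEMA", "legacy table must have columns category,name,value,link")
  if (!"value" %in% names(rows)) rows$value <- ""
  if (!"link" %in% names(rows)) rows$link <- ""

  m <- new_map(map_id)
  last_instance <- NULL
  last_property <- NULL
  for (i in seq_len(nrow(rows))) {
    term <- trimws(rows$category[[i]])
    if (!term %in% IM_LEGACY_TERMS)
      im_stop("E_UNKNOWN_LEGACY_TERM", "row %d: unknown legacy category '%s'",
              i, term)
    directive <- map_legacy(term, property_default)
    name <- trimws(rows$name[[i]])
    value <- trimws(rows$value[[i]] %||% "")
    link <- trimws(rows$link[[i]] %||% "")
    if (directive$type == "attachment") {
      if (is.null(last_property))
        im_stop("E_ORPHAN_SUPPLEMENTARY",
                "row %d: supplementary row with no preceding property", i)
      target <- if (nzchar(link)) link else if (nzchar(value)) value else name
      m <- attach_resource(m, last_property,
                           resource_link(target, "supplementary",
                                         media_hint = if (nzchar(name)) name))
      next
    }
    id <- legacy_id(name, names(m$nodes))
    fields <- list()
    if (nzchar(value)) fields$value <- value
    links <- if (nzchar(link)) list(resource_link(link, "resource")) else list()
    m <- add_node(m, im_node(id, directive$kind, label = name,
                             fields = fields, links = links))
    if (directive$kind == "Instance") {
      if (!is.null(last_instance))
        m <- add_edge(m, last_instance, id)
      last_instance <- id
      last_property <- NULL
    } else if (directive$kind %in% c("Material", "Medium")) {
      if (!is.null(last_instance))
        m <- add_edge(m, id, last_instance)
    } else {  # property row
      if (!is.null(last_instance))
        m <- add_edge(m, last_instance, id)
      last_property <- id
    }
  }
  m
}
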