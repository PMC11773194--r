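# The instance-map graph document: nodes, directed edges, annotation regions,
# resource links, cross-map links, and map/node metadata. All constructors are
# pure: they return an updated copy of the map, and no construction call can
# yield a map violating the structural invariants (unique node ids, no
# dangling edge endpoints or region members).

IM_ID_RE <- "^[A-Za-z0-9_.-]+$"

im_check_id <- function(id, what = "node id") {
  if (length(id) != 1L || is.na(id) || !grepl(IM_ID_RE, id))
    im_stop("E_BAD_ID", "malformed %s: %s", what,
            paste(as.character(id), collapse = ", "))
  id
}

IM_META_FIELDS <- c("description", "keywords", "version", "created",
                    "licence", "contributors", "references")

# Shared metadata block for maps and nodes: free-text description, keywords,
# version, ISO-8601 creation date, licence, contributors, references.
im_meta <- function(description = NULL, keywords = NULL, version = NULL,
                    created = NULL, licence = NULL, contributors = NULL,
                    references = NULL) {
  if (!is.null(created)) {
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}", created) &&
      !is.na(as.Date(substr(created, 1, 10), format = "%Y-%m-%d"))
    if (!ok)
      im_stop("E_BAD_DATE", "created is not an ISO-8601 date: %s", created)
  }
  aslist <- function(x)
    if (is.null(x)) NULL else unname(lapply(unlist(x), as.character))
  m <- list(description = description, keywords = aslist(keywords),
            version = version, created = created, licence = licence,
            contributors = aslist(contributors),
            references = aslist(references))
  m[!vapply(m, is.null, TRUE)]
}

#' Resource link attached to a node
#'
#' A pointer (URL or relative path) from a node to an external resource: a
#' protocol document, SOP, ELN page, raw-data file, supplementary image, etc.
#' Links are stored opaquely; their content is never fetched or parsed.
#'
#' @param target Non-empty URL or relative path.
#' @param role Identifier naming the link's role (e.g. \code{"protocol"},
#'   \code{"sop"}, \code{"raw_data"}, \code{"supplementary"},
#'   \code{"eln_page"}). Roles participate in completeness scoring.
#' @param media_hint Optional free-text hint about the resource format.
#' @return An object of class \code{im_resource_link}.
#' @export
resource_link <- function(target, role, media_hint = NULL) {
  if (length(target) != 1L || is.na(target) || !nzchar(target))
    im_stop("E_BAD_ID", "resource link target must be a non-empty string")
  im_check_id(role, "resource link role")
  structure(list(target = target, role = role, media_hint = media_hint),
            class = "im_resource_link")
}

#' Create an instance-map node
#'
#' @param id Stable identifier matching \code{[A-Za-z0-9_.-]+}; caller-supplied
#'   so that nodes keep their identity across map versions (needed for
#'   [map_diff()]).
#' @param kind A registered node kind (see [builtin_taxonomy()]).
#' @param label Human-readable label; defaults to the id.
#' @param meta Optional named list of node metadata (description, keywords,
#'   version, created, licence, contributors, references).
#' @param fields Named list of structured metadata values, e.g.
#'   \code{list(medium_volume = "900 mL")}. Field names participate in
#'   completeness scoring.
#' @param links List of [resource_link()] objects.
#' @param colour_override Optional colour string overriding the category
#'   default for presentation. Overrides never affect validation.
#' @param taxonomy Taxonomy used to check the kind.
#' @return An object of class \code{im_node}.
#' @export
im_node <- function(id, kind, label = id, meta = list(), fields = list(),
                    links = list(), colour_override = NULL,
                    taxonomy = builtin_taxonomy()) {
  im_check_id(id)
  if (length(kind) != 1L || !kind %in% names(taxonomy))
    im_stop("E_UNKNOWN_KIND", "unknown node kind: %s",
            paste(as.character(kind), collapse = ", "))
  if (length(fields) && (is.null(names(fields)) || any(!nzchar(names(fields)))))
    im_stop("E_BAD_ID", "node fields must be a named list")
  fields <- if (length(fields)) as.list(fields) else list()
  links <- lapply(links, function(l) {
    if (!inherits(l, "im_resource_link"))
      l <- do.call(resource_link, l)
    l
  })
  structure(list(id = id, kind = kind, label = label,
                 meta = do.call(im_meta, as.list(meta)),
                 fields = fields, links = links,
                 colour_override = colour_override),
            class = "im_node")
}

#' Create a directed edge
#'
#' Edge direction encodes flow and time: for instance-to-instance edges the
#' source precedes the target. The triple (source, target, label) is the
#' edge's identity within a map.
#'
#' @param source,target Node ids (must exist in the map when added).
#' @param label Optional free-text label.
#' @return An object of class \code{im_edge}.
#' @export
im_edge <- function(source, target, label = NULL) {
  im_check_id(source, "edge source")
  im_check_id(target, "edge target")
  structure(list(source = source, target = target, label = label),
            class = "im_edge")
}

#' Create an annotation region
#'
#' Regions highlight an area of a map (e.g. the phases of a synthesis, or the
#' sections of a multi-study workflow). Regions may overlap.
#'
#' @param id Region identifier.
#' @param label Human-readable label.
#' @param members Character vector of member node ids.
#' @param colour Optional colour string.
#' @return An object of class \code{im_region}.
#' @export
im_region <- function(id, label = id, members = character(), colour = NULL) {
  im_check_id(id, "region id")
  structure(list(id = id, label = label,
                 members = sort(unique(as.character(members))),
                 colour = colour),
            class = "im_region")
}

#' Create a cross-map link
#'
#' Links a local node to a node in another map (e.g. a chronic-test exposure
#' concentration determined from an acute test's dose-response curve).
#' Resolution is deferred: maps travel separately, so an unresolvable target
#' is a warning, never an error (see [resolve_links()]).
#'
#' @param source_node Local node id.
#' @param target_map Id of the target map.
#' @param target_node Node id within the target map.
#' @param relation Free-text description of the relation.
#' @return An object of class \code{im_map_link}.
#' @export
im_map_link <- function(source_node, target_map, target_node, relation = "") {
  im_check_id(source_node, "map-link source node")
  im_check_id(target_map, "map-link target map")
  im_check_id(target_node, "map-link target node")
  structure(list(source_node = source_node, target_map = target_map,
                 target_node = target_node, relation = relation),
            class = "im_map_link")
}

#' Create an empty instance map
#'
#' An instance map is a directed, usually acyclic and often tree-like graph
#' whose main branches are consecutive instances (a material in its medium at
#' a moment in time), with side branches for materials, media, protocols,
#' properties and data.
#'
#' @param id Map identifier.
#' @param meta Optional named list of map metadata.
#' @return An object of class \code{instance_map}.
#' @examples
#' m <- new_map("culture", meta = list(description = "running culture"))
#' m <- add_node(m, im_node("medium1", "Medium", "high hardness medium"))
#' @export
new_map <- function(id, meta = list()) {
  im_check_id(id, "map id")
  structure(list(id = id, meta = do.call(im_meta, as.list(meta)),
                 nodes = structure(list(), names = character(0)),
                 edges = list(), regions = list(), map_links = list()),
            class = "instance_map")
}

#' Add a node to a map
#'
#' @param map An [new_map()] instance map.
#' @param node An [im_node()] object.
#' @return The updated map.
#' @export
add_node <- function(map, node) {
  stopifnot(inherits(map, "instance_map"))
  if (!inherits(node, "im_node"))
    im_stop("E_BAD_ID", "add_node expects an im_node object")
  if (node$id %in% names(map$nodes))
    im_stop("E_DUP_NODE", "duplicate node id: %s", node$id)
  map$nodes[[node$id]] <- node
  # maps are kept in canonical order (nodes by id, edges by source/target/label)
  # at all times, so serialisation is byte-stable and round trips are identities
  map$nodes <- map$nodes[order(names(map$nodes), method = "radix")]
  map
}

#' Add an edge to a map
#'
#' @param map An instance map.
#' @param edge An [im_edge()], or the source node id when \code{target} given.
#' @param target,label Optional shorthand: \code{add_edge(m, "a", "b")}.
#' @return The updated map.
#' @export
add_edge <- function(map, edge, target = NULL, label = NULL) {
  stopifnot(inherits(map, "instance_map"))
  if (!inherits(edge, "im_edge"))
    edge <- im_edge(edge, target, label)
  for (ep in c(edge$source, edge$target))
    if (!ep %in% names(map$nodes))
      im_stop("E_DANGLING", "edge endpoint not in map: %s", ep)
  key <- function(e) paste(e$source, e$target, e$label %||% "", sep = "\r")
  if (key(edge) %in% vapply(map$edges, key, ""))
    im_stop("E_DUP_EDGE", "duplicate edge: %s -> %s", edge$source, edge$target)
  map$edges[[length(map$edges) + 1L]] <- edge
  map$edges <- map$edges[order(vapply(map$edges, key, ""), method = "radix")]
  map
}

#' Add an annotation region to a map
#'
#' @param map An instance map.
#' @param region An [im_region()] object; all members must exist in the map.
#' @return The updated map.
#' @export
add_region <- function(map, region) {
  stopifnot(inherits(map, "instance_map"), inherits(region, "im_region"))
  missing <- setdiff(region$members, names(map$nodes))
  if (length(missing))
    im_stop("E_DANGLING", "region member not in map: %s",
            paste(missing, collapse = ", "))
  if (region$id %in% vapply(map$regions, `[[`, "", "id"))
    im_stop("E_DUP_NODE", "duplicate region id: %s", region$id)
  map$regions[[length(map$regions) + 1L]] <- region
  map$regions <- map$regions[order(vapply(map$regions, `[[`, "", "id"),
                                   method = "radix")]
  map
}

#' Attach a resource link to a node
#'
#' @param map An instance map.
#' @param node_id Id of an existing node.
#' @param link A [resource_link()] object.
#' @return The updated map.
#' @export
attach_resource <- function(map, node_id, link) {
  stopifnot(inherits(map, "instance_map"))
  if (!node_id %in% names(map$nodes))
    im_stop("E_DANGLING", "no such node: %s", node_id)
  if (!inherits(link, "im_resource_link"))
    link <- do.call(resource_link, link)
  n <- map$nodes[[node_id]]
  n$links[[length(n$links) + 1L]] <- link
  map$nodes[[node_id]] <- n
  map
}

#' Add a cross-map link
#'
#' @param map An instance map.
#' @param map_link An [im_map_link()]; its source node must exist locally.
#' @return The updated map.
#' @export
add_map_link <- function(map, map_link) {
  stopifnot(inherits(map, "instance_map"), inherits(map_link, "im_map_link"))
  if (!map_link$source_node %in% names(map$nodes))
    im_stop("E_DANGLING", "map-link source node not in map: %s",
            map_link$source_node)
  map$map_links[[length(map$map_links) + 1L]] <- map_link
  mk <- vapply(map$map_links, function(l)
    paste(l$source_node, l$target_map, l$target_node, l$relation, sep = "\r"), "")
  map$map_links <- map$map_links[order(mk, method = "radix")]
  map
}

#' Effective display colour of a node
#'
#' The node's explicit colour override if set, otherwise the default colour of
#' its kind's category. Overrides are purely presentational: re-colouring a
#' node (a common planning trick, e.g. flagging undecided steps in data-red)
#' never changes validation outcomes.
#'
#' @param node An [im_node()].
#' @param taxonomy Taxonomy providing category colours.
#' @return A colour string.
#' @export
effective_colour <- function(node, taxonomy = builtin_taxonomy()) {
  if (!is.null(node$colour_override)) return(node$colour_override)
  spec <- taxonomy[[node$kind]]
  if (is.null(spec))
    im_stop("E_UNKNOWN_KIND", "unknown node kind: %s", node$kind)
  spec$colour
}

# --- small accessors used across modules ------------------------------------

node_kinds <- function(map) vapply(map$nodes, `[[`, "", "kind")

#' Nodes of a given kind
#'
#' @param map An instance map.
#' @param kind A node-kind name.
#' @return Character vector of node ids, in insertion order.
#' @export
nodes_of_kind <- function(map, kind) {
  names(map$nodes)[node_kinds(map) == kind]
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map '%s'> %d nodes, %d edges, %d regions, %d map links\n",
              x$id, length(x$nodes), length(x$edges), length(x$regions),
              length(x$map_links)))
  if (length(x$nodes)) {
    tab <- table(node_kinds(x))
    cat("  nodes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarise an instance map
#'
#' Node counts per kind and category, and the fraction of nodes carrying at
#' least one resource link (resource coverage).
#'
#' @param object An instance map.
#' @param ... Unused.
#' @return A list of class \code{summary.instance_map} with elements
#'   \code{id}, \code{n_nodes}, \code{n_edges}, \code{by_kind},
#'   \code{by_category}, \code{resource_coverage}.
#' @export
summary.instance_map <- function(object, ...) {
  kinds <- node_kinds(object)
  cats <- unname(IM_KIND_CATEGORY[kinds])
  linked <- vapply(object$nodes, function(n) length(n$links) > 0L, TRUE)
  structure(list(
    id = object$id,
    n_nodes = length(object$nodes),
    n_edges = length(object$edges),
    n_regions = length(object$regions),
    n_map_links = length(object$map_links),
    by_kind = if (length(kinds)) table(kinds) else table(character()),
    by_category = if (length(cats)) table(cats) else table(character()),
    resource_coverage = if (length(linked)) mean(linked) else NA_real_
  ), class = "summary.instance_map")
}

#' @export
print.summary.instance_map <- function(x, ...) {
  cat(sprintf("Instance map '%s': %d nodes, %d edges, %d regions, %d map links\n",
              x$id, x$n_nodes, x$n_edges, x$n_regions, x$n_map_links))
  if (x$n_nodes) {
    cat("Nodes per kind:\n")
    for (k in names(x$by_kind))
      cat(sprintf("  %-26s %d\n", k, x$by_kind[[k]]))
    cat("Nodes per category:\n")
    for (k in names(x$by_category))
      cat(sprintf("  %-26s %d\n", k, x$by_category[[k]]))
    cat(sprintf("Resource coverage: %.2f\n", x$resource_coverage))
  }
  invisible(x)
}
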