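# Map diffing/versioning, cross-map link resolution and submap merging.
# Diff granularity is field-level for nodes (matched by their stable ids) and
# identity-level for edges, regions and map links: an edge's only payload is
# its label, and the label participates in edge identity, so "modified edge"
# is not a meaningful category.

node_diff_fields <- c("kind", "label", "meta", "fields", "links",
                      "colour_override")

edge_key <- function(e) paste(e$source, e$target, e$label %||% "", sep = "\r")
region_key <- function(r) r$id
maplink_key <- function(l)
  paste(l$source_node, l$target_map, l$target_node, l$relation, sep = "\r")

im_keyed_diff <- function(a, b, keyfun) {
  ka <- vapply(a, keyfun, "")
  kb <- vapply(b, keyfun, "")
  list(added = b[!kb %in% ka], removed = a[!ka %in% kb])
}

#' Difference between two map versions
#'
#' Nodes are matched by id; for nodes present in both maps, changed fields
#' are enumerated deterministically (sorted by field name) with their old and
#' new values. Edges, regions and map links are compared by identity.
#' Antisymmetry holds: \code{map_diff(a, b)$added_nodes} equals
#' \code{map_diff(b, a)$removed_nodes}.
#'
#' @param a,b Instance maps (old and new version).
#' @param annotation Optional free-text note recording the reason for the
#'   deviation; stored on the diff, not interpreted.
#' @return An object of class \code{im_map_diff}.
#' @export
map_diff <- function(a, b, annotation = NULL) {
  stopifnot(inherits(a, "instance_map"), inherits(b, "instance_map"))
  ids_a <- names(a$nodes); ids_b <- names(b$nodes)
  common <- intersect(ids_a, ids_b)
  modified <- list()
  for (id in sort(common)) {
    na <- a$nodes[[id]]; nb <- b$nodes[[id]]
    changes <- list()
    for (f in sort(node_diff_fields)) {
      if (!identical(na[[f]], nb[[f]]))
        changes[[length(changes) + 1L]] <-
          list(field = f, old = na[[f]], new = nb[[f]])
    }
    if (length(changes)) modified[[id]] <- changes
  }
  meta_changed <- !identical(a$meta, b$meta)
  out <- structure(list(
    added_nodes = sort(setdiff(ids_b, ids_a)),
    removed_nodes = sort(setdiff(ids_a, ids_b)),
    modified_nodes = modified,
    edges = im_keyed_diff(a$edges, b$edges, edge_key),
    regions = im_keyed_diff(a$regions, b$regions, region_key),
    map_links = im_keyed_diff(a$map_links, b$map_links, maplink_key),
    meta_changed = meta_changed,
    new_meta = if (meta_changed) b$meta,
    id_changed = !identical(a$id, b$id),
    new_id = if (!identical(a$id, b$id)) b$id,
    annotation = annotation
  ), class = "im_map_diff")
  # full payload of added nodes rides along as an attribute so the internal
  # patch helper can reconstruct b; the public surface reports ids only
  attr(out, "added_node_payload") <- unname(b$nodes[out$added_nodes])
  out
}

#' Is a diff empty?
#'
#' @param diff An [map_diff()] result.
#' @return TRUE iff the two maps were identical.
#' @export
diff_is_empty <- function(diff) {
  !diff$meta_changed && !isTRUE(diff$id_changed) &&
    !length(diff$added_nodes) && !length(diff$removed_nodes) &&
    !length(diff$modified_nodes) &&
    !length(diff$edges$added) && !length(diff$edges$removed) &&
    !length(diff$regions$added) && !length(diff$regions$removed) &&
    !length(diff$map_links$added) && !length(diff$map_links$removed)
}

#' Render a diff as a JSON changeset
#'
#' @param diff An [map_diff()] result.
#' @return A JSON string.
#' @export
diff_to_json <- function(diff) {
  strip <- function(x) lapply(x, unclass)
  doc <- list(
    added_nodes = as.list(diff$added_nodes),
    removed_nodes = as.list(diff$removed_nodes),
    modified_nodes = lapply(diff$modified_nodes, function(chs)
      lapply(chs, function(ch) list(field = ch$field, old = ch$old,
                                    new = ch$new))),
    added_edges = strip(diff$edges$added),
    removed_edges = strip(diff$edges$removed),
    added_regions = strip(diff$regions$added),
    removed_regions = strip(diff$regions$removed),
    added_map_links = strip(diff$map_links$added),
    removed_map_links = strip(diff$map_links$removed),
    meta_changed = diff$meta_changed
  )
  if (!is.null(diff$annotation)) doc$annotation <- diff$annotation
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"))
}

#' @export
print.im_map_diff <- function(x, ...) {
  if (diff_is_empty(x)) {
    cat("No differences\n")
    return(invisible(x))
  }
  if (length(x$added_nodes))
    cat("+ nodes:", paste(x$added_nodes, collapse = ", "), "\n")
  if (length(x$removed_nodes))
    cat("- nodes:", paste(x$removed_nodes, collapse = ", "), "\n")
  for (id in names(x$modified_nodes)) {
    cat("~ node", id, "\n")
    for (ch in x$modified_nodes[[id]])
      cat(sprintf("    %s: %s -> %s\n", ch$field,
                  paste(deparse(ch$old, nlines = 1L), collapse = ""),
                  paste(deparse(ch$new, nlines = 1L), collapse = "")))
  }
  fmt_edge <- function(e) sprintf("%s->%s%s", e$source, e$target,
                                  if (is.null(e$label)) "" else
                                    sprintf(" [%s]", e$label))
  for (e in x$edges$added) cat("+ edge:", fmt_edge(e), "\n")
  for (e in x$edges$removed) cat("- edge:", fmt_edge(e), "\n")
  for (r in x$regions$added) cat("+ region:", r$id, "\n")
  for (r in x$regions$removed) cat("- region:", r$id, "\n")
  for (l in x$map_links$added)
    cat("+ map link:", l$source_node, "->", l$target_map, "\n")
  for (l in x$map_links$removed)
    cat("- map link:", l$source_node, "->", l$target_map, "\n")
  if (x$meta_changed) cat("~ map metadata changed\n")
  if (!is.null(x$annotation)) cat("note:", x$annotation, "\n")
  invisible(x)
}

# Internal: apply a diff to its base map, reconstructing the target version.
# Used to test the patch property; not part of the public surface.
im_apply_diff <- function(a, diff) {
  b <- a
  for (id in diff$removed_nodes) b$nodes[[id]] <- NULL
  rm_keys <- vapply(diff$edges$removed, edge_key, "")
  b$edges <- b$edges[!vapply(b$edges, edge_key, "") %in% rm_keys]
  rm_r <- vapply(diff$regions$removed, region_key, "")
  b$regions <- b$regions[!vapply(b$regions, region_key, "") %in% rm_r]
  rm_l <- vapply(diff$map_links$removed, maplink_key, "")
  b$map_links <- b$map_links[!vapply(b$map_links, maplink_key, "") %in% rm_l]
  for (id in names(diff$modified_nodes))
    for (ch in diff$modified_nodes[[id]])
      b$nodes[[id]][[ch$field]] <- ch$new
  for (e in diff$edges$added) b <- add_edge_unchecked(b, e)
  for (r in diff$regions$added) b$regions <- c(b$regions, list(r))
  for (l in diff$map_links$added) b$map_links <- c(b$map_links, list(l))
  if (diff$meta_changed) b$meta <- diff$new_meta
  if (isTRUE(diff$id_changed)) b$id <- diff$new_id
  # added nodes come from the target version; the diff carries only their ids,
  # so im_apply_diff is defined for diffs produced with keep_payload = TRUE
  for (n in attr(diff, "added_node_payload") %||% list())
    b$nodes[[n$id]] <- n
  b$nodes <- b$nodes[order(names(b$nodes), method = "radix")]
  b$edges <- b$edges[order(vapply(b$edges, edge_key, ""), method = "radix")]
  b$regions <- b$regions[order(vapply(b$regions, region_key, ""),
                               method = "radix")]
  b$map_links <- b$map_links[order(vapply(b$map_links, maplink_key, ""),
                                   method = "radix")]
  b
}

add_edge_unchecked <- function(map, edge) {
  map$edges[[length(map$edges) + 1L]] <- edge
  map
}

#' A workspace of instance maps
#'
#' @param ... Instance maps (or a single list of them). Map ids must be
#'   unique; they key the workspace.
#' @return An object of class \code{im_workspace}.
#' @export
workspace <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1]], "instance_map"))
    maps <- maps[[1]]
  stopifnot(all(vapply(maps, inherits, TRUE, "instance_map")))
  ids <- vapply(maps, `[[`, "", "id")
  if (anyDuplicated(ids))
    im_stop("E_ID_COLLISION", "duplicate map id in workspace: %s",
            paste(ids[duplicated(ids)], collapse = ", "))
  names(maps) <- ids
  structure(list(maps = maps), class = "im_workspace")
}

#' Resolve cross-map links in a workspace
#'
#' A link resolves iff its target map is in the workspace and the target node
#' exists in that map. Unresolved links are reported at warning status, never
#' as errors: maps travel separately, and a link may point at a map that is
#' simply not loaded.
#'
#' @param ws An [workspace()].
#' @return A data frame with one row per cross-map link: \code{map},
#'   \code{source_node}, \code{target_map}, \code{target_node},
#'   \code{relation}, \code{status} (\code{"resolved"}/\code{"unresolved"})
#'   and \code{detail}.
#' @export
resolve_links <- function(ws) {
  stopifnot(inherits(ws, "im_workspace"))
  rows <- list()
  for (m in ws$maps) {
    for (l in m$map_links) {
      tm <- ws$maps[[l$target_map]]
      if (is.null(tm)) {
        status <- "unresolved"; detail <- "target map not in workspace"
      } else if (!l$target_node %in% names(tm$nodes)) {
        status <- "unresolved"; detail <- "target node not in target map"
      } else {
        status <- "resolved"; detail <- ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        map = m$id, source_node = l$source_node, target_map = l$target_map,
        target_node = l$target_node, relation = l$relation,
        status = status, detail = detail, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(map = character(), source_node = character(),
                      target_map = character(), target_node = character(),
                      relation = character(), status = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Merge several maps into one
#'
#' Takes the union of nodes, edges, regions and cross-map links. With
#' \code{id_prefixing = TRUE} every node id becomes
#' \code{"<map id>.<node id>"}, and cross-map links between the merged maps
#' are rewritten as ordinary edges labelled with the link relation; links to
#' maps outside the merge stay cross-map links (with rewritten source ids).
#' Without prefixing the node id sets must be pairwise disjoint.
#'
#' @param maps A list of instance maps.
#' @param id_prefixing Prefix node ids with their source map id?
#' @param id Id of the merged map.
#' @return An instance map.
#' @export
merge_maps <- function(maps, id_prefixing = FALSE, id = "merged") {
  stopifnot(is.list(maps), length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "instance_map")))
  all_ids <- unlist(lapply(maps, function(m) names(m$nodes)))
  if (!id_prefixing && anyDuplicated(all_ids))
    im_stop("E_ID_COLLISION", "node id collision in merge: %s",
            paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  merged_map_ids <- vapply(maps, `[[`, "", "id")
  pid <- function(map, node_id)
    if (id_prefixing) paste(map$id, node_id, sep = ".") else node_id
  out <- new_map(id)
  for (m in maps)
    for (n in m$nodes) {
      n$id <- pid(m, n$id)
      out <- add_node(out, n)
    }
  for (m in maps) {
    for (e in m$edges)
      out <- add_edge(out, im_edge(pid(m, e$source), pid(m, e$target), e$label))
    for (r in m$regions)
      out <- add_region(out, im_region(
        if (id_prefixing) paste(m$id, r$id, sep = ".") else r$id,
        label = r$label,
        members = vapply(r$members, function(v) pid(m, v), ""),
        colour = r$colour))
    for (l in m$map_links) {
      if (l$target_map %in% merged_map_ids) {
        tgt_map <- maps[[match(l$target_map, merged_map_ids)]]
        out <- add_edge(out, im_edge(pid(m, l$source_node),
                                     pid(tgt_map, l$target_node),
                                     label = if (nzchar(l$relation)) l$relation))
      } else {
        out <- add_map_link(out, im_map_link(pid(m, l$source_node),
                                             l$target_map, l$target_node,
                                             l$relation))
      }
    }
  }
  out
}
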