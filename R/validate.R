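# Structural validation under configurable profiles, instance-backbone
# extraction, measurement-chain checking and completeness scoring.
#
# The strict profile's adjacency whitelist is a deliberate design choice: the
# instance-map format itself never fixed connection rules, and real maps of
# the same study legitimately differ in how the measurement chain
# (sample preparation -> measurement -> raw data -> data processing ->
# processed data) is placed relative to the measured property. The whitelist
# therefore admits both arrangements, and disallowed pairs are warnings, not
# errors: only dangling references and cycles (time must move forward along
# instance edges) are errors in either profile.

IM_STRICT_ADJACENCY <- local({
  props <- c("CuratedProperty", "ComputedProperty", "ExperimentalProperty")
  adj <- list(
    Material = c("Instance", props),
    Medium = c("Instance", props),
    Instance = c("Instance", "TransformationProtocol",
                 "SamplePreparationProtocol", props),
    TransformationProtocol = c("Instance"),
    SamplePreparationProtocol = c("MeasurementProtocol"),
    MeasurementProtocol = c("RawData"),
    RawData = c("DataProcessingProtocol", props),
    DataProcessingProtocol = c("ProcessedData"),
    ProcessedData = props,
    CuratedProperty = c("SamplePreparationProtocol"),
    ComputedProperty = c("SamplePreparationProtocol"),
    ExperimentalProperty = c("SamplePreparationProtocol")
  )
  adj
})

# Expected order of stages in the measurement chain, used by rule R4.
IM_CHAIN_ORDER <- c(SamplePreparationProtocol = 1, MeasurementProtocol = 2,
                    RawData = 3, DataProcessingProtocol = 4, ProcessedData = 5)

#' Validation profile
#'
#' A profile bundles an adjacency whitelist (which source-kind to target-kind
#' edges are considered standard) with per-rule severity overrides. Two
#' built-ins exist: \code{"lenient"} (any connection allowed; non-standard
#' pairs are reported at info level) and \code{"strict"} (non-standard pairs
#' and misordered measurement chains are warnings). Cycles and dangling
#' references are errors under both, because instance order encodes time.
#'
#' @param name \code{"strict"} or \code{"lenient"}.
#' @param adjacency Optional replacement adjacency whitelist: named list,
#'   source kind -> character vector of allowed target kinds.
#' @param severity_overrides Named list mapping rule ids (\code{"R1"} ...
#'   \code{"R6"}) to \code{"error"}, \code{"warning"} or \code{"info"}.
#' @return An object of class \code{im_profile}.
#' @export
validation_profile <- function(name = c("strict", "lenient"),
                               adjacency = NULL,
                               severity_overrides = list()) {
  name <- match.arg(name)
  base <- list(
    R1 = "error",                                     # dangling reference
    R2 = "error",                                     # directed cycle
    R3 = if (name == "strict") "warning" else "info", # non-whitelist adjacency
    R4 = if (name == "strict") "warning" else "info", # misordered chain
    R5 = "info",                                      # unattached Material/Medium
    R6 = "warning"                                    # empty map
  )
  bad <- setdiff(names(severity_overrides), names(base))
  if (length(bad))
    im_stop("E_UNKNOWN_RULE", "unknown rule id: %s", paste(bad, collapse = ", "))
  for (r in names(severity_overrides)) {
    sev <- severity_overrides[[r]]
    if (!sev %in% c("error", "warning", "info"))
      im_stop("E_BAD_SEVERITY", "invalid severity for %s: %s", r, sev)
    base[[r]] <- sev
  }
  structure(list(name = name,
                 adjacency = adjacency %||% IM_STRICT_ADJACENCY,
                 severities = base),
            class = "im_profile")
}

#' Load a validation profile from a config file
#'
#' Reads a YAML or JSON file with optional keys \code{name},
#' \code{adjacency} (mapping source kind to list of allowed target kinds) and
#' \code{severity_overrides} (rule id to severity), enabling
#' community-specific rule sets.
#'
#' @param path Path to a YAML or JSON file.
#' @return An [validation_profile()] object.
#' @export
profile_from_config <- function(path) {
  cfg <- tryCatch(
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) im_stop("E_SCHEMA", "cannot parse profile config %s: %s",
                                path, conditionMessage(e)))
  adjacency <- if (!is.null(cfg$adjacency))
    lapply(cfg$adjacency, function(x) as.character(unlist(x)))
  validation_profile(name = cfg$name %||% "strict",
                     adjacency = adjacency,
                     severity_overrides = cfg$severity_overrides %||% list())
}

im_adjacency_list <- function(map) {
  adj <- lapply(map$nodes, function(n) character(0))
  for (e in map$edges)
    adj[[e$source]] <- c(adj[[e$source]], e$target)
  adj
}

#' Test a map for directed cycles
#'
#' Instance maps encode time along their edges, so a directed cycle is always
#' a structural defect. Uses iterative removal of sources (Kahn's algorithm);
#' when a cycle exists, a witness cycle is recovered by walking the leftover
#' subgraph.
#'
#' @param map An instance map.
#' @return A list with \code{acyclic} (logical) and \code{witness} (character
#'   vector of node ids forming a cycle, or \code{NULL}).
#' @export
is_acyclic <- function(map) {
  ids <- names(map$nodes)
  if (!length(ids)) return(list(acyclic = TRUE, witness = NULL))
  adj <- im_adjacency_list(map)
  # dangling endpoints are rule R1's business; ignore those edges here
  adj <- lapply(adj, function(ws) ws[ws %in% ids])
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (ws in adj) for (w in ws) indeg[[w]] <- indeg[[w]] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(ids)) return(list(acyclic = TRUE, witness = NULL))
  # witness: the unprocessed nodes contain every cycle plus nodes merely
  # downstream of one; strip nodes without successors in the set until only
  # cycle members remain, then walk until a node repeats
  left <- names(indeg)[indeg > 0L]
  repeat {
    keep <- vapply(left, function(v) any(adj[[v]] %in% left), TRUE)
    if (all(keep)) break
    left <- left[keep]
  }
  v <- left[[1]]
  path <- character(0)
  repeat {
    if (v %in% path) {
      cyc <- path[which(path == v)[1]:length(path)]
      return(list(acyclic = FALSE, witness = cyc))
    }
    path <- c(path, v)
    v <- intersect(adj[[v]], left)[[1]]
  }
}

# Instance-level condensed graph: direct Instance->Instance edges plus
# Instance->TransformationProtocol->Instance two-step connections.
im_instance_graph <- function(map) {
  inst <- nodes_of_kind(map, "Instance")
  kinds <- node_kinds(map)
  adj <- im_adjacency_list(map)
  succ <- stats::setNames(vector("list", length(inst)), inst)
  for (v in inst) {
    direct <- adj[[v]][kinds[adj[[v]]] == "Instance"]
    via_tp <- unlist(lapply(adj[[v]][kinds[adj[[v]]] == "TransformationProtocol"],
                            function(tp) adj[[tp]][kinds[adj[[tp]]] == "Instance"]))
    succ[[v]] <- sort(unique(c(direct, via_tp)))
  }
  succ
}

#' Extract the instance backbone of a map
#'
#' The main branches of an instance map are formed by consecutive instances.
#' This returns the maximal directed paths in the subgraph induced by Instance
#' nodes, where two instances are connected either directly or through a
#' single intervening TransformationProtocol. Paths start at instances with no
#' instance-level predecessor and follow edge direction; at branch points each
#' maximal path is reported. Enumeration order is deterministic (ids sorted at
#' every choice point).
#'
#' @param map An acyclic instance map.
#' @return A list of character vectors, each an ordered chain of Instance ids.
#' @export
extract_backbone <- function(map) {
  acy <- is_acyclic(map)
  if (!acy$acyclic)
    im_stop("E_CYCLIC", "map contains a directed cycle: %s",
            paste(acy$witness, collapse = " -> "))
  succ <- im_instance_graph(map)
  inst <- names(succ)
  if (!length(inst)) return(list())
  has_pred <- unique(unlist(succ))
  roots <- sort(setdiff(inst, has_pred))
  if (!length(roots)) roots <- sort(inst)  # isolated safety; acyclic => roots exist
  chains <- list()
  walk <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (!length(nxt)) {
      chains[[length(chains) + 1L]] <<- path
    } else {
      for (w in nxt) walk(c(path, w))
    }
  }
  for (r in roots) walk(r)
  chains
}

im_issue <- function(rule_id, severity, ref, message) {
  structure(list(rule_id = rule_id, severity = severity, ref = ref,
                 message = message),
            class = "im_issue")
}

#' Validate an instance map
#'
#' Applies the structural rules:
#' \describe{
#'   \item{R1}{dangling references (edge endpoints, region members or
#'     map-link sources naming absent nodes) — error.}
#'   \item{R2}{directed cycles — error under both profiles, because instance
#'     order encodes time.}
#'   \item{R3}{edge whose (source kind, target kind) pair is outside the
#'     profile's adjacency whitelist — warning under strict, info under
#'     lenient.}
#'   \item{R4}{misordered measurement chain, e.g. RawData feeding its own
#'     MeasurementProtocol — warning under strict, info under lenient.}
#'   \item{R5}{Material or Medium node not attached to anything — info. The
#'     format leaves open whether such nodes must belong to an instance, so
#'     they are only noticed, never rejected.}
#'   \item{R6}{empty map — warning.}
#' }
#' Problems are returned as issues, never thrown.
#'
#' @param map An instance map.
#' @param profile An [validation_profile()]; default strict.
#' @return An object of class \code{im_validation_report} with \code{issues}
#'   (list) and \code{passed} (TRUE iff no error-severity issues).
#' @export
validate_map <- function(map, profile = validation_profile("strict")) {
  stopifnot(inherits(map, "instance_map"), inherits(profile, "im_profile"))
  sev <- profile$severities
  issues <- list()
  push <- function(rule, ref, msg) {
    issues[[length(issues) + 1L]] <<- im_issue(rule, sev[[rule]], ref, msg)
  }
  ids <- names(map$nodes)
  kinds <- node_kinds(map)

  # R6: empty map
  if (!length(ids)) push("R6", map$id, "map has no nodes")

  # R1: dangling references (defensive: construction API prevents these, but
  # hand-edited documents may not come through it)
  for (i in seq_along(map$edges)) {
    e <- map$edges[[i]]
    for (ep in c(e$source, e$target))
      if (!ep %in% ids)
        push("R1", sprintf("edge[%d] %s->%s", i, e$source, e$target),
             sprintf("edge endpoint '%s' does not exist", ep))
  }
  for (r in map$regions) {
    missing <- setdiff(r$members, ids)
    for (mm in missing)
      push("R1", sprintf("region %s", r$id),
           sprintf("region member '%s' does not exist", mm))
  }
  for (ml in map$map_links)
    if (!ml$source_node %in% ids)
      push("R1", sprintf("map-link to %s", ml$target_map),
           sprintf("map-link source '%s' does not exist", ml$source_node))

  # R2: cycles
  acy <- is_acyclic(map)
  if (!acy$acyclic)
    push("R2", paste(acy$witness, collapse = " -> "),
         "directed cycle: edges must follow the direction of time")

  # R3 + R4 per edge with known endpoints
  for (i in seq_along(map$edges)) {
    e <- map$edges[[i]]
    if (!all(c(e$source, e$target) %in% ids)) next
    ks <- kinds[[e$source]]; kt <- kinds[[e$target]]
    allowed <- profile$adjacency[[ks]]
    if (!kt %in% allowed)
      push("R3", sprintf("edge[%d] %s->%s", i, e$source, e$target),
           sprintf("non-standard connection %s -> %s", ks, kt))
    if (ks %in% names(IM_CHAIN_ORDER) && kt %in% names(IM_CHAIN_ORDER) &&
        IM_CHAIN_ORDER[[ks]] > IM_CHAIN_ORDER[[kt]])
      push("R4", sprintf("edge[%d] %s->%s", i, e$source, e$target),
           sprintf(paste("measurement chain out of order: %s precedes %s, but",
                         "the stages run sample preparation, measurement,",
                         "raw data, data processing, processed data"), ks, kt))
  }

  # R5: unattached Material/Medium
  touched <- unique(unlist(lapply(map$edges, function(e) c(e$source, e$target))))
  for (v in ids[kinds %in% c("Material", "Medium")])
    if (!v %in% touched)
      push("R5", v, sprintf("%s node '%s' is not attached to any instance",
                            kinds[[v]], v))

  n_err <- sum(vapply(issues, function(x) x$severity == "error", TRUE))
  structure(list(issues = issues, passed = n_err == 0L,
                 profile = profile$name),
            class = "im_validation_report")
}

#' @export
print.im_validation_report <- function(x, ...) {
  cat(sprintf("Validation (%s profile): %s, %d issue(s)\n", x$profile,
              if (x$passed) "PASSED" else "FAILED", length(x$issues)))
  for (iss in x$issues)
    cat(sprintf("  [%s/%s] %s: %s\n", iss$rule_id, iss$severity, iss$ref,
                iss$message))
  invisible(x)
}

#' Completeness of a map against the taxonomy's requirement slots
#'
#' For every node, each requirement slot of its kind is satisfied iff the node
#' carries a metadata field whose name, or an attached resource link whose
#' role, is in the slot's \code{satisfied_by} set. Satisfaction is assessed
#' per node: several nodes pointing at the same shared file each satisfy their
#' own slots independently. Node scores are \code{satisfied / required}; the
#' map score is their mean.
#'
#' @param map An instance map.
#' @param taxonomy Taxonomy providing requirement slots.
#' @return An object of class \code{im_completeness_report} with
#'   \code{per_node} (named list with \code{satisfied}, \code{missing},
#'   \code{score}) and \code{map_score}.
#' @export
completeness <- function(map, taxonomy = builtin_taxonomy()) {
  stopifnot(inherits(map, "instance_map"))
  unknown <- setdiff(unique(node_kinds(map)), names(taxonomy))
  if (length(unknown))
    im_stop("E_UNKNOWN_KIND", "unknown node kind: %s",
            paste(unknown, collapse = ", "))
  per_node <- lapply(map$nodes, function(n) {
    slots <- taxonomy[[n$kind]]$requirement_slots
    have <- c(names(n$fields), vapply(n$links, `[[`, "", "role"))
    sat <- vapply(slots, function(s) any(s$satisfied_by %in% have), TRUE)
    list(satisfied = vapply(slots[sat], `[[`, "", "slot_id"),
         missing = vapply(slots[!sat], `[[`, "", "slot_id"),
         score = if (length(slots)) mean(sat) else 1)
  })
  scores <- vapply(per_node, `[[`, 0, "score")
  structure(list(per_node = per_node,
                 map_score = if (length(scores)) mean(scores) else NA_real_),
            class = "im_completeness_report")
}

#' @export
print.im_completeness_report <- function(x, ...) {
  cat(sprintf("Completeness: map score %.2f over %d node(s)\n",
              x$map_score, length(x$per_node)))
  for (id in names(x$per_node)) {
    pn <- x$per_node[[id]]
    cat(sprintf("  %-20s %.2f", id, pn$score))
    if (length(pn$missing))
      cat("  missing: ", paste(pn$missing, collapse = ", "), sep = "")
    cat("\n")
  }
  invisible(x)
}
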