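# Independent oracles and small construction helpers shared across tests.

# Brute-force cycle detector over a plain edge list: for every node, depth-
# first search for a path that returns to it. Deliberately naive and
# independent of the package's Kahn-based implementation.
brute_force_has_cycle <- function(node_ids, edges) {
  succ <- function(v) unlist(lapply(edges, function(e)
    if (e[[1]] == v) e[[2]] else NULL))
  reaches <- function(from, to, seen = character()) {
    for (w in succ(from)) {
      if (w == to) return(TRUE)
      if (!w %in% seen && reaches(w, to, c(seen, from))) return(TRUE)
    }
    FALSE
  }
  any(vapply(node_ids, function(v) reaches(v, v), TRUE))
}

# Exhaustive enumeration of all orderings of `ids` consistent with the given
# precedence pairs (list of c(before, after)); used as the backbone oracle.
all_topological_orders <- function(ids, pairs) {
  if (!length(ids)) return(list(character(0)))
  out <- list()
  for (v in ids) {
    blocked <- any(vapply(pairs, function(p)
      p[[2]] == v && p[[1]] %in% ids, TRUE))
    if (!blocked) {
      rest <- all_topological_orders(setdiff(ids, v), pairs)
      for (r in rest) out[[length(out) + 1L]] <- c(v, r)
    }
  }
  out
}

# Random digraph as an instance map: n nodes, each ordered pair carries an
# edge with probability p. May contain cycles; kinds are irrelevant to
# acyclicity, so all nodes are Instances.
random_digraph_map <- function(seed, n, p = 0.25) {
  set.seed(seed)
  m <- new_map(sprintf("digraph_%d", seed))
  ids <- sprintf("n%02d", seq_len(n))
  for (id in ids) m <- add_node(m, im_node(id, "Instance"))
  for (a in ids) for (b in ids) {
    if (a != b && stats::runif(1) < p) m <- add_edge(m, a, b)
  }
  m
}

edge_pairs <- function(map) lapply(map$edges, function(e) c(e$source, e$target))

# Tiny three-instance chain used by several tests.
chain_map <- function() {
  m <- new_map("chain")
  for (id in c("a", "b", "c")) m <- add_node(m, im_node(id, "Instance"))
  m <- add_edge(m, "a", "b")
  add_edge(m, "b", "c")
}
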