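test_that("acyclicity matches a brute-force DFS oracle on small digraphs", {
  m <- chain_map()
  expect_true(is_acyclic(m)$acyclic)
  m2 <- add_edge(m, "c", "a")
  res <- is_acyclic(m2)
  expect_false(res$acyclic)
  expect_setequal(res$witness, c("a", "b", "c"))
  for (seed in 1:60) {
    n <- 2 + (seed %% 7)  # up to 8 nodes
    g <- random_digraph_map(seed, n, p = 0.3)
    expect_equal(is_acyclic(g)$acyclic,
                 !brute_force_has_cycle(names(g$nodes), edge_pairs(g)),
                 info = sprintf("seed %d", seed))
    res <- is_acyclic(g)
    if (!res$acyclic) {
      # witness really is a cycle
      w <- res$witness
      for (i in seq_along(w)) {
        a <- w[i]; b <- w[if (i == length(w)) 1L else i + 1L]
        expect_true(any(vapply(g$edges, function(e)
          e$source == a && e$target == b, TRUE)))
      }
    }
  }
})

test_that("acyclicity agrees with igraph's DAG test", {
  skip_if_not_installed("igraph")
  for (seed in 101:130) {
    g <- random_digraph_map(seed, 3 + seed %% 5, p = 0.3)
    el <- do.call(rbind, lapply(g$edges, function(e) c(e$source, e$target)))
    ig <- igraph::graph_from_data_frame(as.data.frame(el),
                                        vertices = names(g$nodes))
    expect_equal(is_acyclic(g)$acyclic, igraph::is_dag(ig),
                 info = sprintf("seed %d", seed))
  }
})

test_that("backbone extraction follows instance chains through transformations", {
  expect_equal(extract_backbone(new_map("empty")), list())
  m <- new_map("nb")
  m <- add_node(m, im_node("p1", "ExperimentalProperty"))
  expect_equal(extract_backbone(m), list())
  # chain via a TransformationProtocol counts as consecutive instances
  m <- chain_map()
  m <- add_node(m, im_node("tp", "TransformationProtocol"))
  m <- add_node(m, im_node("d", "Instance"))
  m <- add_edge(m, "c", "tp")
  m <- add_edge(m, "tp", "d")
  expect_equal(extract_backbone(m), list(c("a", "b", "c", "d")))
  cyc <- add_edge(chain_map(), "c", "a")
  expect_error(extract_backbone(cyc), class = "E_CYCLIC")
})

test_that("backbone equals the exhaustive ordering oracle on random chains", {
  for (seed in c(3, 11, 27, 101)) {
    m <- random_map(seed, n_instances = 5, branch_prob = 0.7)
    inst <- nodes_of_kind(m, "Instance")
    pairs <- Filter(function(p) all(p %in% inst), edge_pairs(m))
    orders <- all_topological_orders(inst, pairs)
    # the generator backbone is a single path: its topological order is unique
    expect_length(orders, 1L)
    expect_equal(extract_backbone(m), orders)
  }
})

test_that("validation rules fire with profile-dependent severities", {
  strict <- validation_profile("strict")
  lenient <- validation_profile("lenient")

  # R6 empty map
  r <- validate_map(new_map("empty"), strict)
  expect_true(r$passed)
  expect_equal(r$issues[[1]]$rule_id, "R6")

  # R1 dangling edge (bypassing the construction API, as a hand-edited
  # document would)
  m <- chain_map()
  m$edges[[length(m$edges) + 1L]] <- im_edge("c", "ghost")
  r <- validate_map(m, strict)
  expect_false(r$passed)
  expect_true(any(vapply(r$issues, function(i)
    i$rule_id == "R1" && grepl("ghost", i$message), TRUE)))

  # R2 cycle is an error under both profiles
  cyc <- add_edge(chain_map(), "c", "a")
  expect_false(validate_map(cyc, strict)$passed)
  expect_false(validate_map(cyc, lenient)$passed)

  # R3 non-whitelisted adjacency: warning under strict, info under lenient
  m <- new_map("adj")
  m <- add_node(m, im_node("rd", "RawData"))
  m <- add_node(m, im_node("i", "Instance"))
  m <- add_edge(m, "rd", "i")
  sev_of <- function(map, prof, rule) {
    hits <- Filter(function(i) i$rule_id == rule,
                   validate_map(map, prof)$issues)
    vapply(hits, `[[`, "", "severity")
  }
  expect_equal(sev_of(m, strict, "R3"), "warning")
  expect_equal(sev_of(m, lenient, "R3"), "info")
  expect_true(validate_map(m, strict)$passed)

  # R4 misordered measurement chain, e.g. RawData feeding MeasurementProtocol
  m <- new_map("chain4")
  m <- add_node(m, im_node("rd", "RawData"))
  m <- add_node(m, im_node("mp", "MeasurementProtocol"))
  m <- add_edge(m, "rd", "mp")
  r4 <- Filter(function(i) i$rule_id == "R4",
               validate_map(m, strict)$issues)
  expect_length(r4, 1L)
  expect_equal(r4[[1]]$severity, "warning")
  expect_match(r4[[1]]$message, "sample preparation, measurement")

  # R5 unattached material at info level
  m <- add_node(new_map("m5"), im_node("mat", "Material"))
  r5 <- Filter(function(i) i$rule_id == "R5",
               validate_map(m, strict)$issues)
  expect_length(r5, 1L)
  expect_equal(r5[[1]]$severity, "info")
})

test_that("validation is pure and lenient severities never exceed strict", {
  rank <- c(info = 1, warning = 2, error = 3)
  for (seed in 1:15) {
    m <- random_digraph_map(seed, 5, p = 0.3)
    r1 <- validate_map(m, validation_profile("strict"))
    r2 <- validate_map(m, validation_profile("strict"))
    expect_identical(r1, r2)
    rs <- validate_map(m, validation_profile("strict"))$issues
    rl <- validate_map(m, validation_profile("lenient"))$issues
    # same rules fire under both profiles...
    expect_equal(vapply(rl, `[[`, "", "rule_id"),
                 vapply(rs, `[[`, "", "rule_id"))
    # ...and lenient severity is never above strict severity
    expect_true(all(rank[vapply(rl, `[[`, "", "severity")] <=
                    rank[vapply(rs, `[[`, "", "severity")]))
  }
})

test_that("profiles load from YAML config with severity overrides", {
  cfg <- system.file("extdata", "profile-example.yaml",
                     package = "instancemaps")
  prof <- profile_from_config(cfg)
  expect_equal(prof$severities$R3, "error")
  m <- new_map("adj")
  m <- add_node(m, im_node("rd", "RawData"))
  m <- add_node(m, im_node("i", "Instance"))
  m <- add_edge(m, "rd", "i")
  expect_false(validate_map(m, prof)$passed)
  expect_error(validation_profile("strict",
                                  severity_overrides = list(R9 = "error")),
               class = "E_UNKNOWN_RULE")
})

test_that("completeness scores slots per node and is monotone in links", {
  tax <- builtin_taxonomy()
  m <- new_map("c")
  m <- add_node(m, im_node("med", "Medium",
                           fields = list(recipe = "ISO medium")))
  m <- add_node(m, im_node("mat", "Material"))
  rep <- completeness(m, tax)
  expect_equal(rep$per_node$med$score, 1)
  expect_equal(rep$per_node$mat$score, 0)
  expect_equal(rep$per_node$mat$missing, "characterisation")
  expect_equal(rep$map_score, 0.5)
  # adding a satisfying link never decreases any score
  m2 <- attach_resource(m, "mat", resource_link("tem.pdf", "characterisation"))
  rep2 <- completeness(m2, tax)
  for (id in names(rep$per_node))
    expect_gte(rep2$per_node[[id]]$score, rep$per_node[[id]]$score)
  expect_equal(rep2$per_node$mat$score, 1)
  # invariant under relabelling
  m3 <- m
  m3$nodes$med$label <- "renamed"
  expect_equal(completeness(m3, tax)$map_score, rep$map_score)
})
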