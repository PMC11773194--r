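test_that("diff of identical maps is empty; single changes are localised", {
  m <- build_fixture("oecd202")
  expect_true(diff_is_empty(map_diff(m, m)))

  b <- add_node(m, im_node("extra", "CuratedProperty"))
  d <- map_diff(m, b)
  expect_equal(d$added_nodes, "extra")
  expect_length(d$removed_nodes, 0L)
  expect_length(d$modified_nodes, 0L)
  expect_length(d$edges$added, 0L)

  # antisymmetry
  expect_equal(map_diff(b, m)$removed_nodes, d$added_nodes)

  b2 <- m
  b2$nodes$mat_stock$label <- "renamed stock"
  d2 <- map_diff(m, b2)
  expect_equal(names(d2$modified_nodes), "mat_stock")
  expect_length(d2$modified_nodes$mat_stock, 1L)
  ch <- d2$modified_nodes$mat_stock[[1]]
  expect_equal(ch$field, "label")
  expect_equal(ch$old, "Nanomaterial stock suspension")
  expect_equal(ch$new, "renamed stock")
})

test_that("applying a diff to its base reconstructs the target exactly", {
  for (seed in c(2, 5, 8, 13)) {
    a <- random_map(seed, n_instances = 4, branch_prob = 0.6)
    b <- random_map(seed + 100, n_instances = 5, branch_prob = 0.4)
    expect_identical(instancemaps:::im_apply_diff(a, map_diff(a, b)), b)
    expect_identical(instancemaps:::im_apply_diff(b, map_diff(b, a)), a)
  }
  # also across hand-made edits touching every part
  a <- build_fixture("oecd211")
  b <- a
  b$nodes$med_211$fields$recipe <- "revised medium"
  b$nodes$inst_adults <- NULL
  b$edges <- Filter(function(e) e$source != "inst_adults", b$edges)
  b <- add_node(b, im_node("note", "CuratedProperty", "deviation note"))
  b <- add_region(b, im_region("changed", members = "note"))
  expect_identical(instancemaps:::im_apply_diff(a, map_diff(a, b)), b)
})

test_that("diff renders as a JSON changeset", {
  a <- build_fixture("oecd202")
  b <- add_node(a, im_node("extra", "CuratedProperty"))
  js <- jsonlite::fromJSON(diff_to_json(map_diff(a, b, annotation = "why")),
                           simplifyVector = FALSE)
  expect_equal(unlist(js$added_nodes), "extra")
  expect_equal(js$annotation, "why")
  expect_false(js$meta_changed)
})

test_that("cross-map links resolve exactly when their target is loaded", {
  acute <- build_fixture("oecd202")
  chronic <- build_fixture("oecd211")
  res <- resolve_links(workspace(acute, chronic))
  expect_equal(nrow(res), 1L)
  expect_equal(res$status, "resolved")
  expect_equal(res$target_node, "pd_dose_response")

  res2 <- resolve_links(workspace(chronic))
  expect_equal(res2$status, "unresolved")
  expect_match(res2$detail, "target map")

  expect_equal(nrow(resolve_links(workspace(acute))), 0L)
})

test_that("merge unions maps and rewrites internal cross-map links", {
  acute <- build_fixture("oecd202")
  chronic <- build_fixture("oecd211")

  # identity modulo prefixing
  m1 <- merge_maps(list(acute))
  expect_equal(names(m1$nodes), names(acute$nodes))
  expect_length(m1$edges, length(acute$edges))

  merged <- merge_maps(list(acute, chronic), id_prefixing = TRUE)
  expect_length(merged$nodes, length(acute$nodes) + length(chronic$nodes))
  expect_true("oecd202.pd_dose_response" %in% names(merged$nodes))
  # the cross-map link became an ordinary edge and nothing is left to resolve
  expect_length(merged$map_links, 0L)
  expect_true(any(vapply(merged$edges, function(e)
    e$source == "oecd211.mat_stock211" &&
      e$target == "oecd202.pd_dose_response", TRUE)))
  expect_equal(nrow(resolve_links(workspace(merged))), 0L)

  # collision without prefixing is an error
  expect_error(merge_maps(list(acute, acute)), class = "E_ID_COLLISION")

  # associativity up to prefixing for disjoint maps
  r1 <- random_map(1, 2, 0)
  r2 <- random_map(2, 2, 0)
  r2 <- merge_maps(list(r2), id = "r2b")  # rename to keep map ids distinct
  r3 <- random_map(3, 2, 0)
  # disjoint node ids required: prefix each map's ids via single-map merges
  p <- function(m) merge_maps(list(m), id_prefixing = TRUE, id = m$id)
  r1 <- p(r1); r2 <- p(r2); r3 <- p(r3)
  left <- merge_maps(list(merge_maps(list(r1, r2), id = "ab"), r3))
  right <- merge_maps(list(r1, merge_maps(list(r2, r3), id = "bc")))
  expect_equal(names(left$nodes), names(right$nodes))
  expect_equal(left$edges, right$edges)
})
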