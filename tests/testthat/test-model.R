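test_that("construction API enforces ids, uniqueness and endpoint existence", {
  m <- new_map("t")
  expect_error(add_edge(m, "a", "b"), class = "E_DANGLING")
  m <- add_node(m, im_node("a", "Instance"))
  expect_error(add_node(m, im_node("a", "Material")), class = "E_DUP_NODE")
  expect_error(im_node("bad id!", "Instance"), class = "E_BAD_ID")
  expect_error(im_node("x", "NotAKind"), class = "E_UNKNOWN_KIND")
  expect_error(add_region(m, im_region("r", members = "ghost")),
               class = "E_DANGLING")
  expect_error(attach_resource(m, "ghost", resource_link("x", "sop")),
               class = "E_DANGLING")
  m <- attach_resource(m, "a", resource_link("sop.md", "sop"))
  expect_length(m$nodes$a$links, 1L)
  expect_error(resource_link("", "sop"), class = "E_BAD_ID")
  expect_error(im_node("x", "Instance", meta = list(created = "not-a-date")),
               class = "E_BAD_DATE")
})

test_that("random construction sequences never violate map invariants", {
  check_invariants <- function(m) {
    ids <- names(m$nodes)
    expect_false(anyDuplicated(ids) > 0)
    for (e in m$edges) expect_true(all(c(e$source, e$target) %in% ids))
    for (r in m$regions) expect_true(all(r$members %in% ids))
    keys <- vapply(m$edges, function(e)
      paste(e$source, e$target, e$label %||% "", sep = "\r"), "")
    expect_false(anyDuplicated(keys) > 0)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  set.seed(7)
  for (rep in 1:10) {
    m <- new_map("prop")
    kinds <- names(builtin_taxonomy())
    for (step in 1:40) {
      op <- sample(c("node", "edge", "region", "link"), 1,
                   prob = c(0.4, 0.4, 0.1, 0.1))
      res <- try(switch(op,
        node = add_node(m, im_node(sprintf("n%d", sample(1:20, 1)),
                                   sample(kinds, 1))),
        edge = if (length(m$nodes) >= 2) {
          ab <- sample(names(m$nodes), 2)
          add_edge(m, ab[1], ab[2])
        } else m,
        region = if (length(m$nodes) >= 1)
          add_region(m, im_region(sprintf("r%d", step),
                                  members = sample(names(m$nodes),
                                                   min(3, length(m$nodes)))))
          else m,
        link = if (length(m$nodes) >= 1)
          attach_resource(m, sample(names(m$nodes), 1),
                          resource_link("f.csv", "raw_data"))
          else m), silent = TRUE)
      if (!inherits(res, "try-error")) m <- res
      check_invariants(m)
    }
  }
})

test_that("effective colour honours overrides and category defaults", {
  tax <- builtin_taxonomy()
  raw <- im_node("rd", "RawData")
  expect_equal(effective_colour(raw, tax), tax$RawData$colour)
  expect_equal(effective_colour(im_node("i", "Instance",
                                        colour_override = "#ff0000"), tax),
               "#ff0000")
  # total over all registered kinds
  for (k in names(tax))
    expect_match(effective_colour(im_node("x", k), tax), "^#")
  # overrides are presentation only: validation identical with and without
  m1 <- chain_map()
  m2 <- m1
  m2$nodes$b$colour_override <- "#ff0000"
  r1 <- validate_map(m1, validation_profile("strict"))
  r2 <- validate_map(m2, validation_profile("strict"))
  expect_identical(r1$issues, r2$issues)
  expect_identical(r1$passed, r2$passed)
})

test_that("summary reports counts per kind and resource coverage", {
  m <- build_fixture("daphnia_culture")
  s <- summary(m)
  expect_equal(s$n_nodes, length(m$nodes))
  expect_equal(sum(s$by_kind), s$n_nodes)
  expect_equal(sum(s$by_category), s$n_nodes)
  linked <- sum(vapply(m$nodes, function(n) length(n$links) > 0, TRUE))
  expect_equal(s$resource_coverage, linked / s$n_nodes)
})
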