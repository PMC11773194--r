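test_that("every example map is deterministic, valid and serialisable", {
  for (f in fixture_names()) {
    m <- build_fixture(f)
    expect_identical(build_fixture(f), m, label = f)
    rep <- validate_map(m, validation_profile("lenient"))
    expect_true(rep$passed, label = paste(f, "lenient validation"))
    expect_true(is_acyclic(m)$acyclic, label = f)
    expect_identical(from_document(to_document(m)), m, label = f)
  }
  expect_error(build_fixture("unknown"), class = "E_UNKNOWN_FIXTURE")
})

test_that("sulfidation map has the synthesis chain and tracked variants", {
  m <- build_fixture("sulfidation")
  # the synthesis phase comprises three consecutive instances
  synth <- Filter(function(r) r$id == "phase_synthesis", m$regions)[[1]]
  synth_instances <- intersect(synth$members, nodes_of_kind(m, "Instance"))
  expect_length(synth_instances, 3L)
  # backbone chains all start with that synthesis sequence
  bb <- extract_backbone(m)
  for (chain in bb) expect_equal(chain[1:3], c("syn1", "syn2", "syn3"))
  # one transformation protocol per sulfidation concentration
  tps <- nodes_of_kind(m, "TransformationProtocol")
  expect_length(tps, 3L)
  # tracked nanoparticle variants: sulfidation protocols + the pristine one
  variants <- nodes_of_kind(m, "Material")
  expect_length(variants, length(tps) + 1L)
})

test_that("daphnia culture map carries the printed culture parameters", {
  m <- build_fixture("daphnia_culture")
  med <- m$nodes$med_hh
  expect_equal(med$kind, "Medium")
  expect_equal(med$fields$medium_volume, "900 mL")
  expect_equal(med$fields$vessel, "1 L")
  cult <- m$nodes$cult
  expect_equal(cult$fields$adults, "10-15")
  expect_equal(cult$fields$temperature, "20 °C")
  expect_equal(cult$fields$photoperiod, "16:8")
  # the culture log rides on the raw-data node and ships with the package
  log_links <- m$nodes$rd_log$links
  expect_equal(log_links[[1]]$role, "raw_data")
  csv <- system.file("extdata", log_links[[1]]$target,
                     package = "instancemaps")
  expect_true(nzchar(csv))
  log <- utils::read.csv(csv)
  expect_equal(nrow(log), 16L)
  expect_true(all(c("food_ml", "medium_change") %in% names(log)))
})

test_that("test-guideline maps end in processed data and cross-link", {
  acute <- build_fixture("oecd202")
  pd <- nodes_of_kind(acute, "ProcessedData")
  expect_length(pd, 1L)
  # terminal: the dose-response node has no outgoing edge
  expect_false(any(vapply(acute$edges, function(e) e$source == pd, TRUE)))
  expect_equal(validate_map(acute, validation_profile("strict"))$issues, list())

  chronic <- build_fixture("oecd211")
  expect_length(chronic$map_links, 1L)
  expect_equal(chronic$map_links[[1]]$target_map, "oecd202")
})

test_that("immunotox regions A-E and planning colour overrides are present", {
  im <- build_fixture("immunotox")
  expect_equal(vapply(im$regions, `[[`, "", "id"), c("A", "B", "C", "D", "E"))
  expect_true(all(vapply(im$regions, function(r) length(r$members) > 0, TRUE)))

  pl <- build_fixture("macrame_planning")
  expect_gte(length(nodes_of_kind(pl, "TransformationProtocol")), 2L)
  overridden <- Filter(function(n) !is.null(n$colour_override), pl$nodes)
  expect_gte(length(overridden), 2L)
  # the override borrows the data-category red on non-data kinds
  tax <- builtin_taxonomy()
  for (n in overridden) {
    expect_equal(effective_colour(n, tax), tax$RawData$colour)
    expect_false(n$kind %in% c("RawData", "ProcessedData"))
  }
})

test_that("random maps are seed-deterministic, acyclic and valid", {
  expect_length(random_map(1, 0, 0.5)$nodes, 0L)
  expect_identical(random_map(42, 5, 0.5), random_map(42, 5, 0.5))
  for (seed in 1:40) {
    m <- random_map(seed, n_instances = seed %% 6, branch_prob = 0.5)
    expect_true(is_acyclic(m)$acyclic)
    expect_true(validate_map(m, validation_profile("lenient"))$passed)
  }
  # generator restores the caller's RNG state
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(random_map(7, 3, 0.5)); after <- runif(1)
  expect_identical(before, after)
})
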