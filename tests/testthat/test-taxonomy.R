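test_that("registry has twelve kinds partitioned into the four categories", {
  tax <- builtin_taxonomy()
  expect_length(tax, 12L)
  cats <- vapply(tax, `[[`, "", "category")
  expect_setequal(unique(cats),
                  c("instance-family", "protocol", "property", "data"))
  members <- split(names(tax), cats)
  expect_setequal(members$`instance-family`, c("Instance", "Material", "Medium"))
  expect_setequal(members$protocol,
                  c("TransformationProtocol", "SamplePreparationProtocol",
                    "MeasurementProtocol", "DataProcessingProtocol"))
  expect_setequal(members$property,
                  c("CuratedProperty", "ComputedProperty", "ExperimentalProperty"))
  expect_setequal(members$data, c("RawData", "ProcessedData"))
  # partition: every kind in exactly one category member set
  expect_equal(sort(unlist(members, use.names = FALSE)), sort(names(tax)))
  # registry is deterministic across calls
  expect_identical(builtin_taxonomy(), tax)
})

test_that("every kind has non-empty requirement slots with unique slot ids", {
  tax <- builtin_taxonomy()
  for (kind in names(tax)) {
    slots <- requirements_for(kind, tax)
    expect_gt(length(slots), 0)
    ids <- vapply(slots, `[[`, "", "slot_id")
    expect_false(anyDuplicated(ids) > 0)
    expect_true(all(vapply(slots, function(s) length(s$satisfied_by) > 0, TRUE)))
  }
  medium_labels <- vapply(requirements_for("Medium"), `[[`, "", "label")
  expect_true(any(grepl("recipe of medium", medium_labels)))
  raw_labels <- vapply(requirements_for("RawData"), `[[`, "", "label")
  expect_true(any(grepl("first set of data", raw_labels)))
  expect_error(requirements_for("Widget"), class = "E_UNKNOWN_KIND")
})

test_that("legacy vocabulary maps totally onto the taxonomy", {
  legacy <- c("instance", "material", "medium", "property", "supplementary")
  expect_length(legacy, 5L)
  expect_equal(map_legacy("instance")$kind, "Instance")
  expect_equal(map_legacy("material")$kind, "Material")
  expect_equal(map_legacy("medium")$kind, "Medium")
  expect_equal(map_legacy("property")$kind, "CuratedProperty")
  expect_equal(map_legacy("property", "ExperimentalProperty")$kind,
               "ExperimentalProperty")
  supp <- map_legacy("supplementary")
  expect_equal(supp$type, "attachment")
  expect_equal(supp$role, "supplementary")
  expect_error(map_legacy("widget"), class = "E_UNKNOWN_LEGACY_TERM")
  expect_error(map_legacy("property", "RawData"), class = "E_UNKNOWN_KIND")
})

test_that("taxonomy exports as a JSON reference document", {
  doc <- jsonlite::fromJSON(taxonomy_document(), simplifyVector = FALSE)
  expect_length(doc, 12L)
  expect_equal(doc$Medium$category, "instance-family")
  expect_match(doc$Medium$requirement_slots[[1]]$label, "recipe of medium")
  expect_true(all(vapply(doc, function(d) grepl("^#", d$colour), TRUE)))
})
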