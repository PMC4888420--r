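test_that("validate reports structural issues as data", {
  m <- tiny_model()
  expect_identical(nrow(validate_model(m)), 0L)

  m_bad <- m
  m_bad$items[["IT.3"]]$codelist_ref <- "CL.MISSING"
  issues <- validate_model(m_bad)
  expect_identical(issues$rule, "dangling-ref")
  expect_match(issues$message, "CL.MISSING")

  m_range <- m
  m_range$items[["IT.1"]]$range_min <- 10
  m_range$items[["IT.1"]]$range_max <- 5
  expect_identical(validate_model(m_range)$rule, "range-order")

  m_dup <- m
  m_dup$items[[4]] <- odm_item("IT.1", "Duplicate")
  expect_true("duplicate-oid" %in% validate_model(m_dup)$rule)

  # every model of the demonstration corpus is valid
  for (mod in make_table1_fixture()) {
    expect_identical(nrow(validate_model(mod)), 0L)
  }
})

test_that("set_annotation replaces signatures on items and code-list entries", {
  m <- tiny_model(annotate_height = FALSE)
  m <- set_annotation(m, "IT.1", "C0005890")
  ann <- extract_annotations(m)
  expect_identical(ann$signature[ann$owner_oid == "IT.1"], "C0005890")

  # idempotent: setting the same signature twice changes nothing
  expect_identical(set_annotation(m, "IT.1", "C0005890"), m)

  # replace, not merge
  m2 <- set_annotation(m, "IT.1", c("C0489786"))
  expect_identical(m2$items[["IT.1"]]$annotation, "C0489786")

  # code-list entry via pseudo-OID
  m3 <- set_annotation(m, "CL.BP/LA", "C1522565")
  ann3 <- extract_annotations(m3)
  entry_row <- ann3[ann3$owner_kind == "codelist_entry", ]
  expect_identical(entry_row$owner_oid, "CL.BP/LA")
  expect_identical(entry_row$name, "left arm")

  expect_odmsem_error(set_annotation(m, "IT.999", "C0005890"), "lookup")
})

test_that("extract_annotations lists annotated items and entries only", {
  m <- tiny_model() # 1 of 3 items annotated, no entries
  ann <- extract_annotations(m)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$owner_kind, "item")

  m_entries <- tiny_model(annotate_height = FALSE)
  m_entries <- set_annotation(m_entries, "CL.BP/LA", "C1522565")
  m_entries <- set_annotation(m_entries, "CL.BP/RA", "C1522566")
  ann2 <- extract_annotations(m_entries)
  expect_identical(unique(ann2$owner_kind), "codelist_entry")
  expect_identical(nrow(ann2), 2L)

  # demonstration corpus: total rows equal the sum of its occurrence counts
  total <- sum(vapply(make_table1_fixture(),
                      function(x) nrow(extract_annotations(x)), integer(1)))
  expect_identical(total, 86L + 85L + 66L + 29L + 37L)
})

test_that("coverage counts items plus code-list entries", {
  m <- tiny_model(annotate_height = FALSE) # 3 items + 2 entries
  expect_equal(coverage(m), 0)
  expect_equal(coverage(set_annotation(m, "IT.2", "C0005910")), 1 / 5)
  m_all <- m
  for (oid in c("IT.1", "IT.2", "IT.3", "CL.BP/LA", "CL.BP/RA")) {
    m_all <- set_annotation(m_all, oid, "C0005890")
  }
  expect_equal(coverage(m_all), 1)
  expect_equal(coverage(odm_model("EMPTYISH", items = list(odm_item("A", "a")))), 0)
  # no targets at all: defined as fully covered
  expect_equal(coverage(odm_model("NONE")), 1)
})
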