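test_that("propose_all covers exactly the unannotated targets", {
  vocab <- make_toy_vocabulary()
  idx <- build_index(height_corpus())

  fully <- height_corpus()[[1]] # single, annotated item
  expect_identical(length(propose_all(fully, idx, vocab)), 0L)

  m <- tiny_model(annotate_height = FALSE) # 3 items + 2 entries unannotated
  props <- propose_all(m, idx, vocab)
  expect_identical(length(props), 5L)
  expect_setequal(names(props), c("IT.1", "IT.2", "IT.3", "CL.BP/LA", "CL.BP/RA"))

  # curated re-use ranked first for a known name
  expect_identical(props[["IT.1"]]$suggestions$origin[1], "repository")
  expect_identical(props[["IT.1"]]$suggestions$signature[1], "C0005890")

  cfg <- annotation_config(count_codelist_entries = FALSE)
  expect_setequal(names(propose_all(m, idx, vocab, cfg)),
                  c("IT.1", "IT.2", "IT.3"))
})

test_that("decisions TSV round-trips and rejects inconsistent rows", {
  df <- data.frame(
    target_oid = c("IT.1", "IT.2", "CL.BP/LA"),
    action = c("reuse", "skip", "postcoordinate"),
    codes = c("C0005890", "", "C0011008+C0027361"),
    note = c("", "no code available", ""),
    stringsAsFactors = FALSE
  )
  expect_identical(read_decisions(text = write_decisions(df)), df)
  expect_identical(nrow(read_decisions(text = "target_oid\taction\tcodes\tnote")), 0L)
  expect_odmsem_error(
    read_decisions(text = "target_oid\taction\tcodes\tnote\nIT.1\treuse\t\t"),
    "format")
  expect_odmsem_error(
    read_decisions(text = "target_oid\taction\tcodes\tnote\nIT.1\tdelete\tC1\t"),
    "format")
})

test_that("apply_decisions sets signatures, feeds the index and tallies actions", {
  vocab <- make_toy_vocabulary()
  corpus <- height_corpus()
  idx <- build_index(corpus)
  m <- tiny_model(annotate_height = FALSE)

  decisions <- data.frame(
    target_oid = c("IT.1", "IT.2", "IT.3", "CL.BP/LA"),
    action = c("reuse", "vocabulary", "skip", "postcoordinate"),
    codes = c("C0005890", "C0005910", "", "C0027361+C0011008"),
    note = "", stringsAsFactors = FALSE
  )
  res <- apply_decisions(m, decisions, idx, vocab)
  expect_identical(unname(res$report$actions),
                   c(1L, 1L, 1L, 1L)) # reuse, vocabulary, postcoordinate, skip
  expect_equal(res$report$coverage_before, 0)
  expect_equal(res$report$coverage_after, 3 / 5)
  expect_identical(res$report$skipped_targets, "IT.3")
  expect_identical(res$model$codelists[["CL.BP"]]$entries$annotation[1],
                   "C0011008+C0027361")

  # the re-used combination is now counted once more
  expect_identical(lookup_exact(res$index, "Height")$count,
                   lookup_exact(idx, "Height")$count + 1L)

  # re-applying the same decisions changes nothing
  res2 <- apply_decisions(res$model, decisions, res$index, vocab)
  expect_identical(res2$model, res$model)
  expect_identical(res2$index, res$index)
  expect_identical(res2$report$coverage_before, res2$report$coverage_after)

  # incrementally updated index equals a from-scratch rebuild
  expect_identical(index_entries(res$index),
                   index_entries(build_index(c(corpus, list(res$model)))))

  expect_odmsem_error(
    apply_decisions(m, data.frame(target_oid = "IT.999", action = "reuse",
                                  codes = "C0005890", note = "",
                                  stringsAsFactors = FALSE), idx, vocab),
    "lookup")

  # reuse of a signature unknown to the index is a warning, not an error
  res3 <- apply_decisions(m, data.frame(target_oid = "IT.2", action = "reuse",
                                        codes = "C0201836", note = "",
                                        stringsAsFactors = FALSE), idx, vocab)
  expect_length(res3$report$warnings, 1L)
  expect_match(res3$report$warnings, "C0201836")
})

test_that("re-use annotation makes the next model inherit the curated code", {
  vocab <- make_toy_vocabulary()
  m1 <- odm_model("D1", items = list(
    odm_item("I1", "Date of Birth", data_type = "date",
             annotation = "C0421451")))
  idx <- build_index(list(m1))
  m2 <- odm_model("D2", items = list(
    odm_item("I1", "date of birth", data_type = "date")))
  top <- propose_all(m2, idx, vocab)[["I1"]]$suggestions[1, ]
  expect_identical(top$origin, "repository")
  res <- apply_decisions(m2, data.frame(target_oid = "I1", action = "reuse",
                                        codes = top$signature, note = "",
                                        stringsAsFactors = FALSE), idx, vocab)
  hit <- lookup_exact(res$index, "Date of Birth")
  expect_identical(hit$signature, "C0421451")
  expect_identical(hit$count, 2L)
})
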