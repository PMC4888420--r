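test_that("build_index counts each annotated occurrence once", {
  corpus <- make_table1_fixture()
  idx <- build_index(corpus)
  df <- index_entries(idx)

  # uniform body weight: a single entry with the full occurrence count
  bw <- df[df$name == "body weight", ]
  expect_identical(nrow(bw), 1L)
  expect_identical(bw$signature, "C0005910")
  expect_identical(bw$count, 86L)

  # count conservation over the whole corpus
  expect_identical(sum(df$count),
                   sum(vapply(corpus, function(m) nrow(extract_annotations(m)),
                              integer(1))))

  # counts match a brute-force recount, entry by entry
  expect_identical(df, oracle_counts(corpus))

  expect_identical(nrow(index_entries(build_index(list()))), 0L)
  expect_odmsem_error(build_index(corpus[c(1, 1)]), "duplicate_model")
})

test_that("build equals folding updates in any corpus order", {
  corpus <- make_table1_fixture(n_models = 6)
  idx <- build_index(corpus)
  set.seed(31)
  for (i in 1:3) {
    perm <- sample(corpus)
    expect_identical(index_entries(build_index(perm)), index_entries(idx))
    folded <- Reduce(update_index, perm, init = term_index())
    expect_identical(index_entries(folded), index_entries(idx))
  }
})

test_that("update_index retracts a model's prior contribution first", {
  corpus <- height_corpus()
  idx <- build_index(corpus)

  # unchanged model: no-op
  expect_identical(update_index(idx, corpus[[1]]), idx)

  # annotate one more element: exactly one count changes
  m <- corpus[[1]]
  m$items[["IT.2"]] <- odm_item("IT.2", "Weight", annotation = "C0005910")
  m$groups[["G.1"]]$item_refs <- c("IT.1", "IT.2")
  idx2 <- update_index(idx, m)
  before <- index_entries(idx)
  after <- index_entries(idx2)
  expect_identical(nrow(after), nrow(before) + 1L)
  expect_identical(after[after$name == "weight", "count"], 1L)
  merged <- merge(before, after, by = c("name", "signature"))
  expect_true(all(merged$count.x == merged$count.y))

  # removing all annotations retracts everything the model contributed
  m_none <- corpus[[1]]
  m_none$items[["IT.1"]]$annotation <- NULL
  idx3 <- update_index(idx, m_none)
  after3 <- index_entries(idx3)
  expect_identical(sum(after3$count), sum(before$count) - 1L)
  expect_true(all(merge(before, after3, by = c("name", "signature"))$count.y <=
                    merge(before, after3, by = c("name", "signature"))$count.x))
})

test_that("lookup_exact orders by count then canonical signature", {
  idx <- build_index(make_table1_fixture())
  dob <- lookup_exact(idx, "Date of Birth")
  expect_identical(dob$count, c(55L, 30L))
  expect_identical(dob$signature, c("C0421451", "C0005615+C0011008+C0027361"))
  expect_identical(nrow(lookup_exact(idx, "no such element")), 0L)

  # tie on counts: lexicographically smaller signature first
  m1 <- odm_model("A", items = list(odm_item("I1", "pulse", annotation = "C0034107")))
  m2 <- odm_model("B", items = list(odm_item("I1", "pulse", annotation = "C0030252")))
  tie <- lookup_exact(build_index(list(m1, m2)), "Pulse")
  expect_identical(tie$signature, c("C0030252", "C0034107"))
})

test_that("form_context resolves every form where a combination occurs", {
  corpus <- height_corpus()
  idx <- build_index(corpus)
  ctx <- form_context(idx, "Height", "C0005890", corpus)
  expect_identical(ctx$model_id, "H1")
  expect_identical(ctx$form_name, "Anthropometry")

  # the same signature under another name has its own context rows
  ctx2 <- form_context(idx, "Body height", "C0005890", corpus)
  expect_identical(ctx2$model_id, "H3")

  t1 <- make_table1_fixture()
  ctx3 <- form_context(build_index(t1), "ALT", "C0001899", t1)
  expect_identical(nrow(ctx3), 7L) # 7 occurrences spread over 7 models
  expect_odmsem_error(form_context(idx, "Height", "C0005890", corpus[2]),
                      "missing_model")
  expect_odmsem_error(form_context(idx, "nope", "C0005890", corpus), "lookup")
})

test_that("index persists as JSON lines and round-trips exactly", {
  idx <- build_index(make_table1_fixture())
  expect_identical(load_index(text = save_index(idx)), idx)

  empty <- term_index()
  expect_identical(load_index(text = save_index(empty)), empty)

  path <- withr::local_tempfile(fileext = ".jsonl")
  save_index(idx, path)
  expect_identical(load_index(path), idx)

  txt <- save_index(idx)
  lines <- strsplit(txt, "\n")[[1]]
  corrupt <- sub('"count":86', '"count":-86', lines)
  expect_odmsem_error(load_index(text = paste(corrupt, collapse = "\n")), "format")
  garbled <- c(lines[1], "{not json", lines[-1])
  err <- tryCatch(load_index(text = paste(garbled, collapse = "\n")),
                  odmsem_format = function(e) e)
  expect_match(conditionMessage(err), "line 2")
})
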