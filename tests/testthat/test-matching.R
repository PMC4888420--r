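test_that("normalize_name lowercases, transliterates and collapses punctuation", {
  expect_identical(normalize_name("Height"), "height")
  expect_identical(normalize_name("Größe (cm)"), "grosse cm")
  expect_identical(normalize_name("  Marker,   Serum  "), "marker serum")
  expect_identical(normalize_name("BP-location/left"), "bp location left")
})

test_that("normalize_name is idempotent on random strings", {
  set.seed(11)
  alphabet <- c(letters, LETTERS, 0:9, " ", "-", "(", ")", ",", ".", "/",
                "ä", "ö", "ü", "ß", "é")
  for (i in 1:50) {
    s <- paste(sample(alphabet, sample(0:30, 1), replace = TRUE), collapse = "")
    n1 <- normalize_name(s)
    expect_identical(normalize_name(n1), n1)
  }
})

test_that("similarity matches the closed form and its hand-computed values", {
  expect_equal(name_similarity("height", "height"), 1)
  expect_equal(name_similarity("", ""), 1)
  # token Jaccard 1/2 = 0.5; normalized Levenshtein 1 - 5/11; max is 6/11
  expect_equal(name_similarity("body weight", "weight"), 6 / 11)
  expect_equal(oracle_similarity("body weight", "weight"), 6 / 11)
  # token reordering is free under Jaccard
  expect_equal(name_similarity("marker serum", "serum marker"), 1)
})

test_that("similarity is symmetric and bounded on random pairs", {
  set.seed(23)
  words <- c("body", "weight", "height", "serum", "marker", "count", "x1")
  for (i in 1:40) {
    a <- normalize_name(paste(sample(words, sample(0:3, 1), replace = TRUE), collapse = " "))
    b <- normalize_name(paste(sample(words, sample(0:3, 1), replace = TRUE), collapse = " "))
    sab <- name_similarity(a, b)
    expect_identical(sab, name_similarity(b, a))
    expect_gte(sab, 0)
    expect_lte(sab, 1)
    expect_equal(sab, oracle_similarity(a, b))
  }
})

test_that("search_similar finds, ranks and thresholds similar names", {
  idx <- build_index(height_corpus())
  hits <- search_similar(idx, "Height", threshold = 0.3, limit = 10)
  expect_setequal(hits$name, c("height", "height of lesion", "body height"))
  expect_identical(hits$name[1], "height") # exact match first
  expect_identical(search_similar(idx, "Height", threshold = 1)$name, "height")
  # ranking agrees with a brute-force sort over all entries
  df <- index_entries(idx)
  df$similarity <- vapply(df$name, oracle_similarity, numeric(1), a = "height")
  df <- df[df$similarity >= 0.3, ]
  df <- df[order(-df$similarity, -df$count, df$signature, df$name), ]
  expect_identical(hits$signature, df$signature)
  expect_identical(hits$similarity, unname(df$similarity))
})

test_that("suggest puts curated repository entries before vocabulary fallback", {
  idx <- build_index(height_corpus())
  vocab <- make_toy_vocabulary()
  sl <- suggest(idx, vocab, "Height")
  expect_identical(sl$suggestions$origin[1], "repository")
  expect_identical(sl$suggestions$signature[1], "C0005890")
  expect_true(all(sl$suggestions$count[sl$suggestions$origin == "repository"] >= 1))
  expect_true(all(sl$suggestions$count[sl$suggestions$origin == "vocabulary"] == 0))
  # no repository suggestion may come after a vocabulary one
  origins <- sl$suggestions$origin
  expect_true(all(diff(match(origins, c("repository", "vocabulary"))) >= 0))

  # empty index: vocabulary offers both height codes
  sl0 <- suggest(term_index(), vocab, "height")
  expect_true(all(c("C0489786", "C0005890") %in% sl0$suggestions$signature))
  expect_true(all(sl0$suggestions$origin == "vocabulary"))

  # nothing known anywhere -> empty list (manual postcoordination needed)
  sl_none <- suggest(term_index(), vocabulary(), "door to balloon time")
  expect_identical(nrow(sl_none$suggestions), 0L)
})

test_that("suggestions are deterministic and threshold-monotonic", {
  idx <- build_index(height_corpus())
  vocab <- make_toy_vocabulary()
  expect_identical(suggest(idx, vocab, "Height"), suggest(idx, vocab, "Height"))
  ths <- c(0, 0.3, 0.6, 0.9, 1)
  n_repo <- vapply(ths, function(t) {
    s <- suggest(idx, vocab, "Height", threshold = t)$suggestions
    sum(s$origin == "repository")
  }, numeric(1))
  expect_true(all(diff(n_repo) <= 0))
})
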