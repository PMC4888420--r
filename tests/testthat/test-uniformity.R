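table1_expected <- function() {
  list("Body weight" = c("C0005910" = 86L),
       "Date of Birth" = c("C0421451" = 55L, "C0005615+C0011008+C0027361" = 30L),
       "Creatinine in Serum" = c("C0201976" = 44L, "C0010294" = 13L, "C0201975" = 9L),
       "Platelets" = c("C0005821" = 13L, "C0942474" = 12L, "C1287267" = 4L),
       "ALT" = c("C0201836" = 30L, "C0001899" = 7L))
}

test_that("grouping reproduces the five-element worked example", {
  rows <- group_elements(make_table1_fixture(), table1_label_map())
  expect_identical(vapply(rows, `[[`, "", "element_label"),
                   names(table1_expected()))
  expect_identical(vapply(rows, `[[`, integer(1), "variant_count"),
                   c(1L, 2L, 3L, 3L, 2L))
  expect_identical(vapply(rows, `[[`, integer(1), "total_occurrences"),
                   c(86L, 85L, 66L, 29L, 37L))
  for (r in rows) {
    exp <- table1_expected()[[r$element_label]]
    expect_identical(r$variants$signature, names(exp))
    expect_identical(r$variants$count, unname(exp))
    expect_identical(sum(r$variants$count), r$total_occurrences)
  }
})

test_that("grouping matches a brute-force recount and conserves occurrences", {
  corpus <- make_table1_fixture()
  rows <- group_elements(corpus, table1_label_map())
  ann <- do.call(rbind, lapply(corpus, extract_annotations))
  for (r in rows) {
    sub <- ann[normalize_name(ann$name) == normalize_name(r$element_label), ]
    tab <- sort(table(sub$signature), decreasing = TRUE)
    expect_identical(sum(r$variants$count), nrow(sub))
    expect_setequal(r$variants$signature, names(tab))
    for (sig in names(tab)) {
      expect_identical(r$variants$count[r$variants$signature == sig],
                       as.integer(tab[[sig]]))
    }
  }
  # every annotated occurrence lands in exactly one row here (full label map)
  expect_identical(sum(vapply(rows, `[[`, integer(1), "total_occurrences")),
                   nrow(ann))
})

test_that("unmatched and unannotated occurrences are kept apart", {
  m <- odm_model("U1", items = list(
    odm_item("I1", "Height", annotation = "C0005890"),
    odm_item("I2", "Height"),                       # unannotated, matches
    odm_item("I3", "Pulse", annotation = "C0034107") # annotated, unmatched
  ))
  rows <- group_elements(list(m), list(Height = "height"))
  expect_identical(rows[[1]]$total_occurrences, 1L)
  expect_identical(rows[[1]]$unannotated_occurrences, 1L)

  expect_odmsem_error(
    group_elements(list(m), list(A = "height", B = c("height", "pulse"))),
    "ambiguous_mapping")

  empty <- group_elements(list(), list(Height = "height"))
  expect_identical(empty[[1]]$variant_count, 0L)
  expect_identical(empty[[1]]$total_occurrences, 0L)
})

test_that("summaries count uniform elements and variant spread", {
  rows <- group_elements(make_table1_fixture(), table1_label_map())
  s <- summarize_uniformity(rows)
  expect_identical(s$uniform_elements, 1L)
  expect_identical(s$max_variant_count, 3L)
  expect_identical(s$n_elements, 5L)
  expect_identical(s$by_variant_count, c("1" = 1L, "2" = 2L, "3" = 2L))
  expect_identical(sum(s$by_variant_count), s$n_elements)

  uni <- summarize_uniformity(group_elements(
    list(odm_model("M", items = list(odm_item("I1", "a", annotation = "C0000001")))),
    list(a = "a")))
  expect_identical(uni$max_variant_count, 1L)
  expect_identical(uni$uniform_elements, 1L)
})

test_that("report renders per-variant lines and TSV re-parses identically", {
  rows <- group_elements(make_table1_fixture(), table1_label_map())
  txt <- report_table(rows, format = "text", vocab = make_toy_vocabulary())
  expect_match(txt, "55x C0421451 Patient date of birth", fixed = TRUE)
  expect_match(txt,
               "30x C0005615 Birth C0011008 Date in time C0027361 Persons",
               fixed = TRUE)

  tsv <- report_table(rows, format = "tsv")
  expect_identical(parse_report_tsv(tsv), rows)

  header_only <- report_table(structure(list(), class = "uniformity_report"),
                              format = "tsv")
  expect_identical(length(strsplit(header_only, "\n")[[1]]), 1L)
  expect_odmsem_error(parse_report_tsv("bad\theader"), "format")
})
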