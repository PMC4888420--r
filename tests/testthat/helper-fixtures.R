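# Shared fixture builders and independent oracles for the test suite.

# A minimal single-form model with three items and one annotated code list.
tiny_model <- function(model_id = "TM1", annotate_height = TRUE) {
  bp_entries <- data.frame(
    coded_value = c("LA", "RA"),
    decode = c("left arm", "right arm"),
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  items <- list(
    odm_item("IT.1", "Height", data_type = "float", range_min = 30, range_max = 250,
             unit = "cm", question = "Body height?", question_lang = "en",
             annotation = if (annotate_height) "C0005890" else NULL),
    odm_item("IT.2", "Weight", data_type = "float"),
    odm_item("IT.3", "BP location", data_type = "string", codelist_ref = "CL.BP")
  )
  odm_model(model_id, "Vital signs study",
            forms = list(odm_form("F.1", "Vital Signs", group_refs = "G.1")),
            groups = list(odm_group("G.1", "Vital Sign",
                                    item_refs = c("IT.1", "IT.2", "IT.3"))),
            items = items,
            codelists = list(odm_codelist("CL.BP", "BP location", bp_entries)))
}

# Small corpus around the name "Height" for similar-name search and context
# review: an exact match, a narrower concept, and a synonymous phrasing.
height_corpus <- function() {
  mk <- function(id, item_name, sig) {
    it <- odm_item("IT.1", item_name, data_type = "float", annotation = sig)
    odm_model(id, paste("Study", id),
              forms = list(odm_form("F.5518", "Anthropometry", group_refs = "G.1")),
              groups = list(odm_group("G.1", "Measures", item_refs = "IT.1")),
              items = list(it))
  }
  list(
    mk("H1", "Height", "C0005890"),
    mk("H2", "Height of lesion", "C0475440"),
    mk("H3", "Body height", "C0005890")
  )
}

# Independent similarity oracle: direct transcription of the closed form,
# kept separate from the implementation under test.
oracle_similarity <- function(a, b) {
  if (identical(a, b)) return(1)
  ta <- setdiff(strsplit(a, " ", fixed = TRUE)[[1]], "")
  tb <- setdiff(strsplit(b, " ", fixed = TRUE)[[1]], "")
  u <- union(ta, tb)
  jac <- if (length(u) == 0L) 1 else length(intersect(ta, tb)) / length(u)
  lev <- 1 - drop(utils::adist(a, b)) / max(nchar(a), nchar(b))
  max(jac, lev)
}

# Brute-force recount of (normalized name, signature) occurrences straight
# from extract_annotations, bypassing the index machinery.
oracle_counts <- function(corpus, count_codelist_entries = TRUE) {
  ann <- do.call(rbind, lapply(corpus, extract_annotations))
  if (!count_codelist_entries) ann <- ann[ann$owner_kind == "item", , drop = FALSE]
  if (is.null(ann) || nrow(ann) == 0L) {
    return(data.frame(name = character(0), signature = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(normalize_name(ann$name), ann$signature, sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  df <- data.frame(name = vapply(parts, `[[`, "", 1L),
                   signature = vapply(parts, `[[`, "", 2L),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(df$name, df$signature, method = "radix"), , drop = FALSE]
  row.names(df) <- NULL
  df
}

expect_odmsem_error <- function(expr, kind) {
  expect_error(expr, class = paste0("odmsem_", kind))
}
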