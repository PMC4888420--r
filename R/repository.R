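#' Term index: the local metadata-repository surrogate
#'
#' The term index maps normalized item names to curated annotation signatures
#' with usage counts and form references — the structure an annotator queries
#' to re-use codes ("how many times was this item name / code combination
#' used, and on which forms?"). Entries are keyed by the pair
#' (normalized name, canonical signature). Each entry stores its references
#' as (model, form, n) triples, where `n` is the number of annotated elements
#' that model/form contributed; the entry's count is the sum of its `n`
#' values, so a model's contribution can be fully retracted when the model is
#' re-annotated and re-submitted.
#'
#' @param count_codelist_entries should annotated code-list entries be
#'   indexed alongside items? Both concept and value domains carry meaning,
#'   so the default is `TRUE`; set `FALSE` to index item definitions only.
#' @return `term_index()` returns an empty index of class `term_index`.
#' @seealso [build_index()], [update_index()], [lookup_exact()],
#'   [search_similar()], [save_index()]
#' @export
term_index <- function(count_codelist_entries = TRUE) {
  structure(list(entries = list(),
                 count_codelist_entries = isTRUE(count_codelist_entries)),
            class = "term_index")
}

index_key <- function(name, signature) paste(name, signature, sep = "\t")

entry_count <- function(entry) sum(entry$refs$n)

#' All index entries as a data frame
#'
#' @param index a [term_index].
#' @return data frame with columns `name`, `signature`, `count`, sorted by
#'   name then signature.
#' @export
index_entries <- function(index) {
  es <- index$entries
  df <- data.frame(
    name = vapply(es, `[[`, "", "name"),
    signature = vapply(es, `[[`, "", "signature"),
    count = vapply(es, function(e) as.integer(entry_count(e)), integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$name, df$signature, method = "radix"), , drop = FALSE]
  row.names(df) <- NULL
  df
}

# Per-model contributions: one row per annotated element, with the first
# containing form (NA when no form references the element).
model_contributions <- function(model, count_codelist_entries = TRUE) {
  ann <- extract_annotations(model)
  if (!count_codelist_entries) {
    ann <- ann[ann$owner_kind == "item", , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    return(data.frame(name = character(0), signature = character(0),
                      form = character(0), stringsAsFactors = FALSE))
  }
  # form owning each item: first form (model order) whose groups reference it
  item_form <- new.env(parent = emptyenv())
  for (f in model$forms) {
    for (goid in f$group_refs) {
      for (ioid in model$groups[[goid]]$item_refs) {
        if (is.null(item_form[[ioid]])) item_form[[ioid]] <- f$oid
      }
    }
  }
  owner_form <- function(oid, kind) {
    if (kind == "item") {
      fo <- item_form[[oid]]
      return(if (is.null(fo)) NA_character_ else fo)
    }
    cl_oid <- split_entry_oid(oid)$codelist
    # entry inherits the form of the first item using its code list
    for (it in model$items) {
      if (identical(it$codelist_ref, cl_oid)) return(owner_form(it$oid, "item"))
    }
    NA_character_
  }
  data.frame(
    name = normalize_name(ann$name),
    signature = ann$signature,
    form = mapply(owner_form, ann$owner_oid, ann$owner_kind, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Incrementally update the index with one model
#'
#' Replace-on-update semantics: any previous contribution of `model$model_id`
#' is fully retracted (counts decremented, entries whose count reaches zero
#' removed), then the model's current annotations are added. Updating with an
#' unchanged model is therefore a no-op, and the incremental index always
#' equals a from-scratch [build_index()] over the current corpus state.
#'
#' @param index a [term_index].
#' @param model an [odm_model].
#' @return the updated index.
#' @export
update_index <- function(index, model) {
  es <- index$entries
  # retract
  for (key in names(es)) {
    refs <- es[[key]]$refs
    refs <- refs[refs$model != model$model_id, , drop = FALSE]
    if (nrow(refs) == 0L) {
      es[[key]] <- NULL
    } else {
      row.names(refs) <- NULL
      es[[key]]$refs <- refs
    }
  }
  # add
  contrib <- model_contributions(model, index$count_codelist_entries)
  if (nrow(contrib) > 0L) {
    # sentinel for formless occurrences: aggregate() drops NA groups
    contrib$form[is.na(contrib$form)] <- ""
    agg <- stats::aggregate(list(n = rep(1L, nrow(contrib))),
                            by = contrib[c("name", "signature", "form")],
                            FUN = sum)
    agg$form[agg$form == ""] <- NA_character_
    for (i in seq_len(nrow(agg))) {
      key <- index_key(agg$name[i], agg$signature[i])
      ref <- data.frame(model = model$model_id, form = agg$form[i],
                        n = as.integer(agg$n[i]), stringsAsFactors = FALSE)
      if (is.null(es[[key]])) {
        es[[key]] <- list(name = agg$name[i], signature = agg$signature[i], refs = ref)
      } else {
        refs <- rbind(es[[key]]$refs, ref)
        refs <- refs[order(refs$model, refs$form, method = "radix"), , drop = FALSE]
        row.names(refs) <- NULL
        es[[key]]$refs <- refs
      }
    }
  }
  index$entries <- sort_entries(es)
  index
}

sort_entries <- function(es) {
  if (length(es) == 0L) return(es)
  es[order(names(es), method = "radix")]
}

#' Build a term index from a model corpus
#'
#' Folds [update_index()] over the corpus; the result is independent of
#' corpus order. Models must have distinct `model_id`s.
#'
#' @param corpus list of [odm_model] objects.
#' @inheritParams term_index
#' @return a [term_index].
#' @export
build_index <- function(corpus, count_codelist_entries = TRUE) {
  ids <- vapply(corpus, `[[`, "", "model_id")
  if (anyDuplicated(ids)) {
    odm_error("duplicate_model", sprintf(
      "duplicate model_id(s): %s",
      paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", ")))
  }
  Reduce(update_index, corpus, init = term_index(count_codelist_entries))
}

#' Exact-name lookup
#'
#' Entries whose normalized name equals `normalize_name(name)`, sorted by
#' usage count descending; ties broken by canonical signature ascending, so
#' the most-used curated code combination is always listed first.
#'
#' @param index a [term_index].
#' @param name raw item name.
#' @return data frame with columns `name`, `signature`, `count`.
#' @export
lookup_exact <- function(index, name) {
  df <- index_entries(index)
  df <- df[df$name == normalize_name(name), , drop = FALSE]
  df <- df[order(-df$count, df$signature, method = "radix"), , drop = FALSE]
  row.names(df) <- NULL
  df
}

#' Forms where a name/signature combination occurs
#'
#' Resolves an entry's references against a corpus store so a reviewer can
#' inspect the documentation forms where a candidate annotation was used —
#' the context review step of the workflow.
#'
#' @param index a [term_index].
#' @param name,signature identify the entry (raw name is normalized).
#' @param corpus list of [odm_model] objects covering the entry's models.
#' @return data frame with columns `model_id`, `form_oid`, `form_name`.
#' @export
form_context <- function(index, name, signature, corpus) {
  key <- index_key(normalize_name(name), signature)
  entry <- index$entries[[key]]
  if (is.null(entry)) {
    odm_error("lookup", sprintf("no index entry for %s / %s", sQuote(name), signature))
  }
  ids <- vapply(corpus, `[[`, "", "model_id")
  rows <- lapply(seq_len(nrow(entry$refs)), function(i) {
    mid <- entry$refs$model[i]
    hit <- which(ids == mid)
    if (length(hit) == 0L) {
      odm_error("missing_model", sprintf("model %s not in corpus store", sQuote(mid)))
    }
    m <- corpus[[hit[1L]]]
    foid <- entry$refs$form[i]
    fname <- if (!is.na(foid) && foid %in% names(m$forms)) m$forms[[foid]]$name else NA_character_
    data.frame(model_id = mid, form_oid = foid, form_name = fname,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  row.names(out) <- NULL
  out
}

#' Persist and restore a term index
#'
#' JSON-lines persistence: one object per entry,
#' `{"name", "signature", "count", "refs": [{"model", "form", "n"}]}`, entries
#' sorted by name then signature and refs sorted by model then form, so the
#' file is diff-able. `load_index(save_index(i))` reproduces `i` exactly.
#'
#' @param index a [term_index].
#' @param path optional file; when `NULL`, text is returned/parsed directly.
#' @export
save_index <- function(index, path = NULL) {
  lines <- vapply(index$entries, function(e) {
    refs <- e$refs
    refs$form <- ifelse(is.na(refs$form), "", refs$form)
    jsonlite::toJSON(list(
      name = jsonlite::unbox(e$name),
      signature = jsonlite::unbox(e$signature),
      count = jsonlite::unbox(as.integer(entry_count(e))),
      refs = refs
    ), auto_unbox = FALSE)
  }, character(1), USE.NAMES = FALSE)
  meta <- as.character(jsonlite::toJSON(list(
    format = jsonlite::unbox("odmsemantics-term-index"),
    version = jsonlite::unbox(1L),
    count_codelist_entries = jsonlite::unbox(index$count_codelist_entries)
  )))
  txt <- paste(c(meta, lines), collapse = "\n")
  if (!is.null(path)) {
    writeLines(c(meta, lines), path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @rdname save_index
#' @param text JSON-lines text, as produced by `save_index()`.
#' @export
load_index <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(term_index())
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
             error = function(e) odm_error("format", sprintf(
               "malformed index line %d: %s", i, conditionMessage(e))))
  }
  meta <- parse_line(1L)
  if (!identical(meta$format, "odmsemantics-term-index")) {
    odm_error("format", "line 1: missing term-index header")
  }
  index <- term_index(isTRUE(meta$count_codelist_entries))
  es <- list()
  for (i in seq_along(lines)[-1L]) {
    obj <- parse_line(i)
    refs <- as.data.frame(obj$refs, stringsAsFactors = FALSE)
    ok <- is.character(obj$name) && is_canonical_signature(obj$signature) &&
      nrow(refs) > 0L && all(c("model", "form", "n") %in% names(refs)) &&
      all(refs$n >= 1L) && identical(as.integer(obj$count), as.integer(sum(refs$n)))
    if (!ok) {
      odm_error("format", sprintf("invalid index entry at line %d", i))
    }
    refs$n <- as.integer(refs$n)
    refs$form <- ifelse(refs$form == "", NA_character_, refs$form)
    refs <- refs[c("model", "form", "n")]
    row.names(refs) <- NULL
    key <- index_key(obj$name, obj$signature)
    if (!is.null(es[[key]])) {
      odm_error("format", sprintf("duplicate index entry at line %d", i))
    }
    es[[key]] <- list(name = obj$name, signature = obj$signature, refs = refs)
  }
  index$entries <- sort_entries(es)
  index
}

#' @export
print.term_index <- function(x, ...) {
  df <- index_entries(x)
  cat(sprintf("<term_index> %d entries, %d annotated occurrences\n",
              nrow(df), sum(df$count)))
  invisible(x)
}
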