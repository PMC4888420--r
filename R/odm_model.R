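#' In-memory study metadata model
#'
#' `odm_model()` and its element constructors build the metadata subset of a
#' CDISC ODM 1.3 study that carries data elements and their semantic
#' annotations: forms referencing item groups, item groups referencing items,
#' items optionally referencing code lists, and annotation signatures on items
#' and on code-list entries. Clinical (subject) data is out of scope.
#'
#' Data elements follow the ISO/IEC 11179 split: the item definition is the
#' concept domain, its code list the value domain — both can be annotated.
#' Code-list entries have no OID of their own in ODM; throughout the package
#' they are addressed by the pseudo-OID `"<codelist_oid>/<coded_value>"`.
#'
#' @param model_id,study_name identifiers for the model.
#' @param forms list of `odm_form()` objects.
#' @param groups list of `odm_group()` objects.
#' @param items list of `odm_item()` objects.
#' @param codelists list of `odm_codelist()` objects.
#' @return an object of class `odm_model`.
#' @seealso [read_odm()], [write_odm()], [validate_model()],
#'   [set_annotation()], [extract_annotations()]
#' @export
odm_model <- function(model_id, study_name = model_id, forms = list(),
                      groups = list(), items = list(), codelists = list()) {
  m <- structure(
    list(model_id = as.character(model_id),
         study_name = as.character(study_name),
         forms = forms, groups = groups, items = items, codelists = codelists),
    class = "odm_model"
  )
  names(m$forms) <- vapply(forms, `[[`, "", "oid")
  names(m$groups) <- vapply(groups, `[[`, "", "oid")
  names(m$items) <- vapply(items, `[[`, "", "oid")
  names(m$codelists) <- vapply(codelists, `[[`, "", "oid")
  m
}

.odm_types <- c("integer", "float", "string", "date", "datetime", "boolean", "text")

#' @rdname odm_model
#' @param oid element OID, unique within its element class.
#' @param name human-readable element name.
#' @param group_refs,item_refs ordered character vectors of referenced OIDs.
#' @export
odm_form <- function(oid, name, group_refs = character()) {
  list(oid = as.character(oid), name = as.character(name),
       group_refs = as.character(group_refs))
}

#' @rdname odm_model
#' @export
odm_group <- function(oid, name, item_refs = character()) {
  list(oid = as.character(oid), name = as.character(name),
       item_refs = as.character(item_refs))
}

#' @rdname odm_model
#' @param data_type one of integer, float, string, date, datetime, boolean, text.
#' @param description,question optional display texts (first translation kept).
#' @param question_lang language tag of the kept question text, if any.
#' @param range_min,range_max optional numeric bounds (soft range checks).
#' @param unit optional measurement-unit name.
#' @param codelist_ref optional OID of the item's code list.
#' @param annotation optional annotation signature (canonicalized).
#' @export
odm_item <- function(oid, name, data_type = "string", description = NULL,
                     question = NULL, question_lang = NULL,
                     range_min = NULL, range_max = NULL, unit = NULL,
                     codelist_ref = NULL, annotation = NULL) {
  data_type <- match.arg(data_type, .odm_types)
  if (!is.null(annotation)) annotation <- canonical_signature(signature_codes(annotation))
  list(oid = as.character(oid), name = as.character(name),
       data_type = data_type,
       description = description, question = question,
       question_lang = question_lang,
       range_min = if (is.null(range_min)) NULL else as.numeric(range_min),
       range_max = if (is.null(range_max)) NULL else as.numeric(range_max),
       unit = unit, codelist_ref = codelist_ref, annotation = annotation)
}

#' @rdname odm_model
#' @param entries data frame with columns `coded_value`, `decode`,
#'   `annotation` (NA for unannotated entries).
#' @export
odm_codelist <- function(oid, name, entries) {
  stopifnot(is.data.frame(entries),
            all(c("coded_value", "decode") %in% names(entries)))
  if (is.null(entries$annotation)) entries$annotation <- NA_character_
  entries <- entries[c("coded_value", "decode", "annotation")]
  entries$coded_value <- as.character(entries$coded_value)
  entries$decode <- as.character(entries$decode)
  entries$annotation <- as.character(entries$annotation)
  row.names(entries) <- NULL
  list(oid = as.character(oid), name = as.character(name), entries = entries)
}

#' Validate a study metadata model
#'
#' Checks every structural invariant: OID uniqueness per element class,
#' referential integrity of form-to-group, group-to-item and item-to-codelist
#' references, range ordering (`range_min <= range_max`), uniqueness of coded
#' values within a code list, and canonical form of every annotation
#' signature. Issues are returned as data, not raised.
#'
#' @param model an [odm_model].
#' @return data frame with columns `oid`, `rule`, `message`; zero rows iff the
#'   model is valid.
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(oid, rule, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      oid = oid, rule = rule, message = message, stringsAsFactors = FALSE)
  }
  for (cls in c("forms", "groups", "items", "codelists")) {
    oids <- vapply(model[[cls]], `[[`, "", "oid")
    for (d in unique(oids[duplicated(oids)])) {
      add(d, "duplicate-oid", sprintf("OID %s used more than once in %s", sQuote(d), cls))
    }
  }
  item_oids <- names(model$items)
  group_oids <- names(model$groups)
  cl_oids <- names(model$codelists)
  for (f in model$forms) {
    for (ref in setdiff(f$group_refs, group_oids)) {
      add(f$oid, "dangling-ref", sprintf("form %s references missing item group %s",
                                         sQuote(f$oid), sQuote(ref)))
    }
  }
  for (g in model$groups) {
    for (ref in setdiff(g$item_refs, item_oids)) {
      add(g$oid, "dangling-ref", sprintf("item group %s references missing item %s",
                                         sQuote(g$oid), sQuote(ref)))
    }
  }
  for (it in model$items) {
    if (!is.null(it$codelist_ref) && !it$codelist_ref %in% cl_oids) {
      add(it$oid, "dangling-ref", sprintf("item %s references missing code list %s",
                                          sQuote(it$oid), sQuote(it$codelist_ref)))
    }
    if (!is.null(it$range_min) && !is.null(it$range_max) && it$range_min > it$range_max) {
      add(it$oid, "range-order", sprintf("item %s has range_min %g > range_max %g",
                                         sQuote(it$oid), it$range_min, it$range_max))
    }
    if (!is.null(it$annotation) && !is_canonical_signature(it$annotation)) {
      add(it$oid, "bad-signature", sprintf("item %s annotation %s is not canonical",
                                           sQuote(it$oid), sQuote(it$annotation)))
    }
  }
  for (cl in model$codelists) {
    dup <- unique(cl$entries$coded_value[duplicated(cl$entries$coded_value)])
    for (d in dup) {
      add(cl$oid, "duplicate-coded-value",
          sprintf("code list %s repeats coded value %s", sQuote(cl$oid), sQuote(d)))
    }
    ann <- cl$entries$annotation
    bad <- !is.na(ann) & !vapply(ann, is_canonical_signature, logical(1))
    for (v in cl$entries$coded_value[bad]) {
      add(entry_oid(cl$oid, v), "bad-signature",
          sprintf("code-list entry %s annotation is not canonical", sQuote(v)))
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(oid = character(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

entry_oid <- function(codelist_oid, coded_value) {
  paste0(codelist_oid, "/", coded_value)
}

# Split an entry pseudo-OID at its FIRST "/": codelist OIDs may not contain
# "/", coded values may.
split_entry_oid <- function(oid) {
  pos <- regexpr("/", oid, fixed = TRUE)
  if (pos < 0L) return(NULL)
  list(codelist = substr(oid, 1L, pos - 1L),
       coded_value = substr(oid, pos + 1L, nchar(oid)))
}

#' Set or replace the annotation of an item or code-list entry
#'
#' The target keeps the canonicalized signature; any previous signature is
#' replaced (the reviewer's latest decision is authoritative). All other
#' content is untouched. Code-list entries are addressed by their pseudo-OID
#' `"<codelist_oid>/<coded_value>"`.
#'
#' @param model an [odm_model].
#' @param target_oid item OID or code-list-entry pseudo-OID.
#' @param signature signature string or character vector of concept codes.
#' @return the modified model.
#' @export
set_annotation <- function(model, target_oid, signature) {
  sig <- canonical_signature(unlist(strsplit(as.character(signature), "+", fixed = TRUE)))
  if (target_oid %in% names(model$items)) {
    model$items[[target_oid]]$annotation <- sig
    return(model)
  }
  parts <- split_entry_oid(target_oid)
  if (!is.null(parts) && parts$codelist %in% names(model$codelists)) {
    cl <- model$codelists[[parts$codelist]]
    hit <- cl$entries$coded_value == parts$coded_value
    if (any(hit)) {
      model$codelists[[parts$codelist]]$entries$annotation[hit] <- sig
      return(model)
    }
  }
  odm_error("lookup", sprintf("no item or code-list entry with OID %s", sQuote(target_oid)))
}

#' Extract all annotations from a model
#'
#' One row per annotated item and per annotated code-list entry; unannotated
#' elements are omitted. Code-list entries report their decode text as name.
#'
#' @param model an [odm_model].
#' @return data frame with columns `owner_oid`, `owner_kind`
#'   (`"item"`/`"codelist_entry"`), `name`, `signature`.
#' @export
extract_annotations <- function(model) {
  rows <- list()
  for (it in model$items) {
    if (!is.null(it$annotation)) {
      rows[[length(rows) + 1L]] <- data.frame(
        owner_oid = it$oid, owner_kind = "item", name = it$name,
        signature = it$annotation, stringsAsFactors = FALSE)
    }
  }
  for (cl in model$codelists) {
    ann <- cl$entries$annotation
    keep <- !is.na(ann)
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        owner_oid = entry_oid(cl$oid, cl$entries$coded_value[keep]),
        owner_kind = "codelist_entry",
        name = cl$entries$decode[keep],
        signature = ann[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(owner_oid = character(0), owner_kind = character(0),
                      name = character(0), signature = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Annotation coverage of a model
#'
#' Fraction of annotation targets (items plus code-list entries) that carry a
#' signature. A model with no targets is defined to have coverage 1.
#'
#' @param model an [odm_model].
#' @return a number in \[0, 1\].
#' @export
coverage <- function(model) {
  n_items <- length(model$items)
  n_entries <- sum(vapply(model$codelists, function(cl) nrow(cl$entries), integer(1)))
  total <- n_items + n_entries
  if (total == 0L) return(1)
  ann_items <- sum(vapply(model$items, function(it) !is.null(it$annotation), logical(1)))
  ann_entries <- sum(vapply(model$codelists,
                            function(cl) sum(!is.na(cl$entries$annotation)), integer(1)))
  (ann_items + ann_entries) / total
}

# OIDs of all unannotated targets, in model order (items, then entries).
unannotated_targets <- function(model) {
  out <- character(0)
  for (it in model$items) if (is.null(it$annotation)) out <- c(out, it$oid)
  for (cl in model$codelists) {
    miss <- is.na(cl$entries$annotation)
    out <- c(out, entry_oid(cl$oid, cl$entries$coded_value[miss]))
  }
  out
}

# Display name of a target (item name or entry decode text).
target_name <- function(model, target_oid) {
  if (target_oid %in% names(model$items)) return(model$items[[target_oid]]$name)
  parts <- split_entry_oid(target_oid)
  if (!is.null(parts) && parts$codelist %in% names(model$codelists)) {
    cl <- model$codelists[[parts$codelist]]
    hit <- cl$entries$coded_value == parts$coded_value
    if (any(hit)) return(cl$entries$decode[hit][1L])
  }
  odm_error("lookup", sprintf("no item or code-list entry with OID %s", sQuote(target_oid)))
}

#' @export
print.odm_model <- function(x, ...) {
  cat(sprintf("<odm_model %s> study %s: %d form(s), %d group(s), %d item(s), %d code list(s); coverage %.2f\n",
              x$model_id, sQuote(x$study_name), length(x$forms), length(x$groups),
              length(x$items), length(x$codelists), coverage(x)))
  invisible(x)
}
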